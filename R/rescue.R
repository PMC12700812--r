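# Rescue analysis: a LOWESS null of rescue-vs-control expression, per-variant
# residuals, per-position two-sided Mann-Whitney outlier tests with
# Benjamini-Hochberg FDR, and per-variant rescue-magnitude calls.

#' Robust LOWESS fit evaluated at the input points
#'
#' Locally weighted linear regression with a tricube kernel over the nearest
#' `fraction * n` points and `iterations` bisquare robustifying passes
#' (Cleveland's algorithm). `delta = 0` evaluates the fit exactly at every
#' point. Tied x values receive the same fitted value, and fitted values are
#' returned in the input order.
#'
#' @param x,y numeric vectors (at least 10 points).
#' @param fraction span in (0, 1\].
#' @param iterations robustifying iterations (0 = plain local regression).
#' @param delta interpolation shortcut distance; 0 for exact evaluation.
#' @return fitted values at `x`, in input order.
#' @export
fit_lowess <- function(x, y, fraction = 0.3, iterations = 3, delta = 0) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (length(x) < 10) stop("need at least 10 points")
  if (any(!is.finite(x))) stop("x must be finite")
  lw <- stats::lowess(x, y, f = fraction, iter = iterations, delta = delta)
  ord <- order(x)
  fitted <- numeric(length(x))
  fitted[ord] <- lw$y
  fitted
}

#' Fit the rescue-vs-control null curve
#'
#' Joins the control and rescue score tables on the variant key (variants
#' scored in both conditions), fits a LOWESS curve of rescue score on
#' control score, and computes per-variant residuals (rescue minus fitted).
#' The curve is the null expectation for the magnitude of rescue at each
#' control expression level; residuals measure position-specific departures.
#'
#' @param control,rescue per-variant score tables (tibbles with `variant`
#'   and `score`; `position` and `sem` are carried through when present).
#'   Alternatively `control` may be a pre-paired tibble with columns
#'   `control_score` and `rescue_score` (then `rescue` is ignored).
#' @param fraction,iterations,delta LOWESS parameters
#'   (see [fit_lowess()]).
#' @return an object of class `rescue_fit`: list with `data` (tibble:
#'   `variant`, `position`, `control_score`, `rescue_score`, `rescue_sem`,
#'   `fitted`, `residual`) and `params`.
#' @export
rescue_fit <- function(control, rescue = NULL, fraction = 0.3,
                       iterations = 3, delta = 0) {
  if (!is.null(rescue)) {
    take <- function(d, suffix) {
      d %>%
        dplyr::select(dplyr::any_of(c("variant", "position", "score", "sem"))) %>%
        dplyr::rename_with(~ paste0(suffix, "_", .x),
                           dplyr::any_of(c("score", "sem")))
    }
    paired <- dplyr::inner_join(
      take(control, "control"), take(rescue, "rescue"),
      by = intersect(c("variant", "position"), intersect(names(control), names(rescue)))
    )
  } else {
    paired <- control
  }
  stopifnot(all(c("control_score", "rescue_score") %in% names(paired)))
  paired <- dplyr::filter(paired, !is.na(.data$control_score),
                          !is.na(.data$rescue_score))
  fitted <- fit_lowess(paired$control_score, paired$rescue_score,
                       fraction = fraction, iterations = iterations,
                       delta = delta)
  paired$fitted <- fitted
  paired$residual <- paired$rescue_score - fitted
  structure(list(
    data = tibble::as_tibble(paired),
    params = list(fraction = fraction, iterations = iterations, delta = delta)
  ), class = "rescue_fit")
}

#' @export
print.rescue_fit <- function(x, ...) {
  cat("<rescue_fit>\n")
  cat(sprintf("  %d paired variants; LOWESS fraction %.2f, %d robust iterations\n",
              nrow(x$data), x$params$fraction, x$params$iterations))
  cat(sprintf("  mean residual %.4f, residual s.d. %.4f\n",
              mean(x$data$residual), stats::sd(x$data$residual)))
  invisible(x)
}

#' @export
residuals.rescue_fit <- function(object, ...) object$data$residual

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-variant residual table of a rescue fit
#'
#' @param x a `rescue_fit`.
#' @param ... unused.
#' @return tibble with one row per paired variant.
#' @method tidy rescue_fit
#' @export
tidy.rescue_fit <- function(x, ...) x$data

#' One-row summary of a rescue fit
#'
#' @param x a `rescue_fit`.
#' @param ... unused.
#' @method glance rescue_fit
#' @export
glance.rescue_fit <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$data),
    fraction = x$params$fraction,
    iterations = x$params$iterations,
    mean_residual = mean(x$data$residual),
    sd_residual = stats::sd(x$data$residual)
  )
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties. The p value is exact (from the
#' null distribution of U) when both samples have at most 8 observations
#' and there are no ties; otherwise a normal approximation with tie
#' correction and continuity correction is used. `U` is the statistic of
#' the first sample (number of pairs where `a` exceeds `b`, ties counting
#' one half).
#'
#' @param a,b numeric samples (non-empty).
#' @return tibble with `statistic` (U of `a`), `p.value`, `n_a`, `n_b`,
#'   `method`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4)) # U = 0, p = 1/3
mann_whitney_u <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  n_a <- length(a)
  n_b <- length(b)
  if (n_a == 0 || n_b == 0) stop("both samples must be non-empty")
  all_v <- c(a, b)
  r <- rank(all_v)
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- table(all_v)
  has_ties <- any(ties > 1)
  n <- n_a + n_b

  if (max(ties) == n) {
    return(tibble::tibble(statistic = u, p.value = 1, n_a = n_a, n_b = n_b,
                          method = "degenerate"))
  }
  if (!has_ties && n_a <= 8 && n_b <= 8) {
    p <- 2 * min(stats::pwilcox(u, n_a, n_b),
                 1 - stats::pwilcox(u - 1, n_a, n_b))
    return(tibble::tibble(statistic = u, p.value = min(p, 1),
                          n_a = n_a, n_b = n_b, method = "exact"))
  }
  mu <- n_a * n_b / 2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    return(tibble::tibble(statistic = u, p.value = 1, n_a = n_a, n_b = n_b,
                          method = "degenerate"))
  }
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  tibble::tibble(statistic = u, p.value = p, n_a = n_a, n_b = n_b,
                 method = "normal approximation")
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: with `m` p values sorted ascending, reject the `k`
#' smallest where `k` is the largest index with `p_(k) <= k * alpha / m`.
#' Adjusted q values are `q_(i) = min over j >= i of m * p_(j) / j`, capped
#' at 1; rejection is `q <= alpha`, invariant to input order.
#'
#' @param p p values in \[0, 1\].
#' @param alpha target FDR.
#' @return tibble with `p`, `q`, `rejected` in input order.
#' @export
bh_fdr <- function(p, alpha = 0.1) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  tibble::tibble(p = p, q = q, rejected = !is.na(q) & q <= alpha)
}

#' Per-position rescue-outlier test
#'
#' Restricts to variants with control score below `max_control` (only
#' variants with room to be rescued), then tests each position's residuals
#' against the residuals of all variants at all other positions (two-sided
#' Mann-Whitney U), controls the FDR across positions with
#' Benjamini-Hochberg at `alpha`, and reports the outlier direction from the
#' sign of the position's mean residual. Positions with no qualifying
#' variants are skipped and reported in the `skipped_positions` attribute.
#'
#' @param fit a [rescue_fit()].
#' @param max_control control-score ceiling for inclusion (default 0.85);
#'   applied to both the position's variants and the comparison pool.
#' @param alpha FDR level (default 0.1).
#' @return tibble with one row per tested position: `position`,
#'   `n_variants`, `mean_residual`, `statistic`, `p.value`, `q.value`,
#'   `direction` (`more`/`less`/`none`), `outlier`.
#' @export
position_outlier_test <- function(fit, max_control = 0.85, alpha = 0.1) {
  stopifnot(inherits(fit, "rescue_fit"))
  d <- fit$data %>%
    dplyr::filter(!is.na(.data$position),
                  .data$control_score < max_control)
  skipped <- setdiff(unique(fit$data$position), unique(d$position))
  skipped <- skipped[!is.na(skipped)]
  if (nrow(d) == 0) {
    warning("no variants qualify below max_control = ", max_control)
    out <- tibble::tibble(position = integer(), n_variants = integer(),
                          mean_residual = numeric(), statistic = numeric(),
                          p.value = numeric(), q.value = numeric(),
                          direction = character(), outlier = logical())
    attr(out, "skipped_positions") <- skipped
    return(out)
  }
  if (dplyr::n_distinct(d$position) < 2) {
    stop("need qualifying variants at >= 2 positions")
  }
  stats_tbl <- d %>%
    dplyr::group_by(.data$position) %>%
    dplyr::group_modify(function(grp, key) {
      pool <- d$residual[d$position != key$position]
      tst <- mann_whitney_u(grp$residual, pool)
      tibble::tibble(
        n_variants = nrow(grp),
        mean_residual = mean(grp$residual),
        statistic = tst$statistic,
        p.value = tst$p.value
      )
    }) %>%
    dplyr::ungroup()
  adj <- bh_fdr(stats_tbl$p.value, alpha = alpha)
  out <- stats_tbl %>%
    dplyr::mutate(
      q.value = adj$q,
      outlier = adj$rejected,
      direction = dplyr::case_when(
        !outlier ~ "none",
        mean_residual > 0 ~ "more",
        TRUE ~ "less"
      )
    ) %>%
    dplyr::relocate("direction", .before = "outlier")
  attr(out, "skipped_positions") <- skipped
  out
}

#' Per-variant rescue-magnitude significance
#'
#' A variant is called significantly rescued when its rescue gain
#' (rescue minus control score) exceeds the half-width of the rescue
#' score's 95% confidence interval, i.e. the control score lies below the
#' rescue score's 95% CI.
#'
#' @param control_score,rescue_score per-variant scores.
#' @param rescue_sem standard error of the rescue score (NA gives NA).
#' @param conf_mult CI multiplier (1.96 for a Normal 95% interval).
#' @return logical vector (NA where `rescue_sem` is NA).
#' @export
rescue_magnitude_calls <- function(control_score, rescue_score, rescue_sem,
                                   conf_mult = 1.96) {
  if (any(rescue_sem < 0, na.rm = TRUE)) stop("rescue_sem must be >= 0")
  (rescue_score - control_score) > conf_mult * rescue_sem
}
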