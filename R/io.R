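# Table I/O contracts, run configuration and the end-to-end pipeline driver.
# All tables are TSV with header, UTF-8, "NA" for missing values; variant
# keys are serialized as e.g. "A84P", "W71*", "L62=".

#' Write a package table as TSV
#'
#' Fixed contract: tab-separated, header, `NA` for missing values.
#' @param x tibble.
#' @param path output path.
#' @return `x`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(x, path, na = "NA")
  invisible(x)
}

#' Read a package table from TSV
#'
#' @param path TSV path.
#' @param col_types optional readr column specification.
#' @return a tibble.
#' @export
read_table_tsv <- function(path, col_types = NULL) {
  readr::read_tsv(path, na = "NA", col_types = col_types %||% readr::cols(),
                  progress = FALSE, show_col_types = FALSE)
}

#' Read a per-variant score table
#'
#' Accepts the package's own score TSVs, or any deposited per-variant table
#' with columns `position`, `wt_aa`, `mut_aa` and a score column; a
#' `variant` key column is derived when absent.
#'
#' @param path TSV path.
#' @param score_col name of the score column (renamed to `score`).
#' @return a score tibble keyed by `variant`.
#' @export
read_score_table <- function(path, score_col = "score") {
  x <- read_table_tsv(path)
  if (!score_col %in% names(x)) {
    stop("score column '", score_col, "' not found in ", path)
  }
  if (score_col != "score") x <- dplyr::rename(x, score = dplyr::all_of(score_col))
  if (!"variant" %in% names(x)) {
    stopifnot(all(c("position", "wt_aa", "mut_aa") %in% names(x)))
    x$variant <- format_variant_key(x$wt_aa, x$position, x$mut_aa)
  }
  if (!"vclass" %in% names(x) && all(c("wt_aa", "mut_aa") %in% names(x))) {
    x$vclass <- variant_class(x$wt_aa, x$mut_aa, x$variant)
  }
  tibble::as_tibble(x)
}

# ---- run configuration ------------------------------------------------------

.scoring_defaults <- function() list(min_cells = 50, min_replicates = 2,
                                     max_stop_pos = 299)
.rescue_defaults <- function() list(fraction = 0.3, iterations = 3, delta = 0,
                                    max_control = 0.85, alpha = 0.1)

.merge_section <- function(defaults, user, section) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown key(s) in config section '", section, "': ",
         paste(unknown, collapse = ", "))
  }
  utils::modifyList(defaults, user)
}

#' Build a run configuration
#'
#' @param sim named list of [sim_config()] overrides.
#' @param scoring named list: `min_cells`, `min_replicates`, `max_stop_pos`.
#' @param rescue named list: `fraction`, `iterations`, `delta`,
#'   `max_control`, `alpha`.
#' @param seed overrides `sim$seed` when given.
#' @return an object of class `run_config`.
#' @export
run_config <- function(sim = list(), scoring = list(), rescue = list(),
                       seed = NULL) {
  sim_defaults <- formals(sim_config)
  unknown <- setdiff(names(sim), names(sim_defaults))
  if (length(unknown) > 0) {
    stop("unknown key(s) in config section 'sim': ",
         paste(unknown, collapse = ", "))
  }
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  cfg <- list(
    sim = do.call(sim_config, sim),
    scoring = .merge_section(.scoring_defaults(), scoring, "scoring"),
    rescue = .merge_section(.rescue_defaults(), rescue, "rescue")
  )
  if (cfg$scoring$min_cells < 0) stop("min_cells must be >= 0")
  if (cfg$scoring$min_replicates < 1) stop("min_replicates must be >= 1")
  if (cfg$rescue$alpha <= 0 || cfg$rescue$alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Missing keys take defaults; unknown keys and out-of-range values are
#' rejected with the offending key named. An empty file yields all
#' defaults. Round-trips with [save_config()].
#'
#' @param path YAML file with optional sections `sim`, `scoring`, `rescue`
#'   and top-level `seed`.
#' @return a `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  unknown <- setdiff(names(y), c("sim", "scoring", "rescue", "seed"))
  if (length(unknown) > 0) {
    stop("unknown top-level config key(s): ", paste(unknown, collapse = ", "))
  }
  run_config(sim = y$sim %||% list(), scoring = y$scoring %||% list(),
             rescue = y$rescue %||% list(), seed = y$seed)
}

#' Serialize a run configuration to YAML
#'
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- list(sim = unclass(config$sim), scoring = config$scoring,
              rescue = config$rescue)
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- pipeline ---------------------------------------------------------------

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full simulate-map-score-rescue-annotate pipeline
#'
#' Executes the five stages in order, writing each stage's TSV/JSON outputs
#' into `out_dir` together with the resolved configuration and a manifest
#' (stage, parameters, row counts, file MD5 hashes). Re-running with an
#' identical configuration reproduces identical outputs; a stage failure
#' halts with the failing stage named, retaining earlier outputs.
#'
#' @param config a [run_config()] (or [load_config()] result).
#' @param out_dir output directory (created if needed).
#' @param seed optional seed override.
#' @return invisibly, a list with the main in-memory results
#'   (`experiment`, `map`, `scores`, `fit`, `position_stats`, `annotated`)
#'   and `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir, seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(seed)) {
    config <- run_config(sim = utils::modifyList(
      purrr::keep(unclass(config$sim), ~ !is.null(.x)), list(seed = as.integer(seed))),
      scoring = config$scoring, rescue = config$rescue)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  save_config(config, file.path(out_dir, "config.yaml"))
  manifest <- list()
  note <- function(stage, rows, files) {
    manifest[[length(manifest) + 1]] <<- list(
      stage = stage, rows = rows,
      outputs = as.list(tools::md5sum(file.path(out_dir, files)))
    )
  }

  # 1. simulate
  exper <- .stage("simulate", {
    ex <- simulate_experiment(config$sim)
    lr <- simulate_longreads(ex$library)
    write_table_tsv(ex$counts, file.path(out_dir, "counts.tsv"))
    write_table_tsv(ex$bins, file.path(out_dir, "bins.tsv"))
    write_table_tsv(ex$library$truth, file.path(out_dir, "ground_truth.tsv"))
    write_table_tsv(lr, file.path(out_dir, "longreads.tsv"))
    writeLines(c(">cds", ex$library$cds), file.path(out_dir, "cds.fasta"))
    list(ex = ex, longreads = lr)
  })
  note("simulate", nrow(exper$ex$counts),
       c("counts.tsv", "bins.tsv", "ground_truth.tsv", "longreads.tsv"))

  # 2. map barcodes
  map <- .stage("map-barcodes", {
    m <- build_barcode_map(exper$longreads, exper$ex$library$cds)
    write_table_tsv(m, file.path(out_dir, "barcode_map.tsv"))
    m
  })
  note("map-barcodes", nrow(map), "barcode_map.tsv")

  # 3. score
  scores <- .stage("score", {
    s <- score_experiment(exper$ex$counts, exper$ex$bins, map,
                          min_cells = config$scoring$min_cells,
                          min_replicates = config$scoring$min_replicates,
                          max_stop_pos = config$scoring$max_stop_pos)
    write_table_tsv(s, file.path(out_dir, "scores.tsv"))
    jsonlite::write_json(attr(s, "thresholds"),
                         file.path(out_dir, "thresholds.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    s
  })
  note("score", nrow(scores), c("scores.tsv", "thresholds.json"))

  # 4. rescue
  resc <- .stage("rescue", {
    ctrl <- dplyr::filter(scores, .data$condition == "control")
    trt <- dplyr::filter(scores, .data$condition == "rescue")
    fit <- rescue_fit(ctrl, trt,
                      fraction = config$rescue$fraction,
                      iterations = config$rescue$iterations,
                      delta = config$rescue$delta)
    pos <- position_outlier_test(fit,
                                 max_control = config$rescue$max_control,
                                 alpha = config$rescue$alpha)
    write_table_tsv(tidy(fit), file.path(out_dir, "residuals.tsv"))
    write_table_tsv(pos, file.path(out_dir, "position_stats.tsv"))
    list(fit = fit, pos = pos)
  })
  note("rescue", nrow(resc$pos), c("residuals.tsv", "position_stats.tsv"))

  # 5. annotate
  annotated <- .stage("annotate", {
    ctrl <- dplyr::filter(scores, .data$condition == "control")
    hp <- hydrophobicity_preference(ctrl)
    a <- dplyr::left_join(ctrl, hp, by = "position")
    write_table_tsv(a, file.path(out_dir, "annotated_scores.tsv"))
    a
  })
  note("annotate", nrow(annotated), "annotated_scores.tsv")

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(experiment = exper$ex, map = map, scores = scores,
                 fit = resc$fit, position_stats = resc$pos,
                 annotated = annotated, manifest = manifest))
}
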