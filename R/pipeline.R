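#' Pipeline configuration
#'
#' Collects every tunable constant of the end-to-end analysis: the fold
#' count and seed of the cross-validation, the one-sided clone-screen level
#' (0.1), the marker-selection threshold (0.001), the specificity targets
#' (80% and 90%), the panel sizes enumerated, the number of top models used
#' for usage frequencies (50), the saturation tolerance, the ridge, the
#' prediction-score bin boundary (0.4), and the cap on the number of
#' candidate markers entering the exhaustive search.
#'
#' @param seed integer seed for fold assignment.
#' @param folds number of CV folds (>= 2).
#' @param alpha_screen one-sided clone-screen level in (0,1).
#' @param alpha_select marker-selection p threshold in (0,1).
#' @param spec_targets specificity targets (informational; the metrics are
#'   always reported at 0.80 and 0.90).
#' @param k_range panel sizes to enumerate; `NULL` = all sizes up to the
#'   number of candidates.
#' @param top_n top models per size for usage frequencies (>= 1).
#' @param saturation_eps saturation tolerance.
#' @param ridge ridge penalty.
#' @param score_bin_boundary prediction-score bin boundary in (0,1).
#' @param max_candidates cap on candidates entering the exhaustive search;
#'   when the univariate screen selects more, the smallest p-values win.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, folds = 5, alpha_screen = 0.1,
                            alpha_select = 0.001,
                            spec_targets = c(0.80, 0.90), k_range = NULL,
                            top_n = 50, saturation_eps = 0.0075,
                            ridge = 1e-6, score_bin_boundary = 0.4,
                            max_candidates = 12) {
  cfg <- list(seed = seed, folds = folds, alpha_screen = alpha_screen,
              alpha_select = alpha_select, spec_targets = spec_targets,
              k_range = k_range, top_n = top_n,
              saturation_eps = saturation_eps, ridge = ridge,
              score_bin_boundary = score_bin_boundary,
              max_candidates = max_candidates)
  for (f in c("alpha_screen", "alpha_select", "score_bin_boundary")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
      stop("invalid configuration: '", f, "' must be in (0,1)", call. = FALSE)
    }
  }
  if (any(cfg$spec_targets <= 0) || any(cfg$spec_targets >= 1)) {
    stop("invalid configuration: 'spec_targets' must be in (0,1)", call. = FALSE)
  }
  if (!is.numeric(cfg$folds) || cfg$folds < 2 || cfg$folds != round(cfg$folds)) {
    stop("invalid configuration: 'folds' must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(cfg$top_n) || cfg$top_n < 1) {
    stop("invalid configuration: 'top_n' must be >= 1", call. = FALSE)
  }
  if (!is.numeric(cfg$ridge) || cfg$ridge < 0) {
    stop("invalid configuration: 'ridge' must be >= 0", call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the end-to-end panel discovery and validation pipeline
#'
#' Executes, on one sample table containing both splits: (1) univariate
#' marker screening on the training split; (2) exhaustive cross-validated
#' subset search over the selected candidates with saturation-based panel
#' sizing; (3) final model fit on the full training split; (4) validation
#' on the test split; (5) when serum tumor-marker columns are present, the
#' three-way comparison of autoantibody, serum, and combined models. All
#' randomness flows from `config$seed`.
#'
#' @param table sample table with both `train` and `test` splits.
#' @param config a [pipeline_config()].
#' @return object of class `panel_pipeline`: `config`, `marker_screen`,
#'   `candidates`, `folds`, `search`, `model`, `evaluation`, `comparison`
#'   (or NULL), `version`.
#' @export
run_pipeline <- function(table, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  table <- validate_sample_table(table)
  train <- table[table$split == "train", , drop = FALSE]
  test <- table[table$split == "test", , drop = FALSE]
  if (!nrow(train) || !nrow(test)) {
    stop("table must contain both a train and a test split", call. = FALSE)
  }

  screen <- t_screen(train, alpha_select = config$alpha_select)
  cand <- screen$marker[screen$selected]
  if (!length(cand)) {
    stop("marker screen selected no candidates at alpha_select = ",
         config$alpha_select, call. = FALSE)
  }
  if (length(cand) > config$max_candidates) {
    cand <- cand[seq_len(config$max_candidates)]   # screen is p-ordered
  }

  folds <- make_folds(as_case_labels(train$group), k = config$folds,
                      seed = config$seed)
  k_range <- if (is.null(config$k_range)) seq_along(cand) else config$k_range
  search <- exhaustive_search(train, cand, k_range = k_range, folds = folds,
                              ridge = config$ridge, top_n = config$top_n,
                              eps = config$saturation_eps)
  model <- fit_logistic(train, search$best_panel, ridge = config$ridge)
  evaluation <- validate_panel(model, test,
                               boundary = config$score_bin_boundary)
  comparison <- NULL
  if (length(serum_columns(table))) {
    comparison <- compare_models(train, test, search$best_panel,
                                 ridge = config$ridge,
                                 boundary = config$score_bin_boundary)
  }
  structure(list(config = config, marker_screen = screen, candidates = cand,
                 folds = folds, search = search, model = model,
                 evaluation = evaluation, comparison = comparison,
                 version = as.character(packageVersion("abpanel"))),
            class = "panel_pipeline")
}

#' @export
print.panel_pipeline <- function(x, ...) {
  cat("Autoantibody panel discovery pipeline\n")
  cat(sprintf("  candidates after univariate screen: %d (%s)\n",
              length(x$candidates), paste(x$candidates, collapse = ", ")))
  cat(sprintf("  selected panel (k* = %s): %s\n", format(x$search$k_star),
              paste(x$search$best_panel, collapse = ", ")))
  cat(sprintf("  training CV:  AUC %.4f | sens@80%% %.4f | sens@90%% %.4f\n",
              x$search$saturation$max_auc[x$search$saturation$size == x$search$k_star],
              x$search$saturation$max_sens80[x$search$saturation$size == x$search$k_star],
              x$search$saturation$max_sens90[x$search$saturation$size == x$search$k_star]))
  cat(sprintf("  test set:     AUC %.4f | sens@80%% %.4f | sens@90%% %.4f\n",
              x$evaluation$auc_test, x$evaluation$sens80_test,
              x$evaluation$sens90_test))
  if (!is.null(x$comparison)) {
    print(x$comparison)
  }
  invisible(x)
}

#' Write a pipeline report bundle
#'
#' Writes, under `dir`: `report.json` (config echo, seed, package version,
#' candidates, saturation table, selected panel, training-CV and test
#' metrics, model comparison, artifact paths), `marker_screen.tsv`,
#' `search_evaluations.tsv` (the full ranked enumeration, mirroring the
#' published top-model table layout), and `model.json`. No timestamps are
#' recorded, so identical runs produce byte-identical bundles.
#'
#' @param pipeline a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return path of `report.json`, invisibly.
#' @export
write_pipeline_report <- function(pipeline, dir) {
  stopifnot(inherits(pipeline, "panel_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  screen_path <- file.path(dir, "marker_screen.tsv")
  write.table(as.data.frame(pipeline$marker_screen), screen_path,
              sep = "\t", row.names = FALSE, quote = FALSE)
  ev_path <- file.path(dir, "search_evaluations.tsv")
  write.table(pipeline$search$evaluations, ev_path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  model_path <- file.path(dir, "model.json")
  write_panel_model(pipeline$model, model_path)
  report <- list(
    schema_version = 1L,
    package_version = pipeline$version,
    config = unclass(pipeline$config),
    candidates = pipeline$candidates,
    k_star = pipeline$search$k_star,
    best_panel = pipeline$search$best_panel,
    saturation = pipeline$search$saturation,
    usage_best = as.list(if (!is.na(pipeline$search$k_star))
      marker_usage(pipeline$search) else NULL),
    test_metrics = list(auc = pipeline$evaluation$auc_test,
                        sens80 = pipeline$evaluation$sens80_test,
                        sens90 = pipeline$evaluation$sens90_test),
    score_bins = as.data.frame(pipeline$evaluation$score_bins),
    comparison = if (!is.null(pipeline$comparison))
      pipeline$comparison$table else NULL,
    artifacts = list(marker_screen = basename(screen_path),
                     search_evaluations = basename(ev_path),
                     model = basename(model_path)))
  report_path <- file.path(dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report_path)
}
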