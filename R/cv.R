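#' Stratified fold assignment for cross-validation
#'
#' Partitions samples into `k` folds, stratified by label so that fold
#' sizes within each class differ by at most one. Deterministic given the
#' seed; the caller's RNG state is untouched.
#'
#' @param labels per-sample class labels (any vector; stratification is by
#'   distinct value).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return object of class `fold_assignment`: `fold` (integer in 1..k per
#'   sample), `k`, `seed`.
#' @examples
#' f <- make_folds(rep(c(TRUE, FALSE), c(10, 10)), k = 5, seed = 1)
#' table(f$fold, rep(c(TRUE, FALSE), c(10, 10)))
#' @export
make_folds <- function(labels, k = 5, seed) {
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k != round(k)) {
    stop("'k' must be an integer >= 2", call. = FALSE)
  }
  n <- length(labels)
  cls <- split(seq_len(n), labels)
  small <- names(cls)[vapply(cls, length, integer(1)) < k]
  if (length(small)) {
    stop("class(es) smaller than k = ", k, ": ",
         paste(small, collapse = ", "),
         "; reduce the number of folds", call. = FALSE)
  }
  fold <- integer(n)
  with_seed(seed, {
    for (idx in cls) {
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(list(fold = fold, k = as.integer(k), seed = seed,
                 stratified_by = labels), class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("Stratified %d-fold assignment of %d samples (seed %s)\n",
              x$k, length(x$fold), format(x$seed)))
  print(table(fold = x$fold, label = x$stratified_by))
  invisible(x)
}

# Shared backend: pooled out-of-fold score matrix for a list of marker
# subsets under one fold assignment.
cv_scores_matrix <- function(table, candidates, subsets_idx, folds,
                             ridge = 1e-6, max_iter = 100, tol = 1e-8) {
  check_markers_present(table, candidates)
  y <- as_case_labels(table$group)
  if (length(folds$fold) != nrow(table)) {
    stop("fold assignment does not cover the table", call. = FALSE)
  }
  X <- as.matrix(table[, candidates, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing values in marker columns", call. = FALSE)
  cv_pool_scores_cpp(X, as.numeric(y), as.integer(folds$fold - 1L), folds$k,
                     lapply(subsets_idx, function(s) as.integer(s - 1L)),
                     ridge, max_iter, tol)
}

#' Cross-validated evaluation of one marker subset
#'
#' For each fold, fits a ridge logistic model on the remaining folds
#' (standardisation learned on the training folds and frozen) and scores
#' the held-out fold; every sample is scored exactly once, by the model not
#' trained on it. Metrics are computed on the pooled out-of-fold scores by
#' default; `pooled = FALSE` instead averages per-fold metrics.
#'
#' @param table sample table with a `group` column.
#' @param markers marker subset to evaluate.
#' @param folds a [make_folds()] assignment covering the table.
#' @param ridge ridge penalty.
#' @param pooled pool out-of-fold scores (default) or average per-fold
#'   metrics.
#' @return object of class `panel_cv`: `markers`, `pooled_scores` (named by
#'   sample id when available), `auc_cv`, `sens80`, `sens90`, `folds`.
#' @export
cv_evaluate <- function(table, markers, folds, ridge = 1e-6, pooled = TRUE) {
  stopifnot(inherits(folds, "fold_assignment"))
  scores <- drop(cv_scores_matrix(table, markers, list(seq_along(markers)),
                                  folds, ridge))
  y <- as_case_labels(table$group)
  if ("sample_id" %in% names(table)) names(scores) <- table$sample_id
  if (pooled) {
    auc <- roc_auc(scores, y)
    s80 <- sens_at_spec(scores, y, 0.80)
    s90 <- sens_at_spec(scores, y, 0.90)
  } else {
    per <- vapply(seq_len(folds$k), function(f) {
      i <- folds$fold == f
      c(roc_auc(scores[i], y[i]),
        sens_at_spec(scores[i], y[i], 0.80),
        sens_at_spec(scores[i], y[i], 0.90))
    }, numeric(3))
    auc <- mean(per[1, ]); s80 <- mean(per[2, ]); s90 <- mean(per[3, ])
  }
  structure(list(markers = markers, pooled_scores = scores, auc_cv = auc,
                 sens80 = s80, sens90 = s90, pooled = pooled, folds = folds),
            class = "panel_cv")
}

#' @export
print.panel_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV of {%s}: AUC %.4f, sens@80%% %.4f, sens@90%% %.4f%s\n",
              x$folds$k, paste(x$markers, collapse = ", "),
              x$auc_cv, x$sens80, x$sens90,
              if (x$pooled) "" else " (fold-averaged)"))
  invisible(x)
}
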