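#' Univariate screening of autoantibody markers
#'
#' Screens each marker column of a sample table by a two-sample t-test of
#' cases against pooled controls (benign + normal). Welch's
#' unequal-variance form is the default; `pooled_var = TRUE` gives the
#' classical equal-variance test. A marker is selected when its two-sided
#' p-value falls below `alpha_select` *and* its case mean exceeds its
#' control mean (autoantibody signal is one-directional: elevated in
#' cancer). Optionally, a cross-validated single-marker logistic AUC is
#' reported per marker as a diagnostic.
#'
#' Markers with zero variance in both groups carry no information and are
#' reported with `t_stat = 0`, `p_value = 1`, flagged `degenerate`.
#'
#' @param table sample table with a `group` column; all rows passed in are
#'   used (subset to the training split upstream).
#' @param alpha_select selection threshold on the two-sided p-value
#'   (default 0.001).
#' @param pooled_var use the pooled-variance t-test instead of Welch.
#' @param folds optional [make_folds()] assignment; when supplied, the
#'   column `cv_auc_univ` holds each marker's pooled out-of-fold
#'   single-marker logistic AUC.
#' @param ridge ridge used for the optional univariate CV fits.
#' @return data frame of class `marker_screen`, ordered by p-value
#'   ascending: `marker`, `mean_case`, `mean_control`, `t_stat`, `df`,
#'   `p_value`, `cv_auc_univ`, `degenerate`, `selected`.
#' @export
t_screen <- function(table, alpha_select = 0.001, pooled_var = FALSE,
                     folds = NULL, ridge = 1e-6) {
  if (!is.numeric(alpha_select) || alpha_select <= 0 || alpha_select >= 1) {
    stop("'alpha_select' must be in (0,1)", call. = FALSE)
  }
  markers <- marker_columns(table)
  if (!length(markers)) stop("no marker columns in 'table'", call. = FALSE)
  y <- as_case_labels(table$group)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 < 2L || n0 < 2L) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  X <- as.matrix(table[, markers, drop = FALSE])
  m1 <- colMeans(X[y, , drop = FALSE])
  m0 <- colMeans(X[!y, , drop = FALSE])
  v1 <- apply(X[y, , drop = FALSE], 2, stats::var)
  v0 <- apply(X[!y, , drop = FALSE], 2, stats::var)
  if (pooled_var) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, length(markers))
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  degenerate <- se == 0
  t_stat <- ifelse(degenerate, 0, (m1 - m0) / se)
  p <- ifelse(degenerate, 1, 2 * pt(abs(t_stat), df, lower.tail = FALSE))
  cv_auc <- rep(NA_real_, length(markers))
  if (!is.null(folds)) {
    for (i in seq_along(markers)) {
      cv_auc[i] <- cv_evaluate(table, markers[i], folds, ridge = ridge)$auc_cv
    }
  }
  out <- data.frame(marker = markers, mean_case = m1, mean_control = m0,
                    t_stat = t_stat, df = df, p_value = p,
                    cv_auc_univ = cv_auc, degenerate = degenerate,
                    selected = !degenerate & p < alpha_select & m1 > m0,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$marker), ]
  rownames(out) <- NULL
  attr(out, "alpha_select") <- alpha_select
  class(out) <- c("marker_screen", class(out))
  out
}

#' @export
print.marker_screen <- function(x, ...) {
  cat(sprintf("Marker screen: %d of %d markers selected (p < %g, case > control)\n",
              sum(x$selected), nrow(x), attr(x, "alpha_select")))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

#' Cross-validated AUC of a single-marker logistic model
#'
#' Fits a one-marker logistic model per training fold and pools the
#' held-out scores; returns the AUC of the pooled scores.
#'
#' @param table sample table with a `group` column.
#' @param marker marker column name.
#' @param folds a [make_folds()] assignment, or an integer fold count `k`
#'   (then `seed` is required to build a stratified assignment).
#' @param seed seed used when `folds` is a count.
#' @param ridge ridge penalty for the fold fits.
#' @return the pooled out-of-fold AUC.
#' @export
univariate_cv <- function(table, marker, folds = 5, seed = NULL,
                          ridge = 1e-6) {
  check_markers_present(table, marker)
  if (!inherits(folds, "fold_assignment")) {
    if (is.null(seed)) {
      stop("supply 'seed' when 'folds' is a fold count", call. = FALSE)
    }
    folds <- make_folds(as_case_labels(table$group), k = folds, seed = seed)
  }
  cv_evaluate(table, marker, folds, ridge = ridge)$auc_cv
}
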