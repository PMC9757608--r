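#' Validate a frozen panel model on an independent test set
#'
#' Scores the test samples with a model fitted on the training split —
#' coefficients *and* standardisation frozen — and reports test-set AUC,
#' sensitivity at 80% and 90% specificity, and the prediction-score bin
#' counts per group with the boundary at 0.4 (bins `[0, 0.4)` and
#' `[0.4, 1]`, left-closed). Any overlap between the model's training
#' sample ids and the test sample ids is an error (leakage guard) unless
#' resubstitution is explicitly allowed, in which case the report is
#' flagged.
#'
#' @param model a [fit_logistic()] model.
#' @param test_table sample table to score.
#' @param boundary score-bin boundary (default 0.4).
#' @param allow_resubstitution permit scoring samples the model was trained
#'   on; the report is then flagged `resubstitution`.
#' @return object of class `panel_eval`: `markers`, `auc_test`,
#'   `sens80_test`, `sens90_test`, `score_bins` (group x bin counts),
#'   `scores`, `labels`, `boundary`, `resubstitution`.
#' @export
validate_panel <- function(model, test_table, boundary = 0.4,
                           allow_resubstitution = FALSE) {
  stopifnot(inherits(model, "panel_model"))
  if (!is.numeric(boundary) || boundary <= 0 || boundary >= 1) {
    stop("'boundary' must be in (0,1)", call. = FALSE)
  }
  resub <- FALSE
  if (!is.null(model$train_ids) && "sample_id" %in% names(test_table)) {
    overlap <- intersect(model$train_ids, test_table$sample_id)
    if (length(overlap)) {
      if (!allow_resubstitution) {
        stop("training/test leakage: ", length(overlap),
             " sample id(s) appear in both sets (e.g. ", overlap[1],
             "); pass allow_resubstitution = TRUE only for a deliberate ",
             "resubstitution estimate", call. = FALSE)
      }
      resub <- TRUE
    }
  }
  scores <- predict(model, test_table)
  y <- as_case_labels(test_table$group)
  bins <- rbind(
    control = c(sum(scores[!y] < boundary), sum(scores[!y] >= boundary)),
    tumor = c(sum(scores[y] < boundary), sum(scores[y] >= boundary)))
  colnames(bins) <- c(sprintf("[0,%g)", boundary), sprintf("[%g,1]", boundary))
  structure(list(
    markers = model$markers,
    auc_test = roc_auc(scores, y),
    sens80_test = sens_at_spec(scores, y, 0.80),
    sens90_test = sens_at_spec(scores, y, 0.90),
    score_bins = bins,
    scores = scores, labels = y, boundary = boundary,
    resubstitution = resub
  ), class = "panel_eval")
}

#' @export
print.panel_eval <- function(x, ...) {
  cat(sprintf("Test-set validation of %d-marker panel%s\n", length(x$markers),
              if (x$resubstitution) " [RESUBSTITUTION]" else ""))
  cat(sprintf("  AUC %.4f | sens@80%% spec %.4f | sens@90%% spec %.4f\n",
              x$auc_test, x$sens80_test, x$sens90_test))
  cat("  prediction-score bins:\n")
  print(x$score_bins)
  invisible(x)
}

#' @export
plot.panel_eval <- function(x, breaks = seq(0, 1, by = 0.05), ...) {
  h1 <- hist(x$scores[x$labels], breaks = breaks, plot = FALSE)
  h0 <- hist(x$scores[!x$labels], breaks = breaks, plot = FALSE)
  ylim <- c(0, max(h1$counts, h0$counts))
  plot(h0, col = grDevices::adjustcolor(4, 0.5), ylim = ylim,
       main = "Prediction-score distribution", xlab = "prediction score", ...)
  plot(h1, col = grDevices::adjustcolor(2, 0.5), add = TRUE)
  abline(v = x$boundary, lty = 2)
  legend("top", c("control", "tumor"), bty = "n",
         fill = grDevices::adjustcolor(c(4, 2), 0.5))
  invisible(x)
}

#' Principal-component projection of a marker block
#'
#' Z-scores the marker columns and eigen-decomposes their correlation
#' matrix (markers are on arbitrary fluorescence scales, so the
#' correlation, not covariance, matrix is the meaningful structure).
#' Samples are projected on the top two components. Sign convention: each
#' loading vector's largest-magnitude entry is positive.
#'
#' @param table sample table (>= 3 rows).
#' @param markers marker columns (>= 2).
#' @return object of class `panel_pca`: `scores` (n x 2, PC1/PC2),
#'   `loadings` (markers x 2), `explained` (all explained-variance
#'   fractions, non-increasing), and `group` when present in `table`.
#' @export
pca_projection <- function(table, markers) {
  check_markers_present(table, markers)
  if (nrow(table) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (length(markers) < 2L) stop("need at least 2 markers", call. = FALSE)
  X <- as.matrix(table[, markers, drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant marker(s) (zero variance): ",
         paste(markers[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  flip <- vapply(1:2, function(j) {
    v <- pc$rotation[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x[, 1:2, drop = FALSE], 2, flip, "*")
  loadings <- sweep(pc$rotation[, 1:2, drop = FALSE], 2, flip, "*")
  colnames(scores) <- colnames(loadings) <- c("PC1", "PC2")
  structure(list(scores = scores, loadings = loadings,
                 explained = pc$sdev^2 / sum(pc$sdev^2),
                 group = if ("group" %in% names(table)) table$group else NULL),
            class = "panel_pca")
}

#' @export
print.panel_pca <- function(x, ...) {
  cat(sprintf("PCA of %d markers: PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$loadings), 100 * x$explained[1], 100 * x$explained[2]))
  invisible(x)
}

#' @export
plot.panel_pca <- function(x, ...) {
  col <- if (is.null(x$group)) 1 else ifelse(as_case_labels(x$group), 2, 4)
  plot(x$scores[, 1], x$scores[, 2], col = col, pch = 16,
       xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained[1]),
       ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained[2]), ...)
  if (!is.null(x$group)) {
    legend("topright", c("tumor", "control"), col = c(2, 4), pch = 16,
           bty = "n")
  }
  invisible(x)
}

#' Compare autoantibody, serum-marker, and combined panels on a test set
#'
#' Fits three logistic models on the training table — model A on the
#' autoantibody panel, model B on the conventional serum tumor markers,
#' model C on their union — under identical ridge and standardisation
#' conventions, and validates each on the test table via
#' [validate_panel()].
#'
#' @param train,test training and test sample tables.
#' @param panel autoantibody marker names (model A).
#' @param serum_markers serum-marker column names (model B); default: all
#'   `stm_`-prefixed columns of `train`.
#' @param ridge ridge penalty shared by the three fits.
#' @param boundary score-bin boundary passed to [validate_panel()].
#' @return object of class `panel_comparison`: `reports` (named list of
#'   `panel_eval` for A/B/C) and `table` (one row per model with test AUC
#'   and sensitivities).
#' @export
compare_models <- function(train, test, panel, serum_markers = NULL,
                           ridge = 1e-6, boundary = 0.4) {
  if (is.null(serum_markers)) serum_markers <- serum_columns(train)
  if (!length(serum_markers)) {
    stop("no serum-marker columns found (expected prefix '", serum_prefix(),
         "')", call. = FALSE)
  }
  for (tb in list(train = train, test = test)) {
    missing <- setdiff(c(panel, serum_markers), names(tb))
    if (length(missing)) {
      stop("column(s) missing: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  sets <- list(A = panel, B = serum_markers,
               C = union(panel, serum_markers))
  reports <- lapply(sets, function(mk) {
    validate_panel(fit_logistic(train, mk, ridge = ridge), test,
                   boundary = boundary)
  })
  tab <- data.frame(
    model = names(sets),
    n_markers = vapply(sets, length, integer(1)),
    auc_test = vapply(reports, function(r) r$auc_test, numeric(1)),
    sens80_test = vapply(reports, function(r) r$sens80_test, numeric(1)),
    sens90_test = vapply(reports, function(r) r$sens90_test, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(reports = reports, table = tab, sets = sets),
            class = "panel_comparison")
}

#' @export
print.panel_comparison <- function(x, ...) {
  cat("Model comparison on the test set\n")
  cat("  A: autoantibody panel | B: serum tumor markers | C: combined\n")
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.panel_comparison <- function(x, ...) {
  cols <- c(A = 2, B = 4, C = 1)
  first <- TRUE
  for (m in names(x$reports)) {
    rc <- roc_curve(x$reports[[m]]$scores, x$reports[[m]]$labels)
    plot(rc, add = !first, col = cols[[m]],
         main = if (first) "Test-set ROC curves" else NULL)
    first <- FALSE
  }
  legend("bottomright", sprintf("%s (AUC %.3f)", x$table$model,
                                x$table$auc_test),
         col = cols[x$table$model], lty = 1, lwd = 2, bty = "n")
  invisible(x)
}
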