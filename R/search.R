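#' Exhaustive cross-validated search over marker subsets
#'
#' Enumerates every subset of the candidate markers at each requested panel
#' size and evaluates each subset by k-fold cross-validated logistic
#' regression, all under the *same* fold assignment so that performance
#' differences reflect marker content rather than fold noise. Subsets are
#' ranked by pooled out-of-fold AUC (ties broken by sensitivity at 90%
#' specificity, then at 80%, then lexicographically by marker names). The
#' result carries the per-size saturation table, the marker usage
#' frequencies among the top-ranked models, and the selected panel.
#'
#' The enumeration is guarded at 20 candidates (about 184,000 subsets at
#' the worst size); restrict `k_range` or pre-screen candidates beyond
#' that.
#'
#' @param table sample table with a `group` column (training split).
#' @param candidates candidate marker names (<= 20).
#' @param k_range panel sizes to enumerate (default all of
#'   `1:length(candidates)`).
#' @param folds a [make_folds()] assignment covering `table`.
#' @param ridge ridge penalty for every fold fit.
#' @param top_n number of top-ranked models per size used for the usage
#'   frequencies (default 50).
#' @param eps saturation tolerance in AUC/sensitivity units (default
#'   0.0075); see [saturation_analysis()].
#' @param pooled pool out-of-fold scores (default) or average per-fold
#'   metrics.
#' @return object of class `panel_search` with elements
#'   \describe{
#'     \item{evaluations}{data frame, one row per subset, ranked: `size`,
#'       `markers` (comma-joined), `auc_cv`, `sens80`, `sens90`, `rank`.}
#'     \item{saturation}{per-size maxima of the three metrics.}
#'     \item{k_star}{selected panel size (smallest size beyond which no
#'       metric improves by `eps` or more).}
#'     \item{usage}{list per size: marker usage counts among the `top_n`
#'       best models of that size.}
#'     \item{best_panel}{markers of the top-ranked subset of size `k_star`.}
#'     \item{best_scores}{pooled out-of-fold scores of `best_panel`.}
#'   }
#' @export
exhaustive_search <- function(table, candidates, k_range = NULL, folds,
                              ridge = 1e-6, top_n = 50, eps = 0.0075,
                              pooled = TRUE) {
  m <- length(candidates)
  if (m > 20) {
    stop("exhaustive enumeration supports at most 20 candidates (got ", m,
         "); pre-screen the candidates or restrict 'k_range'", call. = FALSE)
  }
  check_markers_present(table, candidates)
  stopifnot(inherits(folds, "fold_assignment"))
  if (is.null(k_range)) k_range <- seq_len(m)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1) || any(k_range > m)) {
    stop("'k_range' must lie within 1..", m, call. = FALSE)
  }

  subsets <- list(); sizes <- integer(0)
  for (k in k_range) {
    sk <- utils::combn(m, k, simplify = FALSE)
    subsets <- c(subsets, sk)
    sizes <- c(sizes, rep(k, length(sk)))
  }
  scores <- cv_scores_matrix(table, candidates, subsets, folds, ridge)
  y <- as_case_labels(table$group)

  n_sub <- length(subsets)
  auc <- numeric(n_sub); s80 <- numeric(n_sub); s90 <- numeric(n_sub)
  if (pooled) {
    for (s in seq_len(n_sub)) {
      sc <- scores[, s]
      auc[s] <- roc_auc(sc, y)
      s80[s] <- sens_at_spec(sc, y, 0.80)
      s90[s] <- sens_at_spec(sc, y, 0.90)
    }
  } else {
    fold_idx <- lapply(seq_len(folds$k), function(f) folds$fold == f)
    for (s in seq_len(n_sub)) {
      sc <- scores[, s]
      per <- vapply(fold_idx, function(i) {
        c(roc_auc(sc[i], y[i]), sens_at_spec(sc[i], y[i], 0.80),
          sens_at_spec(sc[i], y[i], 0.90))
      }, numeric(3))
      auc[s] <- mean(per[1, ]); s80[s] <- mean(per[2, ]); s90[s] <- mean(per[3, ])
    }
  }

  marker_str <- vapply(subsets, function(s)
    paste(sort(candidates[s]), collapse = ","), character(1))
  ord <- order(-auc, -s90, -s80, marker_str)
  ev <- data.frame(size = sizes, markers = marker_str, auc_cv = auc,
                   sens80 = s80, sens90 = s90,
                   stringsAsFactors = FALSE)[ord, ]
  ev$rank <- seq_len(n_sub)
  rownames(ev) <- NULL

  sat <- data.frame(
    size = k_range,
    max_auc = vapply(k_range, function(k) max(ev$auc_cv[ev$size == k]), numeric(1)),
    max_sens80 = vapply(k_range, function(k) max(ev$sens80[ev$size == k]), numeric(1)),
    max_sens90 = vapply(k_range, function(k) max(ev$sens90[ev$size == k]), numeric(1)))

  usage <- lapply(k_range, function(k) {
    top <- utils::head(ev[ev$size == k, ], top_n)
    counts <- table(unlist(strsplit(top$markers, ",", fixed = TRUE)))
    u <- setNames(rep(0L, m), sort(candidates))
    u[names(counts)] <- as.integer(counts)
    sort(u, decreasing = TRUE)
  })
  names(usage) <- as.character(k_range)

  res <- structure(list(evaluations = ev, saturation = sat, usage = usage,
                        candidates = candidates, k_range = k_range,
                        top_n = top_n, eps = eps, pooled = pooled,
                        folds = folds),
                   class = "panel_search")
  contiguous <- length(k_range) == 1L || all(diff(k_range) == 1L)
  if (contiguous) {
    sa <- saturation_analysis(res, eps = eps)
    res$k_star <- sa$k_star
  } else {
    res$k_star <- NA_integer_
  }
  best_size <- if (is.na(res$k_star)) ev$size[1] else res$k_star
  best_row <- ev[ev$size == best_size, ][1, ]
  res$best_panel <- strsplit(best_row$markers, ",", fixed = TRUE)[[1]]
  best_s <- which(sizes == best_size)[
    which(marker_str[sizes == best_size] == best_row$markers)]
  res$best_scores <- scores[, best_s]
  if ("sample_id" %in% names(table)) names(res$best_scores) <- table$sample_id
  res
}

#' Panel-size saturation analysis
#'
#' Finds the smallest panel size `k*` beyond which cross-validated
#' performance has stopped improving: for every larger evaluated size, the
#' per-size maxima of AUC, sensitivity at 80% specificity and sensitivity
#' at 90% specificity all improve by less than `eps` relative to size `k*`.
#'
#' @param result a [exhaustive_search()] result (its `k_range` must be
#'   contiguous).
#' @param eps improvement tolerance (default 0.0075 in AUC/sensitivity
#'   units; "no longer increases" is necessarily a tolerance judgement).
#'   The tolerance should exceed the one-case resolution of the pooled
#'   sensitivities (`1/n_cases`, about 0.003 at the default design scale);
#'   below that, the rule reacts to single-sample noise in the per-size
#'   maxima rather than to real improvement.
#' @return list with the per-size `table`, the selected `k_star`, and
#'   `eps`.
#' @export
saturation_analysis <- function(result, eps = 0.0075) {
  stopifnot(inherits(result, "panel_search"))
  sat <- result$saturation
  ks <- sat$size
  if (length(ks) > 1L && any(diff(ks) != 1L)) {
    stop("saturation analysis requires a contiguous range of panel sizes",
         call. = FALSE)
  }
  k_star <- ks[length(ks)]
  for (i in seq_along(ks)) {
    later <- seq_along(ks) > i
    if (!any(later)) break
    ok <- all(sat$max_auc[later] - sat$max_auc[i] < eps) &&
      all(sat$max_sens80[later] - sat$max_sens80[i] < eps) &&
      all(sat$max_sens90[later] - sat$max_sens90[i] < eps)
    if (ok) { k_star <- ks[i]; break }
  }
  list(table = sat, k_star = k_star, eps = eps)
}

#' Marker usage frequency among top-ranked models
#'
#' @param result a [exhaustive_search()] result.
#' @param size panel size (default the selected `k_star`).
#' @param top_n kept for documentation symmetry; the counts were computed
#'   with the search's `top_n`.
#' @return named integer vector of usage counts, decreasing.
#' @export
marker_usage <- function(result, size = result$k_star, top_n = result$top_n) {
  stopifnot(inherits(result, "panel_search"))
  key <- as.character(size)
  if (!key %in% names(result$usage)) {
    stop("size ", size, " was not part of the search", call. = FALSE)
  }
  result$usage[[key]]
}

#' @export
print.panel_search <- function(x, ...) {
  cat(sprintf("Exhaustive panel search: %d subsets of %d candidates (sizes %s), %d-fold CV\n",
              nrow(x$evaluations), length(x$candidates),
              paste(range(x$k_range), collapse = "-"), x$folds$k))
  cat(sprintf("Selected panel size k* = %s (eps = %g)\n",
              format(x$k_star), x$eps))
  cat("Best panel:", paste(x$best_panel, collapse = ", "), "\n")
  top <- x$evaluations[x$evaluations$size == (if (is.na(x$k_star)) x$evaluations$size[1] else x$k_star), ]
  cat("Top models at that size:\n")
  print(utils::head(top, 5), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
summary.panel_search <- function(object, ...) {
  print(object)
  cat("\nSaturation table:\n")
  print(object$saturation, digits = 4, row.names = FALSE)
  cat(sprintf("\nMarker usage in top %d models of size %s:\n",
              object$top_n, format(object$k_star)))
  if (!is.na(object$k_star)) print(marker_usage(object))
  invisible(object)
}

#' @export
plot.panel_search <- function(x, ...) {
  sat <- x$saturation
  plot(sat$size, sat$max_auc, type = "b", pch = 16, ylim = c(0, 1),
       xlab = "panel size", ylab = "best cross-validated value",
       main = "Panel-size saturation", ...)
  lines(sat$size, sat$max_sens80, type = "b", pch = 17, col = 2)
  lines(sat$size, sat$max_sens90, type = "b", pch = 15, col = 4)
  if (!is.na(x$k_star)) abline(v = x$k_star, lty = 2, col = "grey40")
  legend("bottomright", c("AUC", "sens @ 80% spec", "sens @ 90% spec"),
         col = c(1, 2, 4), pch = c(16, 17, 15), lty = 1, bty = "n")
  invisible(x)
}
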