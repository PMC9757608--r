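#' Area under the ROC curve (Mann-Whitney form)
#'
#' Computes the AUC as the Mann-Whitney probability: the fraction of
#' (case, control) pairs in which the case scores higher, with ties counted
#' half. Equivalent to the trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric scores, higher meaning more case-like.
#' @param labels case/control labels: logical, 0/1, or group strings
#'   (`"case"` vs `"benign"`/`"normal"`).
#' @return the AUC in \[0,1\].
#' @examples
#' roc_auc(c(0.9, 0.8, 0.8, 0.7), c(1, 1, 0, 0))  # 0.875
#' @export
roc_auc <- function(scores, labels) {
  y <- as_case_labels(labels)
  stopifnot(length(scores) == length(y))
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores)                      # midranks handle ties as 0.5 credit
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity at a fixed specificity
#'
#' Maximum true-positive rate attainable by any threshold `t` (a sample is
#' called positive iff `score >= t`) whose specificity is at least
#' `spec_target`. Thresholds are enumerated at the observed score values
#' plus `+Inf`, so the value is an empirical pooled fraction (step-function
#' ROC, no interpolation).
#'
#' @inheritParams roc_auc
#' @param spec_target required specificity in (0,1), e.g. 0.80 or 0.90.
#' @return the sensitivity in \[0,1\].
#' @examples
#' sens_at_spec(c(0.9, 0.7, 0.6, 0.2, 0.8, 0.5, 0.4, 0.1),
#'              c(1, 1, 1, 1, 0, 0, 0, 0), 0.75)  # 0.75
#' @export
sens_at_spec <- function(scores, labels, spec_target) {
  y <- as_case_labels(labels)
  stopifnot(length(scores) == length(y))
  if (!is.numeric(spec_target) || length(spec_target) != 1L ||
      spec_target <= 0 || spec_target >= 1) {
    stop("'spec_target' must be in (0,1)", call. = FALSE)
  }
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  case_sorted <- sort(scores[y])
  ctrl_sorted <- sort(scores[!y])
  thr <- c(sort(unique(scores)), Inf)
  # counts strictly below each threshold
  ctrl_lt <- findInterval(thr, ctrl_sorted, left.open = TRUE)
  case_lt <- findInterval(thr, case_sorted, left.open = TRUE)
  specificity <- ctrl_lt / n0
  tpr <- (n1 - case_lt) / n1
  max(tpr[specificity >= spec_target])
}

#' Empirical ROC curve
#'
#' Enumerates thresholds at the observed score values (closed on the
#' positive side: positive iff `score >= t`) and returns the step-function
#' ROC from (0,0) to (1,1) with its trapezoidal area.
#'
#' @inheritParams roc_auc
#' @return data frame of class `roc_curve` with columns `threshold`, `fpr`,
#'   `tpr`, and the AUC as attribute `auc`.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_case_labels(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  fpr <- vapply(thr, function(t) mean(scores[!y] >= t), numeric(1))
  tpr <- vapply(thr, function(t) mean(scores[y] >= t), numeric(1))
  out <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  attr(out, "auc") <- auc
  class(out) <- c("roc_curve", class(out))
  out
}

#' @export
plot.roc_curve <- function(x, add = FALSE, col = 1, lwd = 2, ...) {
  if (!add) {
    plot(x$fpr, x$tpr, type = "s", col = col, lwd = lwd,
         xlab = "1 - specificity", ylab = "sensitivity",
         xlim = c(0, 1), ylim = c(0, 1), ...)
    abline(0, 1, lty = 3, col = "grey")
  } else {
    lines(x$fpr, x$tpr, type = "s", col = col, lwd = lwd, ...)
  }
  invisible(x)
}
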