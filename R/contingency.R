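#' One-sided Yates continuity-corrected chi-square test for clone reactivity
#'
#' Tests whether a clone's reactivity rate against cancer sera (`tp / n_pos`)
#' exceeds its rate against healthy sera (`fp / n_neg`). The 2x2 table
#' `[[tp, fp], [n_pos - tp, n_neg - fp]]` is tested with the Yates-corrected
#' chi-square statistic, with the correction term floored at zero
#' (`chi2 = sum(max(|O - E| - 0.5, 0)^2 / E)`) so near-balanced tables are
#' never inflated. The one-sided p-value is half the two-sided 1-df
#' chi-square p when the observed direction is favourable
#' (`tp/n_pos > fp/n_neg`), and `1 - p/2` otherwise.
#'
#' Degenerate tables in which a column margin vanishes (no reactive serum at
#' all, or every serum reactive) carry no directional information and are
#' reported as `chi2 = 0`, `p_one_sided = 0.5`, flagged `degenerate`.
#'
#' @param tp count of reactive cancer sera (vectorised).
#' @param fp count of reactive healthy sera (vectorised).
#' @param n_pos,n_neg serum panel sizes (default 30, recycled).
#' @return data frame with one row per input: `tp`, `fp`, `n_pos`, `n_neg`,
#'   `chi2`, `p_one_sided` (full precision), `direction_ok`, `degenerate`.
#' @examples
#' yates_one_sided(12, 5)          # p ~= 0.043
#' yates_one_sided(c(5, 7), c(0, 7))
#' @export
yates_one_sided <- function(tp, fp, n_pos = 30, n_neg = 30) {
  m <- max(length(tp), length(fp), length(n_pos), length(n_neg))
  tp <- rep_len(tp, m); fp <- rep_len(fp, m)
  n_pos <- rep_len(n_pos, m); n_neg <- rep_len(n_neg, m)
  if (any(n_pos <= 0) || any(n_neg <= 0)) {
    stop("'n_pos' and 'n_neg' must be positive", call. = FALSE)
  }
  if (any(tp < 0) || any(tp > n_pos) || any(fp < 0) || any(fp > n_neg)) {
    stop("counts must satisfy 0 <= tp <= n_pos and 0 <= fp <= n_neg",
         call. = FALSE)
  }
  chi2 <- numeric(m); p1 <- numeric(m)
  dir_ok <- tp / n_pos > fp / n_neg
  degenerate <- (tp + fp == 0) | (tp == n_pos & fp == n_neg)
  for (i in seq_len(m)) {
    if (degenerate[i]) {
      chi2[i] <- 0; p1[i] <- 0.5
      next
    }
    O <- matrix(c(tp[i], n_pos[i] - tp[i], fp[i], n_neg[i] - fp[i]), 2, 2)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    chi2[i] <- sum(pmax(abs(O - E) - 0.5, 0)^2 / E)
    p2 <- pchisq(chi2[i], df = 1, lower.tail = FALSE)
    p1[i] <- if (dir_ok[i]) p2 / 2 else 1 - p2 / 2
  }
  data.frame(tp = tp, fp = fp, n_pos = n_pos, n_neg = n_neg, chi2 = chi2,
             p_one_sided = p1, direction_ok = dir_ok, degenerate = degenerate)
}

#' Screen candidate clones by one-sided Yates-corrected significance
#'
#' Applies [yates_one_sided()] to a table of second-round screening counts
#' and flags the clones whose cancer-serum reactivity is significantly
#' higher than their healthy-serum reactivity at the one-sided level
#' `alpha` (strict inequality `p < alpha`). No multiplicity adjustment is
#' applied by default, matching a uniform per-clone acceptance rule;
#' `adjust = "BH"` enables Benjamini-Hochberg as an extension.
#'
#' @param counts data frame with columns `clone_id`, `tp`, `fp` and
#'   optionally `n_pos`, `n_neg` (default 30/30).
#' @param alpha one-sided significance level in (0,1); default 0.1.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return the input with appended columns `chi2`, `p_one_sided`,
#'   `direction_ok`, `degenerate`, `passed`, of class `clone_screen`;
#'   the pass/fail tally is attached as attribute `summary`.
#' @examples
#' screen_clones(data.frame(clone_id = c("a", "b"), tp = c(12, 3), fp = c(5, 3)))
#' @export
screen_clones <- function(counts, alpha = 0.1, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be in (0,1)", call. = FALSE)
  }
  need <- c("clone_id", "tp", "fp")
  missing <- setdiff(need, names(counts))
  if (length(missing)) {
    stop("'counts' lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(counts) == 0L) {
    warning("empty clone count table; returning empty result")
    out <- cbind(counts, chi2 = numeric(0), p_one_sided = numeric(0),
                 direction_ok = logical(0), degenerate = logical(0),
                 passed = logical(0))
    class(out) <- c("clone_screen", class(out))
    return(out)
  }
  if (anyDuplicated(counts$clone_id)) {
    stop("duplicate clone_id: ",
         paste(unique(counts$clone_id[duplicated(counts$clone_id)]),
               collapse = ", "), call. = FALSE)
  }
  n_pos <- if ("n_pos" %in% names(counts)) counts$n_pos else 30
  n_neg <- if ("n_neg" %in% names(counts)) counts$n_neg else 30
  res <- yates_one_sided(counts$tp, counts$fp, n_pos, n_neg)
  p_eff <- if (adjust == "BH") stats::p.adjust(res$p_one_sided, "BH") else res$p_one_sided
  out <- data.frame(clone_id = counts$clone_id, res,
                    passed = res$direction_ok & p_eff < alpha,
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- c(passed = sum(out$passed),
                            failed = sum(!out$passed))
  attr(out, "alpha") <- alpha
  class(out) <- c("clone_screen", class(out))
  out
}

#' @export
print.clone_screen <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("Clone screen (one-sided Yates chi-square, alpha = %g): %d passed, %d failed of %d\n",
              attr(x, "alpha"), s[["passed"]], s[["failed"]], nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Reference second-round clone screening counts
#'
#' The reactivity counts of the 36 clones retained by the second round of a
#' serological expression-library screen: for each clone, the number of
#' reactive sera among 30 early-stage NSCLC sera (`tp`) and among 30
#' healthy sera (`fp`). All 36 clones pass [screen_clones()] at the
#' one-sided 0.1 level.
#'
#' @return data frame with columns `clone_id`, `tp`, `fp`, `n_pos`, `n_neg`.
#' @examples
#' head(clone_screen_counts())
#' @export
clone_screen_counts <- function() {
  path <- system.file("extdata", "second_round_clone_counts.tsv",
                      package = "abpanel", mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
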