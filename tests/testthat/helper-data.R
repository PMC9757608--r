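# Small simulated tables shared across tests. Kept deliberately small so
# the whole suite stays fast; full-scale behaviour is covered by the
# acceptance tests.

small_config <- function(seed = 42, ...) {
  panel_sim_config(n_case_train = 40, n_benign_train = 20,
                   n_normal_train = 20, n_case_test = 25, n_benign_test = 25,
                   n_markers = 10, n_informative = 4, panel_true = 1:3,
                   seed = seed, ...)
}

small_sim <- function(seed = 42, ...) simulate_panel_data(small_config(seed, ...))

# Brute-force AUC: enumerate all (case, control) pairs, ties get half credit.
auc_bruteforce <- function(scores, y) {
  cs <- scores[y]; ct <- scores[!y]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# Brute-force sensitivity at specificity: try every observed score and +Inf
# as threshold (positive iff score >= t).
sens_bruteforce <- function(scores, y, target) {
  best <- 0
  for (t in c(scores, Inf)) {
    spec <- mean(scores[!y] < t)
    if (spec >= target) best <- max(best, mean(scores[y] >= t))
  }
  best
}

# Textbook Welch t statistic.
welch_oracle <- function(x, y) {
  se <- sqrt(var(x) / length(x) + var(y) / length(y))
  t <- (mean(x) - mean(y)) / se
  df <- se^4 / ((var(x) / length(x))^2 / (length(x) - 1) +
                  (var(y) / length(y))^2 / (length(y) - 1))
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}
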