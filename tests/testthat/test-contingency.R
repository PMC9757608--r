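test_that("one-sided Yates p-values reproduce the reference screening table", {
  # rows of the second-round screen whose full-precision p rounds cleanly
  # to the printed 3-dp value
  cases <- rbind(
    c(12, 5, 0.043), c(5, 0, 0.031), c(4, 0, 0.060), c(8, 1, 0.015),
    c(13, 5, 0.024), c(11, 3, 0.016), c(9, 3, 0.053), c(8, 3, 0.091),
    c(7, 2, 0.074), c(5, 1, 0.098), c(10, 3, 0.030), c(6, 1, 0.054),
    c(8, 2, 0.042))
  res <- yates_one_sided(cases[, 1], cases[, 2], 30, 30)
  expect_equal(round(res$p_one_sided, 3), cases[, 3])
  expect_true(all(res$direction_ok))
})

test_that("symmetric tables yield chi2 = 0 and p = 0.5; direction gates the tail", {
  r <- yates_one_sided(7, 7)
  expect_equal(r$chi2, 0)
  expect_equal(r$p_one_sided, 0.5)
  expect_false(r$direction_ok)
  # unfavourable direction: one-sided p is 1 - p_two/2, always >= 0.5
  r2 <- yates_one_sided(0, 10)
  expect_false(r2$direction_ok)
  expect_gt(r2$p_one_sided, 0.9)
  # degenerate margins
  r3 <- yates_one_sided(c(0, 30), c(0, 30))
  expect_true(all(r3$degenerate))
  expect_equal(r3$p_one_sided, c(0.5, 0.5))
})

test_that("chi2 and p agree with independent oracles over the full 31x31 grid", {
  grid <- expand.grid(tp = 0:30, fp = 0:30)
  res <- yates_one_sided(grid$tp, grid$fp, 30, 30)
  for (i in seq_len(nrow(grid))) {
    tp <- grid$tp[i]; fp <- grid$fp[i]
    if (res$degenerate[i]) next
    O <- matrix(c(tp, 30 - tp, fp, 30 - fp), 2, 2)
    # brute-force four-cell summation
    E <- outer(rowSums(O), colSums(O)) / 60
    chi_manual <- 0
    for (r in 1:2) for (cc in 1:2) {
      chi_manual <- chi_manual + max(abs(O[r, cc] - E[r, cc]) - 0.5, 0)^2 / E[r, cc]
    }
    expect_equal(res$chi2[i], chi_manual, tolerance = 1e-12)
    # stats::chisq.test applies the identical min(|O-E|, 0.5) correction
    p_ref <- suppressWarnings(chisq.test(O, correct = TRUE)$p.value)
    expect_equal(pchisq(res$chi2[i], 1, lower.tail = FALSE), p_ref,
                 tolerance = 1e-12)
    # one-tailed normal tail of the signed root statistic
    z <- sqrt(res$chi2[i]) * if (tp / 30 > fp / 30) 1 else -1
    expect_equal(res$p_one_sided[i], pnorm(z, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("p is monotone in tp at fixed fp, and swaps under tp<->fp exchange", {
  for (fp in c(0, 3, 8)) {
    tps <- (fp + 1):30   # direction_ok region at equal panel sizes
    p <- yates_one_sided(tps, rep(fp, length(tps)))$p_one_sided
    expect_true(all(diff(p) <= 1e-12))
  }
  # symmetry away from the floored-correction region
  for (pair in list(c(12, 5), c(20, 2), c(9, 3))) {
    p_ab <- yates_one_sided(pair[1], pair[2])$p_one_sided
    p_ba <- yates_one_sided(pair[2], pair[1])$p_one_sided
    expect_equal(p_ab, 1 - p_ba, tolerance = 1e-12)
  }
})

test_that("screen_clones passes all 36 reference clones and enforces its contracts", {
  counts <- clone_screen_counts()
  expect_equal(nrow(counts), 36L)
  res <- screen_clones(counts, alpha = 0.1)
  expect_true(all(res$passed))
  expect_equal(res$clone_id, counts$clone_id)  # input order preserved
  # symmetric and wrong-direction tables fail
  res2 <- screen_clones(data.frame(clone_id = c("x", "y"),
                                   tp = c(3, 0), fp = c(3, 10)))
  expect_false(any(res2$passed))
  expect_false(res2$direction_ok[2])
  # duplicates are an error; empty input warns
  expect_error(screen_clones(data.frame(clone_id = c("a", "a"),
                                        tp = c(1, 2), fp = c(0, 0))),
               "duplicate")
  expect_warning(screen_clones(data.frame(clone_id = character(0),
                                          tp = integer(0), fp = integer(0))),
                 "empty")
})

test_that("the screen controls its type-I error under the null generator", {
  g <- simulate_screen_counts(4000, 0, tp_rate_true = 0.15, bg_rate = 0.15,
                              seed = 99)
  expect_false(any(g$is_true))
  res <- screen_clones(g$counts, alpha = 0.1)
  # Yates correction makes the test conservative: pass rate stays below alpha
  expect_lte(mean(res$passed), 0.1)
})
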