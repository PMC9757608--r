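test_that("Welch t equals the textbook formula and stats::t.test on small vectors", {
  set.seed(2)
  for (i in 1:20) {
    n1 <- sample(3:10, 1); n0 <- sample(3:10, 1)
    x <- rnorm(n1, 1, 2); z <- rnorm(n0)
    tb <- data.frame(group = c(rep("case", n1), rep("normal", n0)),
                     m = exp(c(x, z)))  # positive scale, screened on raw values
    tb$m <- c(x, z)
    sc <- t_screen(tb, alpha_select = 0.05)
    o <- welch_oracle(x, z)
    expect_equal(sc$t_stat, o$t, tolerance = 1e-10)
    expect_equal(sc$p_value, o$p, tolerance = 1e-10)
    ref <- t.test(x, z)
    expect_equal(sc$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("selection requires both significance and the case > control direction", {
  set.seed(6)
  n <- 100
  up <- c(rnorm(n, 5), rnorm(n, 0))     # elevated in cases: selected
  down <- c(rnorm(n, 0), rnorm(n, 5))   # elevated in controls: rejected
  null <- rnorm(2 * n)
  tb <- data.frame(group = rep(c("case", "normal"), each = n),
                   m_up = up, m_down = down, m_null = null)
  sc <- t_screen(tb, alpha_select = 0.001)
  sel <- setNames(sc$selected, sc$marker)
  expect_true(sel[["m_up"]])
  expect_false(sel[["m_down"]])
  expect_false(sel[["m_null"]])
  expect_equal(sc$marker[1], "m_up")  # ordered by p ascending
})

test_that("identical case/control values give t = 0, p = 1, degenerate flag", {
  tb <- data.frame(group = rep(c("case", "normal"), each = 10),
                   m = rep(3, 20), m2 = c(rnorm(10, 2), rnorm(10)))
  sc <- t_screen(tb, alpha_select = 0.05)
  row <- sc[sc$marker == "m", ]
  expect_equal(row$t_stat, 0)
  expect_equal(row$p_value, 1)
  expect_true(row$degenerate)
  expect_false(row$selected)
})

test_that("all planted core markers are selected on default-scale synthetic data", {
  hits <- 0
  for (s in 1:5) {
    sim <- simulate_panel_data(panel_sim_config(seed = 200 + s))
    train <- sim$table[sim$table$split == "train", ]
    sc <- t_screen(train, alpha_select = 0.001)
    hits <- hits + all(sim$truth$panel_true %in% sc$marker[sc$selected])
  }
  expect_gte(hits, 5)
})

test_that("permuting labels on null data yields the nominal false-selection rate", {
  sim <- simulate_panel_data(panel_sim_config(
    n_case_train = 150, n_benign_train = 75, n_normal_train = 75,
    n_case_test = 20, n_benign_test = 20, effect_log = 0,
    effect_log_weak = 0, seed = 55))
  train <- sim$table[sim$table$split == "train", ]
  alpha <- 0.05
  false_sel <- 0; total <- 0
  set.seed(56)
  for (r in 1:10) {
    train$group <- sample(train$group)
    sc <- t_screen(train, alpha_select = alpha)
    # direction requirement halves the two-sided rate
    false_sel <- false_sel + sum(sc$p_value < alpha)
    total <- total + nrow(sc)
  }
  expect_lt(abs(false_sel / total - alpha), 3 * sqrt(alpha / total))
})

test_that("univariate CV AUC behaves at the extremes and under monotone transforms", {
  sim <- small_sim(seed = 13)
  train <- sim$table[sim$table$split == "train", ]
  f <- make_folds(train$group == "case", k = 5, seed = 13)
  # perfectly separated synthetic marker
  train$perfect <- ifelse(train$group == "case",
                          100 + seq_len(nrow(train)), seq_len(nrow(train)))
  expect_equal(univariate_cv(train, "perfect", f), 1.0)
  # a monotone transform of the pooled scores leaves the AUC unchanged
  cvr <- cv_evaluate(train, marker_columns(train)[1], f)
  expect_equal(roc_auc(cvr$pooled_scores, train$group),
               roc_auc(plogis(qlogis(cvr$pooled_scores) * 2 + 1), train$group),
               tolerance = 1e-12)
  expect_equal(cvr$auc_cv, roc_auc(cvr$pooled_scores, train$group))
})

test_that("a label-independent marker scores near AUC 0.5 under CV", {
  aucs <- numeric(10)
  for (s in 1:10) {
    set.seed(400 + s)
    n <- 2000
    tb <- data.frame(group = rep(c("case", "normal"), each = n / 2),
                     m = exp(rnorm(n)))
    f <- make_folds(tb$group == "case", k = 5, seed = 400 + s)
    aucs[s] <- univariate_cv(tb, "m", f)
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.015)
  expect_lt(max(abs(aucs - 0.5)), 0.05)
})
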