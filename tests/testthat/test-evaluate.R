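test_that("the leakage guard refuses overlapping train/test identifiers", {
  sim <- small_sim(seed = 47)
  train <- sim$table[sim$table$split == "train", ]
  test <- sim$table[sim$table$split == "test", ]
  fit <- fit_logistic(train, marker_columns(train)[1:3])
  expect_error(validate_panel(fit, train), "leakage")
  # deliberate resubstitution is permitted but flagged
  ev <- validate_panel(fit, train, allow_resubstitution = TRUE)
  expect_true(ev$resubstitution)
  ev2 <- validate_panel(fit, test)
  expect_false(ev2$resubstitution)
})

test_that("score bins partition each group at the 0.4 boundary", {
  sim <- small_sim(seed = 53)
  train <- sim$table[sim$table$split == "train", ]
  test <- sim$table[sim$table$split == "test", ]
  fit <- fit_logistic(train, marker_columns(train)[1:3])
  ev <- validate_panel(fit, test)
  y <- test$group == "case"
  expect_equal(sum(ev$score_bins["tumor", ]), sum(y))
  expect_equal(sum(ev$score_bins["control", ]), sum(!y))
  expect_equal(unname(ev$score_bins["tumor", 1]),
               sum(ev$scores[y] < 0.4))
})

test_that("a zero-coefficient model scores everything 0.5 with AUC exactly 0.5", {
  tb <- data.frame(sample_id = sprintf("t%02d", 1:40),
                   group = rep(c("case", "normal"), each = 20),
                   split = "test", m = rep(1.7, 40))
  fit_tb <- data.frame(sample_id = sprintf("r%02d", 1:40), tb[-1])
  fit <- fit_logistic(fit_tb, "m")
  ev <- validate_panel(fit, tb)
  expect_equal(ev$auc_test, 0.5)        # midrank tie rule
  expect_true(all(ev$score_bins[, 2] %in% c(20)))  # all scores ~0.5 in [0.4,1]
})

test_that("test AUC tracks the training CV AUC on fresh data (no overfitting)", {
  diffs <- numeric(5)
  for (s in 1:5) {
    sim <- simulate_panel_data(panel_sim_config(
      n_case_train = 150, n_benign_train = 75, n_normal_train = 75,
      n_case_test = 120, n_benign_test = 120, seed = 500 + s))
    train <- sim$table[sim$table$split == "train", ]
    test <- sim$table[sim$table$split == "test", ]
    f <- make_folds(train$group == "case", 5, seed = 500 + s)
    cvr <- cv_evaluate(train, sim$truth$panel_true, f)
    fit <- fit_logistic(train, sim$truth$panel_true)
    ev <- validate_panel(fit, test)
    diffs[s] <- ev$auc_test - cvr$auc_cv
  }
  expect_lt(max(abs(diffs)), 0.05)
})

test_that("PCA of two correlated markers has the closed-form leading structure", {
  set.seed(59)
  n <- 20000
  rho <- 0.6
  z <- matrix(rnorm(2 * n), n, 2)
  x <- cbind(z[, 1], rho * z[, 1] + sqrt(1 - rho^2) * z[, 2])
  tb <- data.frame(a = x[, 1], b = x[, 2])
  p <- pca_projection(tb, c("a", "b"))
  expect_equal(unname(p$loadings[, "PC1"]), c(1, 1) / sqrt(2), tolerance = 0.02)
  expect_equal(p$explained[1], (1 + rho) / 2, tolerance = 0.02)
  # loadings orthonormal
  expect_equal(crossprod(p$loadings), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("PCA is invariant to marker column order up to the sign convention", {
  sim <- small_sim(seed = 61)
  train <- sim$table[sim$table$split == "train", ]
  mk <- marker_columns(train)[1:4]
  p1 <- pca_projection(train, mk)
  p2 <- pca_projection(train, rev(mk))
  expect_equal(p1$scores, p2$scores, tolerance = 1e-9)
  expect_equal(p1$explained, p2$explained, tolerance = 1e-12)
  expect_equal(p1$loadings[mk, ], p2$loadings[mk, ], tolerance = 1e-9)
  # isotropic data: explained fractions near equal
  set.seed(62)
  iso <- as.data.frame(matrix(rnorm(4 * 5000), ncol = 4,
                              dimnames = list(NULL, paste0("v", 1:4))))
  pe <- pca_projection(iso, paste0("v", 1:4))$explained
  expect_lt(max(abs(pe - 0.25)), 0.03)
  # constant marker is named in the error
  iso$v4 <- 1
  expect_error(pca_projection(iso, paste0("v", 1:4)), "v4")
})

test_that("model comparison orders and degenerates as the data dictate", {
  sim <- small_sim(seed = 67)
  train <- sim$table[sim$table$split == "train", ]
  test <- sim$table[sim$table$split == "test", ]
  panel <- sim$truth$panel_true
  cmp <- compare_models(train, test, panel)
  expect_named(cmp$reports, c("A", "B", "C"))
  expect_equal(cmp$table$model, c("A", "B", "C"))
  # degenerate overlap: panel == serum markers makes A and B identical
  serum <- serum_columns(train)
  cmp2 <- compare_models(train, test, serum, serum_markers = serum)
  expect_equal(cmp2$reports$A$auc_test, cmp2$reports$B$auc_test)
  expect_equal(cmp2$reports$A$scores, cmp2$reports$B$scores)
  # missing serum columns are listed
  expect_error(compare_models(train, test, panel,
                              serum_markers = c("stm_missing")),
               "stm_missing")
})

test_that("noise serum markers give a near-chance serum model", {
  aucs <- numeric(5)
  for (s in 1:5) {
    sim <- simulate_panel_data(panel_sim_config(
      n_case_train = 200, n_benign_train = 100, n_normal_train = 100,
      n_case_test = 150, n_benign_test = 150, serum_marker_effect = 0,
      seed = 600 + s))
    train <- sim$table[sim$table$split == "train", ]
    test <- sim$table[sim$table$split == "test", ]
    cmp <- compare_models(train, test, sim$truth$panel_true)
    aucs[s] <- cmp$table$auc_test[cmp$table$model == "B"]
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  expect_lt(max(abs(aucs - 0.5)), 0.1)
})
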