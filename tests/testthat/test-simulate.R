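test_that("identical config and seed reproduce the table exactly", {
  a <- small_sim(seed = 5)
  b <- small_sim(seed = 5)
  expect_identical(a$table, b$table)
  expect_identical(a$truth, b$truth)
  c <- small_sim(seed = 6)
  expect_false(identical(a$table, c$table))
})

test_that("the table has the configured layout and strictly positive values", {
  sim <- small_sim()
  tb <- sim$table
  expect_equal(sum(tb$split == "train"), 80)
  expect_equal(sum(tb$split == "test"), 50)
  expect_equal(as.integer(table(tb$group)[c("case", "benign", "normal")]),
               c(65L, 45L, 20L))
  expect_length(marker_columns(tb), 10)
  expect_length(serum_columns(tb), 4)
  expect_true(all(as.matrix(tb[, marker_columns(tb)]) > 0))
  # ground-truth invariants
  pos <- sim$truth$per_sample_positivity
  expect_true(all(pos[tb$group != "case", ] == 0))
  noninf <- setdiff(colnames(pos), sim$truth$informative_markers)
  expect_true(all(pos[, noninf] == 0))
  expect_true(all(sim$truth$panel_true %in% sim$truth$informative_markers))
})

test_that("case positivity rates match the configured rate (binomial bounds)", {
  cfg <- panel_sim_config(n_case_train = 332, n_benign_train = 30,
                          n_normal_train = 30, n_case_test = 163,
                          n_benign_test = 30, seed = 8)
  sim <- simulate_panel_data(cfg)
  pos <- sim$truth$per_sample_positivity
  cases <- sim$table$group == "case"
  n <- sum(cases)
  se <- sqrt(0.35 * 0.65 / n)
  for (mk in sim$truth$panel_true) {
    expect_lt(abs(mean(pos[cases, mk]) - 0.35), 3 * se)
  }
})

test_that("a null generator (no effects) produces no spurious group signal", {
  cfg <- panel_sim_config(n_case_train = 100, n_benign_train = 50,
                          n_normal_train = 50, n_case_test = 20,
                          n_benign_test = 20, n_markers = 20,
                          effect_log = 0, effect_log_weak = 0,
                          serum_marker_effect = 0, seed = 31)
  # p-values approximately uniform: rejection rate at 0.05 near nominal,
  # pooled over markers and replicates
  reject <- 0; total <- 0
  for (s in 1:5) {
    cfg$seed <- 30 + s
    sim <- simulate_panel_data(cfg)
    train <- sim$table[sim$table$split == "train", ]
    sc <- t_screen(train, alpha_select = 0.001)
    reject <- reject + sum(sc$p_value < 0.05)
    total <- total + nrow(sc)
  }
  rate <- reject / total  # 100 marker-tests
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / total))
})

test_that("screen-count generator honours its contracts", {
  # n_true = 0: all flags false
  g0 <- simulate_screen_counts(50, 0, tp_rate_true = 0.9, bg_rate = 0.1,
                               seed = 1)
  expect_false(any(g0$is_true))
  # forced extreme: certain reactivity, zero background
  g1 <- simulate_screen_counts(20, 20, tp_rate_true = 1, bg_rate = 0,
                               seed = 2)
  expect_true(all(g1$counts$tp == 30))
  expect_true(all(g1$counts$fp == 0))
  expect_true(all(screen_clones(g1$counts)$passed))
  # determinism
  expect_identical(simulate_screen_counts(30, 10, tp_rate_true = 0.4,
                                          bg_rate = 0.1, seed = 9),
                   simulate_screen_counts(30, 10, tp_rate_true = 0.4,
                                          bg_rate = 0.1, seed = 9))
  # invalid rates
  expect_error(simulate_screen_counts(10, 5, tp_rate_true = 1.2,
                                      bg_rate = 0.1), "tp_rate_true")
})

test_that("invalid generator configurations name the offending field", {
  expect_error(panel_sim_config(n_markers = 0), "n_markers")
  expect_error(panel_sim_config(n_informative = 40), "n_informative")
  expect_error(panel_sim_config(positivity_rate = 1.5), "positivity_rate")
  expect_error(panel_sim_config(log_sd = 0), "log_sd")
  expect_error(panel_sim_config(panel_true = c(1, 1, 2)), "panel_true")
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123); before <- .Random.seed
  invisible(small_sim())
  expect_identical(.Random.seed, before)
})
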