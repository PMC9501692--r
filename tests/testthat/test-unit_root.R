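test_that("MacKinnon response-surface p-values match frozen reference points", {
  # reference values computed from an independent implementation of the
  # MacKinnon (1994) surface
  ref <- rbind(
    c(-4.0, 7.326906e-05, 1.410511e-03, 8.793701e-03),
    c(-3.0, 2.663735e-03, 3.489440e-02, 1.320810e-01),
    c(-2.5, 1.200404e-02, 1.154743e-01, 3.279623e-01),
    c(-1.5, 1.252401e-01, 5.335113e-01, 8.291323e-01),
    c(-0.5, 4.961240e-01, 8.920165e-01, 9.834338e-01),
    c(0.5, 8.248792e-01, 9.848731e-01, 9.968519e-01))
  specs <- c("none", "intercept", "trend_intercept")
  for (i in seq_len(nrow(ref))) {
    for (j in 1:3) {
      expect_equal(mackinnon_pvalue(ref[i, 1], specs[j]), ref[i, j + 1],
                   tolerance = 1e-6)
    }
  }
})

test_that("ADF with zero max lag equals the DF statistic", {
  x <- quick_panel(seed = 8)$lgdp
  for (sp in c("intercept", "trend_intercept")) {
    a <- adf_test(x, sp, max_lag = 0)
    d <- df_test(x, sp)
    expect_lt(abs(a$statistic - d$statistic), 1e-12)
    expect_equal(d$test, "DF")
  }
})

test_that("ADF and PP statistics are invariant to location/scale under an intercept", {
  x <- quick_panel(seed = 9, T = 50)$lgdp
  for (f in list(adf_test, pp_test)) {
    s0 <- f(x, "intercept")$statistic
    expect_lt(abs(f(x + 100, "intercept")$statistic - s0), 1e-8)
    expect_lt(abs(f(x * 3, "intercept")$statistic - s0), 1e-8)
  }
})

test_that("ADF keeps size and shows power in Monte Carlo", {
  set.seed(31)
  n_mc <- 200
  p_null <- p_alt <- numeric(n_mc)
  for (i in seq_len(n_mc)) {
    rw <- cumsum(rnorm(200))
    p_null[i] <- adf_test(rw, "intercept")$p_value
    ar <- as.numeric(arima.sim(list(ar = 0.3), 200))
    p_alt[i] <- adf_test(ar, "intercept")$p_value
  }
  expect_gte(mean(p_null > 0.10), 0.90)
  expect_gte(mean(p_alt < 0.05), 0.90)
  # empirical size at nominal 5%, driftless random walks, T = 100
  rej <- mean(replicate(500, adf_test(cumsum(rnorm(100)),
                                      "intercept")$p_value < 0.05))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.09)
})

test_that("PP rejects white noise and tolerates a drifting random walk", {
  set.seed(37)
  rej_wn <- mean(replicate(200, pp_test(rnorm(500), "intercept")$p_value < 0.01))
  expect_gte(rej_wn, 0.95)
  keep_rw <- mean(replicate(200, {
    pp_test(cumsum(rnorm(200, mean = 0.05)), "trend_intercept")$p_value > 0.05
  }))
  expect_gte(keep_rw, 0.85)
})

test_that("integration classification follows the I(0)/I(1) rule", {
  r <- function(p) structure(list(p_value = p), class = "unit_root_result")
  expect_equal(classify_integration(list(r(0.5), r(0.03)), list(r(0.5)))$order,
               "I0")
  expect_equal(classify_integration(list(r(0.5), r(0.4)), list(r(0.01)))$order,
               "I1")
  expect_warning(
    out <- classify_integration(list(r(0.5)), list(r(0.5)), label = "x"),
    "not admissible")
  expect_equal(out$order, "inadmissible")
})

test_that("unit root grid covers the conventional test/spec cells", {
  g <- unit_root_grid(quick_panel(seed = 4))
  # per variable: DF x 2 specs + ADF x 3 + PP x 3
  expect_equal(nrow(g), 3 * 8)
  expect_true(all(g$p_value > 0 & g$p_value < 1))
  expect_match(g$display[1], "^-?\\d+\\.\\d{4}\\**\\s\\(\\d\\)$")
})
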