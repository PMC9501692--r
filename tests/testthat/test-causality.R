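test_that("planted one-period causality is detected with the right sign", {
  set.seed(61)
  T <- 100
  x <- cumsum(rnorm(T, 0, 0.05))
  dy <- c(0, 0.9 * diff(x)[1:(T - 2)]) + rnorm(T - 1, 0, 0.005)
  y <- cumsum(c(8, dy))
  panel <- country_panel("Z", 2000:(2000 + T - 1), y, 6 + x,
                         fardl:::emp_walk(T))
  r <- granger_short_run(panel, effect = "LGDP", cause = "LHEP",
                         control = "EMP", lag = 1)
  expect_lt(r$p, 0.01)
  expect_equal(r$sign, "+")
  expect_gt(r$F, 50)
})

test_that("the F statistic equals the Wald quadratic form", {
  panel <- quick_panel(seed = 62, T = 40)
  r <- granger_short_run(panel, "LGDP", "LHEP", "EMP", lag = 2, k = 1.5)
  # rebuild the same regression to apply the oracle
  T <- panel_length(panel)
  d <- lapply(panel_variables(), function(v) diff(panel_series(panel, v)))
  names(d) <- panel_variables()
  idx <- 4:T
  X <- cbind(const = 1, fourier_term(T, 1.5)[idx, ])
  for (v in c("LGDP", "LHEP", "EMP")) {
    for (i in 1:2) {
      X <- cbind(X, d[[v]][idx - 1 - i])
      colnames(X)[ncol(X)] <- paste0("d.", v, ".l", i)
    }
  }
  fit <- ols_fit(d$LGDP[idx - 1], X)
  wf <- wald_f_oracle(fit, c("d.LHEP.l1", "d.LHEP.l2"))
  expect_lt(abs(r$F - wf) / wf, 1e-6)
})

test_that("relabeling cause and control with identical series leaves F unchanged", {
  # regressions run in first differences, so exchange the increment
  # series between the LHEP and EMP slots and swap the labels: the
  # design and the excluded columns are then identical by construction
  set.seed(63)
  T <- 30
  inc1 <- rnorm(T - 1, 0, 0.004)
  inc2 <- rnorm(T - 1, 0, 0.004)
  lgdp <- 8 + cumsum(c(0, rnorm(T - 1, 0, 0.03)))
  yrs <- 2000:(2000 + T - 1)
  panelA <- country_panel("A", yrs, lgdp, 6 + cumsum(c(0, inc1)),
                          0.9 + cumsum(c(0, inc2)))
  panelB <- country_panel("B", yrs, lgdp, 6 + cumsum(c(0, inc2)),
                          0.9 + cumsum(c(0, inc1)))
  rA <- granger_short_run(panelA, "LGDP", cause = "LHEP", control = "EMP")
  rB <- granger_short_run(panelB, "LGDP", cause = "EMP", control = "LHEP")
  expect_equal(rA$F, rB$F, tolerance = 1e-10)
  expect_equal(rA$p, rB$p, tolerance = 1e-10)
})

test_that("the test keeps nominal size under an independent cause", {
  set.seed(64)
  rej <- 0
  n_mc <- 200
  for (i in seq_len(n_mc)) {
    panel <- generate(dgp_config("independent_rw", T = 100, seed = 4000 + i))
    r <- granger_short_run(panel, "LGDP", "LHEP", "EMP", lag = 1)
    if (r$p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_mc, 0.02)
  expect_lte(rej / n_mc, 0.09)
})

test_that("the Granger F grows with signal-to-noise", {
  fs <- vapply(c(0.1, 0.4, 0.9), function(b) {
    set.seed(65)
    T <- 100
    x <- cumsum(rnorm(T, 0, 0.05))
    dy <- c(0, b * diff(x)[1:(T - 2)]) + rnorm(T - 1, 0, 0.02)
    panel <- country_panel("Z", 2000:(2000 + T - 1), cumsum(c(8, dy)),
                           6 + x, fardl:::emp_walk(T))
    granger_short_run(panel, "LGDP", "LHEP", "EMP", lag = 1)$F
  }, numeric(1))
  expect_true(all(diff(fs) > 0))
})

test_that("granger_matrix covers all ordered pairs with p in (0, 1]", {
  g <- granger_matrix(quick_panel(seed = 66), lag = 1, k = 1)
  expect_equal(nrow(g), 6)
  expect_true(all(g$p > 0 & g$p <= 1))
  expect_true(all(g$sign %in% c("+", "-", "0")))
  expect_match(g$display[1], "/\\[")
})
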