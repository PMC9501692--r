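test_that("SSR-form F statistics equal the Wald quadratic form", {
  panel <- quick_panel(seed = 51, T = 40)
  sp <- ardl_spec("LGDP", 1, 1, 1, k = 1.4)
  fit <- fit_ardl(panel, sp)
  st <- compute_statistics(fit)
  lv <- c("L.LGDP", "L.LHEP", "L.EMP")
  expect_lt(abs(st$F_overall - wald_f_oracle(fit, lv)) /
              wald_f_oracle(fit, lv), 1e-6)
  expect_lt(abs(st$F2 - wald_f_oracle(fit, lv[2:3])) /
              wald_f_oracle(fit, lv[2:3]), 1e-6)
  # t1 is the coefficient t ratio
  expect_equal(st$t1, unname(fit$coefficients["L.LGDP"] / fit$se["L.LGDP"]))
})

test_that("a restriction satisfied by construction yields F = 0", {
  set.seed(52)
  n <- 60
  X <- cbind(const = 1, a = rnorm(n), b = rnorm(n))
  # noise orthogonalized against the whole design: the coefficient on b
  # is then exactly zero and the restriction costless
  e_raw <- rnorm(n)
  e <- e_raw - drop(X %*% solve(crossprod(X), crossprod(X, e_raw)))
  fit <- ols_fit(drop(X[, 1:2] %*% c(1, 2)) + e, X)
  expect_lt(abs(fit$coefficients[["b"]]), 1e-10)
  expect_lt(fardl:::ssr_f_stat(fit, "b"), 1e-8)
})

test_that("a strong error-correction term drives t1 negative and large", {
  panel <- generate(dgp_config("cointegrated_ecm", T = 200, seed = 53,
                               lambda = -0.8, sigma = 0.02))
  st <- compute_statistics(fit_ardl(panel, ardl_spec("LGDP", 1, 1, 1, k = 1)))
  expect_lt(st$t1, -4)
})

test_that("bootstrap critical values are reproducible and monotone in alpha", {
  panel <- quick_panel(seed = 54)
  sp <- ardl_spec("LGDP", 1, 1, 1, k = 1.2)
  cv1 <- bootstrap_critical_values(panel, sp, "A", n_boot = 199, seed = 9)
  cv2 <- bootstrap_critical_values(panel, sp, "A", n_boot = 199, seed = 9)
  expect_identical(cv1$cv, cv2$cv)
  expect_identical(cv1$draws, cv2$draws)

  draws <- cv1$draws
  q <- quantile(draws, c(0.90, 0.95, 0.99), names = FALSE)
  expect_true(q[1] <= q[2] && q[2] <= q[3])
  cvB <- bootstrap_critical_values(panel, sp, "B", n_boot = 199, seed = 9,
                                   alpha = 0.05)
  cvB10 <- bootstrap_critical_values(panel, sp, "B", n_boot = 199, seed = 9,
                                     alpha = 0.10)
  expect_lte(cvB$cv, cvB10$cv)          # 5% t CV more extreme (more negative)
})

test_that("bootstrap critical values stabilize as replications double", {
  # the replicate-indexed seed stream makes the first n draws of the
  # doubled run identical, so this isolates the pure effect of more
  # replications
  panel <- generate(dgp_config("independent_rw", T = 50, seed = 55))
  sp <- ardl_spec("LGDP", 1, 1, 1, k = 0.8)
  cv_a <- bootstrap_critical_values(panel, sp, "A", n_boot = 2000, seed = 3)
  cv_b <- bootstrap_critical_values(panel, sp, "A", n_boot = 4000, seed = 3)
  expect_lt(abs(cv_a$cv - cv_b$cv) / cv_b$cv, 0.05)
})

test_that("the decision table maps all eight patterns to exactly one status", {
  mk_stats <- function(fs, t1s, f2s) {
    structure(list(F_overall = if (fs) 10 else 1,
                   t1 = if (t1s) -5 else -1,
                   F2 = if (f2s) 10 else 1,
                   t2 = c(L.LHEP = 1, L.EMP = 1)),
              class = "ardl_test_stats")
  }
  cvs <- structure(list(F_star = 4, t1_star = -3, F2_star = 4, t2_star = 3,
                        alpha = 0.05), class = "bootstrap_cv_set")
  expected <- list(
    c(TRUE, TRUE, TRUE, "cointegration"),
    c(TRUE, TRUE, FALSE, "degenerate_1"),
    c(TRUE, FALSE, TRUE, "degenerate_2"),
    c(TRUE, FALSE, FALSE, "no_cointegration"),
    c(FALSE, TRUE, TRUE, "no_cointegration"),
    c(FALSE, TRUE, FALSE, "no_cointegration"),
    c(FALSE, FALSE, TRUE, "no_cointegration"),
    c(FALSE, FALSE, FALSE, "no_cointegration"))
  seen <- character(0)
  for (e in expected) {
    r <- classify(mk_stats(as.logical(e[1]), as.logical(e[2]),
                           as.logical(e[3])), cvs)
    expect_equal(r$status, e[4])
    seen <- c(seen, r$status)
  }
  expect_length(seen, 8)
  expect_setequal(unique(seen),
                  c("cointegration", "degenerate_1", "degenerate_2",
                    "no_cointegration"))
})

test_that("degenerate DGPs are steered away from a cointegration call", {
  # lagged independents absent: expect degenerate #1 or no-cointegration
  p1 <- generate(dgp_config("degenerate_1", T = 60, seed = 57, sigma = 0.05))
  sp <- ardl_spec("LGDP", 1, 1, 1, k = 1)
  r1 <- classify(compute_statistics(fit_ardl(p1, sp)),
                 bootstrap_all_cvs(p1, sp, n_boot = 199, seed = 5))
  expect_true(r1$status %in% c("degenerate_1", "no_cointegration"))
})

test_that("long-run causality demands a cointegrated relation and shows power", {
  panel <- quick_panel(seed = 58)
  sp <- ardl_spec("LGDP", 1, 1, 1, k = 1)
  fake <- structure(list(status = "no_cointegration"),
                    class = "cointegration_result")
  expect_error(long_run_causality(panel, sp, "LHEP", fake), "state error")

  # power: the dependent error-corrects toward LHEP, so excluding LHEP
  # from the ECM should be rejected most of the time
  rej <- 0
  n_mc <- 25
  for (s in seq_len(n_mc)) {
    pec <- generate(dgp_config("cointegrated_ecm", T = 100, seed = 900 + s,
                               lambda = -0.5, sigma = 0.05))
    ok <- structure(list(status = "cointegration"),
                    class = "cointegration_result")
    lr <- long_run_causality(pec, sp, "LHEP", ok, n_boot = 199,
                             seed = 900 + s)
    if (lr$p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_mc, 0.60)
})
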