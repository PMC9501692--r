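# Residual-bootstrap inference for the Fourier ARDL bounds test:
# observed F / t1 / F2 statistics, bootstrap critical values under the
# three nulls, classification into cointegration / no-cointegration /
# degenerate cases, and the long-run causality test used when
# cointegration holds.
#
# The bootstrap regenerates the dependent variable from the
# null-restricted equation and the independents from their own marginal
# ARDL fits (a system bootstrap), preserving the feedback the bounds
# test is designed to allow.

# deterministic seed derivation: master seed + string key -> int < 2^31
derive_seed <- function(master, key) {
  h <- as.double(master %% 2147483647)
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# unvalidated panel for bootstrap pseudo-samples (emp range etc. need
# not hold on resampled paths)
panel_unsafe <- function(template, series) {
  structure(list(country = template$country, years = template$years,
                 lgdp = series$LGDP, lhep = series$LHEP, emp = series$EMP),
            class = "country_panel")
}

panel_series_list <- function(panel) {
  out <- lapply(panel_variables(), panel_series, panel = panel)
  names(out) <- panel_variables()
  out
}

restricted_columns <- function(spec, null = c("A", "B", "C")) {
  null <- match.arg(null)
  ldep <- paste0("L.", spec$dependent)
  lind <- paste0("L.", spec$independents)
  switch(null, A = c(ldep, lind), B = ldep, C = lind)
}

# refit a design with columns dropped; returns ardl_fit
drop_refit <- function(fit, drop) {
  keep <- setdiff(colnames(fit$X), drop)
  if (length(keep) == 0) stop("specification error: restriction removes all regressors")
  ols_fit(fit$y, fit$X[, keep, drop = FALSE], spec = fit$spec,
          t_index = fit$t_index, T = fit$T)
}

# F statistic by restricted/unrestricted SSR comparison
ssr_f_stat <- function(fit, drop) {
  rf <- drop_refit(fit, drop)
  ((rf$ssr - fit$ssr) / length(drop)) / (fit$ssr / fit$dof)
}

#' Bounds-test statistics from a fitted Fourier ARDL regression
#'
#' Computes the three statistics that drive the cointegration decision:
#' the overall F on all lagged-level coefficients (null A: all zero),
#' the t ratio on the lagged dependent level (null B), and the joint F2
#' on the lagged independent levels (null C). Per-coefficient t ratios
#' on the lagged independents are reported alongside for table fidelity.
#'
#' @param fit An `ardl_fit` from [fit_ardl()] with positive residual
#'   degrees of freedom.
#' @return An `ardl_test_stats` list: `F_overall`, `t1`, `F2`, `t2`
#'   (named vector).
#' @export
compute_statistics <- function(fit) {
  stopifnot(inherits(fit, "ardl_fit"), fit$dof > 0)
  spec <- fit$spec
  ldep <- paste0("L.", spec$dependent)
  lind <- paste0("L.", spec$independents)
  stopifnot(all(c(ldep, lind) %in% colnames(fit$X)))
  structure(list(F_overall = ssr_f_stat(fit, c(ldep, lind)),
                 t1 = unname(fit$tvalues[ldep]),
                 F2 = ssr_f_stat(fit, lind),
                 t2 = fit$tvalues[lind]),
            class = "ardl_test_stats")
}

#' @export
print.ardl_test_stats <- function(x, ...) {
  cat(sprintf("F = %.3f, t1 = %.3f, F2 = %.3f, t2 = (%s)\n", x$F_overall,
              x$t1, x$F2, paste(sprintf("%.3f", x$t2), collapse = ", ")))
  invisible(x)
}

# marginal ARDL fit for one independent variable:
# dx_t = c + g1 sin + g2 cos + a1 dx_{t-1} + u
marginal_model <- function(x, T, k) {
  dx <- diff(x)
  idx <- 3:T
  X <- cbind(const = 1, if (!is.null(k)) fourier_term(T, k)[idx, , drop = FALSE],
             d.l1 = dx[idx - 2])
  fit <- stats::lm.fit(X, dx[idx - 1])
  res <- fit$residuals
  list(coef = fit$coefficients, resid = res - mean(res))
}

# simulate one marginal independent path with resampled residuals
simulate_marginal <- function(x, mm, T, k) {
  u <- sample(mm$resid, T - 2, replace = TRUE)
  idx <- 3:T
  det <- mm$coef[["const"]] + u
  if (!is.null(k)) {
    Fm <- fourier_term(T, k)[idx, , drop = FALSE]
    det <- det + Fm[, "sin"] * mm$coef[["sin"]] + Fm[, "cos"] * mm$coef[["cos"]]
  }
  dx_new <- stats::filter(det, mm$coef[["d.l1"]], method = "recursive",
                          init = x[2] - x[1])
  c(x[1], x[2], x[2] + cumsum(as.numeric(dx_new)))
}

# simulate the dependent path from the restricted equation:
# det_part: deterministic + independent-variable part per row (length n)
# b1: coefficient on own lagged level; phi: coefficients on own lagged
# differences; y_init: observed levels 1..trim+1; e: resampled residuals
simulate_dependent <- function(det_part, b1, phi, y_init, e) {
  p <- length(phi)
  if (p == 0) a <- 1 + b1
  else a <- c(1 + b1 + phi[1],
              if (p > 1) phi[2:p] - phi[1:(p - 1)],
              -phi[p])
  init <- rev(utils::tail(y_init, p + 1))
  y_new <- stats::filter(det_part + e, a, method = "recursive", init = init)
  c(y_init, as.numeric(y_new))
}

# one pseudo panel under the null-restricted model
rebuild_pseudo_panel <- function(panel, spec, trim_lag, rfit, marg, e_centered) {
  T <- panel_length(panel)
  obs <- panel_series_list(panel)
  series <- obs
  for (v in spec$independents) {
    series[[v]] <- simulate_marginal(obs[[v]], marg[[v]], T, spec$k)
  }
  # deterministic + regressor part that does not involve the dependent:
  # build the restricted design on a panel holding the new x paths and
  # the observed dependent, then strip the dependent's own columns.
  ph_panel <- panel_unsafe(panel, series)
  d <- build_design(ph_panel, spec, trim_lag = trim_lag)
  cols_r <- colnames(rfit$X)
  Xr <- d$X[, cols_r, drop = FALSE]
  dep_cols <- grep(paste0("^(L|d)\\.", spec$dependent), cols_r, value = TRUE)
  beta <- rfit$coefficients
  free <- setdiff(cols_r, dep_cols)
  det_part <- drop(Xr[, free, drop = FALSE] %*% beta[free])
  ldep <- paste0("L.", spec$dependent)
  b1 <- if (ldep %in% cols_r) beta[[ldep]] else 0
  phi <- if (spec$p > 0) {
    unname(beta[paste0("d.", spec$dependent, ".l", seq_len(spec$p))])
  } else numeric(0)
  e <- sample(e_centered, length(det_part), replace = TRUE)
  series[[spec$dependent]] <- simulate_dependent(
    det_part, b1, phi, obs[[spec$dependent]][seq_len(trim_lag + 1)], e)
  panel_unsafe(panel, series)
}

#' Bootstrap critical values for the bounds-test statistics
#'
#' Residual bootstrap under the chosen null: the null-restricted model
#' (tested level coefficients set to zero, all other terms retained) is
#' estimated, its centered residuals resampled i.i.d., and pseudo-samples
#' rebuilt recursively from the restricted equation with the observed
#' initial values and the same Fourier term; the independents are
#' regenerated from their own marginal fits. The unrestricted model is
#' re-estimated on every pseudo-sample and the statistic's empirical
#' quantile returned: upper (1 - alpha) for F-type statistics, lower
#' alpha for t1 (one-sided, lower tail).
#'
#' @param panel A `country_panel`.
#' @param spec An `ardl_spec` with a Fourier frequency.
#' @param null `"A"` (all levels), `"B"` (lagged dependent), `"C"`
#'   (lagged independents).
#' @param n_boot Bootstrap replications (>= 199; 5000 for final tables).
#' @param alpha Significance level.
#' @param seed Integer seed; the replicate stream is replicate-indexed,
#'   so dropped replicates do not shift subsequent draws.
#' @return A `bootstrap_cvs` list: `cv`, `draws`, `t2_draws` (null C
#'   only: max |t| over the lagged independents), `null`, `alpha`,
#'   `n_boot`, `n_failed`, `seed`.
#' @export
bootstrap_critical_values <- function(panel, spec, null = c("A", "B", "C"),
                                      n_boot = 5000, alpha = 0.05, seed = 1) {
  null <- match.arg(null)
  stopifnot(n_boot >= 199)
  trim_lag <- max(spec$p, spec$q1, spec$q2)
  fit <- fit_ardl(panel, spec)
  drop <- restricted_columns(spec, null)
  rfit <- drop_refit(fit, drop)
  e_centered <- rfit$residuals - mean(rfit$residuals)
  marg <- lapply(panel_series_list(panel)[spec$independents], marginal_model,
                 T = panel_length(panel), k = spec$k)
  lind <- paste0("L.", spec$independents)
  draws <- rep(NA_real_, n_boot)
  t2_draws <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    set.seed(derive_seed(seed, paste0(null, ":", b)))
    stat <- tryCatch({
      pp <- rebuild_pseudo_panel(panel, spec, trim_lag, rfit, marg, e_centered)
      ufit <- fit_ardl(pp, spec)
      if (null == "C") t2_draws[b] <- max(abs(ufit$tvalues[lind]))
      switch(null,
             A = ssr_f_stat(ufit, restricted_columns(spec, "A")),
             B = unname(ufit$tvalues[paste0("L.", spec$dependent)]),
             C = ssr_f_stat(ufit, restricted_columns(spec, "C")))
    }, error = function(e) NA_real_)
    draws[b] <- stat
  }
  n_failed <- sum(!is.finite(draws))
  if (n_failed > 0.05 * n_boot) {
    stop("bootstrap-instability error: ", n_failed, " of ", n_boot,
         " replicates failed")
  }
  ok <- is.finite(draws)
  cv <- if (null == "B") stats::quantile(draws[ok], alpha, names = FALSE)
        else stats::quantile(draws[ok], 1 - alpha, names = FALSE)
  structure(list(cv = cv, draws = draws[ok],
                 t2_draws = if (null == "C") t2_draws[is.finite(t2_draws)],
                 null = null, alpha = alpha, n_boot = n_boot,
                 n_failed = n_failed, seed = seed),
            class = "bootstrap_cvs")
}

#' @export
print.bootstrap_cvs <- function(x, ...) {
  cat(sprintf("<bootstrap_cvs> null %s: cv = %.4f (alpha = %.2f, n_boot = %d, %d failed)\n",
              x$null, x$cv, x$alpha, x$n_boot, x$n_failed))
  invisible(x)
}

#' Bootstrap critical values for all three nulls
#'
#' @inheritParams bootstrap_critical_values
#' @return A `bootstrap_cv_set`: `F_star`, `t1_star`, `F2_star`,
#'   `t2_star` (from the max-|t| distribution under null C), `alpha`,
#'   `n_boot`, `seed`, and the per-null `bootstrap_cvs` in `runs`.
#' @export
bootstrap_all_cvs <- function(panel, spec, n_boot = 5000, alpha = 0.05,
                              seed = 1) {
  runs <- lapply(c("A", "B", "C"), function(nl) {
    bootstrap_critical_values(panel, spec, nl, n_boot, alpha,
                              seed = derive_seed(seed, paste0("null", nl)))
  })
  names(runs) <- c("A", "B", "C")
  structure(list(F_star = runs$A$cv, t1_star = runs$B$cv, F2_star = runs$C$cv,
                 t2_star = stats::quantile(runs$C$t2_draws, 1 - alpha,
                                           names = FALSE),
                 alpha = alpha, n_boot = n_boot, seed = seed, runs = runs),
            class = "bootstrap_cv_set")
}

#' Classify the cointegration outcome
#'
#' Decision table on the three significance indicators (F against F*,
#' t1 one-sided against t1*, F2 against F2*):
#' all three significant -> cointegration; F and t1 only ->
#' degenerate case #1 (lagged independents do not enter); F and F2
#' only -> degenerate case #2 (no error correction); every other
#' pattern -> no cointegration.
#'
#' @param statistics An `ardl_test_stats`.
#' @param cvs A `bootstrap_cv_set` at the same significance level.
#' @return A `cointegration_result`: `statistics`, `cvs`, `significant`
#'   (named logical F/t1/F2) and `status` in
#'   `{"cointegration", "no_cointegration", "degenerate_1", "degenerate_2"}`.
#' @export
classify <- function(statistics, cvs) {
  f_sig <- statistics$F_overall > cvs$F_star
  t1_sig <- statistics$t1 < cvs$t1_star
  f2_sig <- statistics$F2 > cvs$F2_star
  status <- if (f_sig && t1_sig && f2_sig) "cointegration"
            else if (f_sig && t1_sig) "degenerate_1"
            else if (f_sig && f2_sig) "degenerate_2"
            else "no_cointegration"
  structure(list(statistics = statistics, cvs = cvs,
                 significant = c(F = f_sig, t1 = t1_sig, F2 = f2_sig),
                 status = status),
            class = "cointegration_result")
}

#' Human-readable cointegration status label
#' @param status Internal status string.
#' @return Display label as used in reporting.
#' @export
status_label <- function(status) {
  switch(status,
         cointegration = "Cointegration",
         no_cointegration = "No-cointegration",
         degenerate_1 = "Degeneration Case #1",
         degenerate_2 = "Degeneration Case #2",
         stop("unknown status: ", status))
}

#' @export
print.cointegration_result <- function(x, ...) {
  cat(sprintf("<cointegration_result> %s  (F %.3f vs %.3f, t1 %.3f vs %.3f, F2 %.3f vs %.3f)\n",
              status_label(x$status), x$statistics$F_overall, x$cvs$F_star,
              x$statistics$t1, x$cvs$t1_star, x$statistics$F2, x$cvs$F2_star))
  invisible(x)
}

#' Long-run causality test within a cointegrated relation
#'
#' F test of excluding one regressor's lagged level together with its
#' lagged differences from the error-correction equation, with the
#' p-value from the same residual-bootstrap scheme (pseudo-samples
#' generated under the exclusion null). Only meaningful when the
#' relation was classified as cointegrated.
#'
#' @param panel A `country_panel`.
#' @param spec The cointegrated `ardl_spec`.
#' @param cause One of the spec's independent variables.
#' @param result The `cointegration_result` for this spec; must have
#'   status `"cointegration"`.
#' @param n_boot Bootstrap replications.
#' @param seed Integer seed.
#' @param levels_only Exclude only the lagged level, keeping the lagged
#'   differences (default `FALSE`: level + differences).
#' @return List with `F`, `p` (bootstrap probability), `cause`,
#'   `excluded` column names and `n_boot`.
#' @export
long_run_causality <- function(panel, spec, cause, result, n_boot = 999,
                               seed = 1, levels_only = FALSE) {
  if (!inherits(result, "cointegration_result") ||
      result$status != "cointegration") {
    stop("state error: long-run causality requires a cointegrated relation")
  }
  if (!cause %in% spec$independents) stop(cause, " is not a regressor of this spec")
  fit <- fit_ardl(panel, spec)
  qx <- if (cause == spec$independents[1]) spec$q1 else spec$q2
  excl <- paste0("L.", cause)
  if (!levels_only && qx > 0) {
    excl <- c(excl, paste0("d.", cause, ".l", seq_len(qx)))
  }
  F_obs <- ssr_f_stat(fit, excl)
  # bootstrap under the exclusion null
  trim_lag <- max(spec$p, spec$q1, spec$q2)
  rfit <- drop_refit(fit, excl)
  e_centered <- rfit$residuals - mean(rfit$residuals)
  marg <- lapply(panel_series_list(panel)[spec$independents], marginal_model,
                 T = panel_length(panel), k = spec$k)
  draws <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    set.seed(derive_seed(seed, paste0("LR:", cause, ":", b)))
    draws[b] <- tryCatch({
      pp <- rebuild_pseudo_panel(panel, spec, trim_lag, rfit, marg, e_centered)
      ssr_f_stat(fit_ardl(pp, spec), excl)
    }, error = function(e) NA_real_)
  }
  ok <- is.finite(draws)
  if (sum(!ok) > 0.05 * n_boot) stop("bootstrap-instability error in long-run test")
  p <- (1 + sum(draws[ok] >= F_obs)) / (1 + sum(ok))
  list(F = F_obs, p = p, cause = cause, excluded = excl, n_boot = n_boot)
}
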