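# Short-run Granger causality between the analysis variables, used when
# no cointegration is found. Tests run in first differences with the
# Fourier deterministic term included.

#' Short-run Granger causality test
#'
#' Regresses the effect variable's first difference on its own lagged
#' differences, the lagged differences of the cause and of the control
#' variable, and the Fourier deterministic term; then F-tests the joint
#' exclusion of the cause's lagged differences. The sign of the summed
#' excluded coefficients gives the direction of the short-run effect.
#'
#' @param panel A `country_panel`.
#' @param effect Dependent variable label.
#' @param cause Variable whose lagged differences are tested.
#' @param control The remaining variable, kept as a control.
#' @param lag Tested lag depth (>= 1, default 1).
#' @param k Fourier frequency for the deterministic term (default 1;
#'   the pipeline passes the frequency selected for the rotation).
#'   `NULL` drops the Fourier term.
#' @param bootstrap_p Compute the p-value by residual bootstrap under
#'   the exclusion null instead of the F distribution (default `FALSE`,
#'   matching conventional reporting).
#' @param n_boot Replications when `bootstrap_p = TRUE`.
#' @param seed Seed for the bootstrap p-value.
#' @return A `causality_result`: `cause`, `effect`, `F`, `p`, `lag`,
#'   `sign` (`"+"`, `"-"` or `"0"`), `coef_sum`.
#' @export
granger_short_run <- function(panel, effect, cause, control, lag = 1, k = 1,
                              bootstrap_p = FALSE, n_boot = 999, seed = 1) {
  stopifnot(lag >= 1)
  vars <- c(effect, cause, control)
  stopifnot(setequal(vars, panel_variables()))
  T <- panel_length(panel)
  d <- lapply(vars, function(v) diff(panel_series(panel, v)))
  names(d) <- vars
  idx <- (lag + 2):T                    # time index on the levels scale
  n <- length(idx)
  y <- d[[effect]][idx - 1]
  X <- cbind(const = rep(1, n))
  if (!is.null(k)) X <- cbind(X, fourier_term(T, k)[idx, , drop = FALSE])
  for (v in vars) {
    for (i in seq_len(lag)) {
      X <- cbind(X, d[[v]][idx - 1 - i])
      colnames(X)[ncol(X)] <- paste0("d.", v, ".l", i)
    }
  }
  if (n < ncol(X) + 2) stop("sample too short for lag = ", lag)
  fit <- ols_fit(y, X)
  excl <- paste0("d.", cause, ".l", seq_len(lag))
  F_obs <- ssr_f_stat(fit, excl)
  coef_sum <- sum(fit$coefficients[excl])
  if (bootstrap_p) {
    rfit <- drop_refit(fit, excl)
    e_c <- rfit$residuals - mean(rfit$residuals)
    draws <- vapply(seq_len(n_boot), function(b) {
      set.seed(derive_seed(seed, paste0("G:", cause, ":", b)))
      yb <- rfit$fitted + sample(e_c, n, replace = TRUE)
      tryCatch(ssr_f_stat(ols_fit(yb, X), excl), error = function(e) NA_real_)
    }, numeric(1))
    ok <- is.finite(draws)
    p <- (1 + sum(draws[ok] >= F_obs)) / (1 + sum(ok))
  } else {
    p <- stats::pf(F_obs, lag, fit$dof, lower.tail = FALSE)
  }
  structure(list(cause = cause, effect = effect, F = F_obs, p = p,
                 lag = as.integer(lag), coef_sum = coef_sum,
                 sign = if (abs(coef_sum) < 1e-12) "0"
                        else if (coef_sum > 0) "+" else "-"),
            class = "causality_result")
}

#' @export
print.causality_result <- function(x, ...) {
  cat(sprintf("%s -> %s: F = %.6f%s [%.4f], lag %d, sign %s\n", x$cause,
              x$effect, x$F, significance_stars(x$p), x$p, x$lag, x$sign))
  invisible(x)
}

#' Pairwise short-run Granger causality matrix
#'
#' All six ordered (cause, effect) pairs of the three analysis
#' variables, each with the remaining variable as control.
#'
#' @param panel A `country_panel`.
#' @param lag Tested lag depth.
#' @param k Fourier frequency for the deterministic term.
#' @return Data frame with one row per ordered pair: `cause`, `effect`,
#'   `F`, `p`, `sign` and the formatted `display` cell `"F***/[p]"`.
#' @export
granger_matrix <- function(panel, lag = 1, k = 1) {
  vars <- panel_variables()
  rows <- list()
  for (effect in vars) {
    for (cause in setdiff(vars, effect)) {
      control <- setdiff(vars, c(effect, cause))
      r <- granger_short_run(panel, effect, cause, control, lag = lag, k = k)
      rows[[length(rows) + 1]] <- data.frame(
        cause = cause, effect = effect, F = r$F, p = r$p, sign = r$sign,
        display = sprintf("%.6f%s/[%.4f]", r$F, significance_stars(r$p), r$p),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
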