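# DF / ADF / Phillips-Perron unit-root tests with MacKinnon
# response-surface p-values, and the I(0)/I(1) admissibility check that
# gates the ARDL bounds test.

# MacKinnon (1994) response-surface coefficients for the single-variable
# Dickey-Fuller tau distribution, by deterministic specification:
# p = Phi(c0 + c1*tau + c2*tau^2 [+ c3*tau^3]), with the cubic branch used
# above tau_star. Outside [tau_min, tau_max] the p-value saturates at 0/1.
.mackinnon_tab <- list(
  none = list(star = -1.04, min = -19.04, max = Inf,
              small = c(0.6344, 1.2378, 0.032496),
              large = c(0.4797, 0.93557, -0.06999, 0.033066)),
  intercept = list(star = -1.61, min = -18.83, max = 2.74,
                   small = c(2.1659, 1.4412, 0.038269),
                   large = c(1.7339, 0.93202, -0.12745, -0.010368)),
  trend_intercept = list(star = -2.89, min = -16.18, max = 0.7,
                         small = c(3.2512, 1.6047, 0.049588),
                         large = c(2.5261, 0.61654, -0.37956, -0.060285)))

#' MacKinnon response-surface p-value for a Dickey-Fuller-type statistic
#'
#' Approximate asymptotic p-value of a tau statistic from the DF/ADF/PP
#' family, using MacKinnon's (1994) regression-surface polynomials for a
#' single series under the given deterministic specification.
#'
#' @param tau Test statistic.
#' @param spec `"intercept"`, `"trend_intercept"` or `"none"`.
#' @return p-value in (0, 1), saturated at the table bounds.
#' @export
mackinnon_pvalue <- function(tau, spec = c("intercept", "trend_intercept", "none")) {
  spec <- match.arg(spec)
  tb <- .mackinnon_tab[[spec]]
  p <- if (tau > tb$max) 1
       else if (tau < tb$min) 0
       else {
         co <- if (tau <= tb$star) tb$small else tb$large
         stats::pnorm(sum(co * tau^(seq_along(co) - 1)))
       }
  # keep p interior: beyond the table range the decision is unambiguous
  min(max(p, 1e-6), 1 - 1e-6)
}

unit_root_result <- function(test, spec, differenced, statistic,
                             lags_or_bandwidth, p_value) {
  structure(list(test = test, spec = spec, differenced = differenced,
                 statistic = statistic,
                 lags_or_bandwidth = as.integer(lags_or_bandwidth),
                 p_value = p_value,
                 reject_levels = c("10%", "5%", "1%")[c(0.10, 0.05, 0.01) > p_value]),
            class = "unit_root_result")
}

#' @export
print.unit_root_result <- function(x, ...) {
  cat(sprintf("%s [%s%s] stat %.4f%s (%d), p = %.4f\n", x$test, x$spec,
              if (x$differenced) ", 1st diff" else "", x$statistic,
              significance_stars(x$p_value), x$lags_or_bandwidth, x$p_value))
  invisible(x)
}

det_terms <- function(n, spec) {
  switch(spec,
         none = matrix(numeric(0), nrow = n, ncol = 0),
         intercept = cbind(const = rep(1, n)),
         trend_intercept = cbind(const = rep(1, n), trend = seq_len(n)))
}

# ADF regression at a fixed lag p on observations start..T of dx
adf_regression <- function(x, spec, p, start = p + 2) {
  n <- length(x)
  dx <- diff(x)
  idx <- start:n                       # time indices of the dependent dx_t
  y <- dx[idx - 1]
  X <- cbind(det_terms(length(idx), spec), level = x[idx - 1])
  if (p > 0) {
    for (i in seq_len(p)) X <- cbind(X, dx[idx - 1 - i])
  }
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  ssr <- sum(res^2)
  k <- ncol(X)
  nobs <- length(y)
  XtXinv <- chol2inv(chol(crossprod(X)))
  s2 <- ssr / (nobs - k)
  se <- sqrt(s2 * diag(XtXinv))
  j <- which(colnames(X) == "level")
  list(tau = fit$coefficients[j] / se[j], ssr = ssr, nobs = nobs, k = k,
       aic = nobs * log(ssr / nobs) + 2 * k,
       residuals = res, coefficients = fit$coefficients, se = se)
}

#' Augmented Dickey-Fuller test
#'
#' ADF regression of the first difference on the lagged level, the chosen
#' deterministic terms and `lag` lagged differences. The lag order is
#' chosen by minimum AIC over 0..`max_lag`, with all candidates fit on the
#' common sample implied by `max_lag` so their AICs are comparable; the
#' reported statistic is from a refit at the chosen lag on its maximal
#' sample. With `max_lag = 0` this is the plain Dickey-Fuller test.
#'
#' @param x Numeric series.
#' @param spec Deterministic terms: `"intercept"`, `"trend_intercept"`
#'   or `"none"`.
#' @param max_lag Maximum augmentation lag (default 2, suited to ~20
#'   annual observations).
#' @param differenced Marker recorded in the result (set `TRUE` when `x`
#'   is already a first difference).
#' @return A `unit_root_result`.
#' @export
adf_test <- function(x, spec = c("intercept", "trend_intercept", "none"),
                     max_lag = 2, differenced = FALSE) {
  spec <- match.arg(spec)
  x <- as.numeric(x)
  if (length(x) < max_lag + 8) stop("insufficient data: need length >= max_lag + 8")
  aics <- vapply(0:max_lag, function(p) {
    adf_regression(x, spec, p, start = max_lag + 2)$aic
  }, numeric(1))
  p_best <- (0:max_lag)[which.min(aics)]
  reg <- adf_regression(x, spec, p_best)
  unit_root_result(if (max_lag == 0) "DF" else "ADF", spec, differenced,
                   unname(reg$tau), p_best, mackinnon_pvalue(reg$tau, spec))
}

#' Dickey-Fuller test (no augmentation)
#'
#' @inheritParams adf_test
#' @return A `unit_root_result` with `test = "DF"`.
#' @export
df_test <- function(x, spec = c("intercept", "trend_intercept"),
                    differenced = FALSE) {
  adf_test(x, match.arg(spec), max_lag = 0, differenced = differenced)
}

#' Phillips-Perron test
#'
#' Z-tau statistic: the Dickey-Fuller regression without augmentation,
#' corrected nonparametrically for serial correlation with a
#' Bartlett-kernel long-run variance at the Newey-West automatic
#' bandwidth `floor(4 (n/100)^(2/9))`, floored at 1.
#'
#' @inheritParams adf_test
#' @return A `unit_root_result` with `test = "PP"` and the bandwidth in
#'   `lags_or_bandwidth`.
#' @export
pp_test <- function(x, spec = c("intercept", "trend_intercept", "none"),
                    differenced = FALSE) {
  spec <- match.arg(spec)
  x <- as.numeric(x)
  if (length(x) < 10) stop("insufficient data: need length >= 10")
  reg <- adf_regression(x, spec, 0, start = 2)
  u <- reg$residuals
  n <- reg$nobs
  q <- max(1L, floor(4 * (n / 100)^(2 / 9)))
  g0 <- sum(u^2) / n
  lrv <- g0
  for (j in seq_len(q)) {
    lrv <- lrv + 2 * (1 - j / (q + 1)) * sum(u[(j + 1):n] * u[1:(n - j)]) / n
  }
  if (lrv <= 0) lrv <- g0                 # kernel guard for tiny samples
  se_rho <- reg$se[which(names(reg$coefficients) == "level")]
  tau <- reg$tau
  s2 <- reg$ssr / (n - reg$k)
  z_tau <- sqrt(g0 / lrv) * tau -
    (lrv - g0) * n * se_rho / (2 * sqrt(lrv) * sqrt(s2))
  unit_root_result("PP", spec, differenced, unname(z_tau), q,
                   mackinnon_pvalue(z_tau, spec))
}

#' Classify the integration order of a series
#'
#' Implements the admissibility gate of the bootstrap ARDL bounds test:
#' the test is valid when every series is I(0) or I(1). A series is
#' called I(0) if any level-term test rejects a unit root at the chosen
#' level, I(1) if levels never reject but the first difference does, and
#' inadmissible otherwise. The default level is 10%, the most permissive
#' conventional mark.
#'
#' @param level_results List of `unit_root_result`s on the level series.
#' @param diff_results List of `unit_root_result`s on the first difference.
#' @param label Series label carried into the result.
#' @param alpha Rejection level for the gate (default 0.10).
#' @return An `integration_order` list with fields `label` and
#'   `order` in `{"I0", "I1", "inadmissible"}`.
#' @export
classify_integration <- function(level_results, diff_results, label = "",
                                 alpha = 0.10) {
  stopifnot(length(level_results) >= 1, length(diff_results) >= 1)
  rej <- function(rs) any(vapply(rs, function(r) r$p_value < alpha, logical(1)))
  order <- if (rej(level_results)) "I0"
           else if (rej(diff_results)) "I1"
           else "inadmissible"
  if (order == "inadmissible") {
    warning("series '", label, "' is neither I(0) nor I(1) at the ",
            alpha * 100, "% level; cointegration testing is not admissible")
  }
  structure(list(label = label, order = order), class = "integration_order")
}

#' Unit-root test grid for a panel
#'
#' Runs the DF (intercept, trend+intercept), ADF and PP (those two plus
#' no-deterministics) tests on every analysis variable, on levels or on
#' first differences, mirroring the conventional reporting grid.
#'
#' @param panel A `country_panel`.
#' @param differenced Test first differences instead of levels.
#' @param max_lag Maximum ADF augmentation lag.
#' @return Data frame with one row per (variable, test, spec): statistic,
#'   lag/bandwidth, p-value and a formatted `display` cell
#'   `"stat*** (lags)"`.
#' @export
unit_root_grid <- function(panel, differenced = FALSE, max_lag = 2) {
  rows <- list()
  for (v in panel_variables()) {
    x <- panel_series(panel, v)
    if (differenced) x <- diff(x)
    for (test in c("DF", "ADF", "PP")) {
      specs <- if (test == "DF") c("intercept", "trend_intercept")
               else c("intercept", "trend_intercept", "none")
      for (sp in specs) {
        r <- switch(test,
                    DF = df_test(x, sp, differenced = differenced),
                    ADF = adf_test(x, sp, max_lag = max_lag,
                                   differenced = differenced),
                    PP = pp_test(x, sp, differenced = differenced))
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, test = test, spec = sp, statistic = r$statistic,
          lags_or_bandwidth = r$lags_or_bandwidth, p_value = r$p_value,
          display = sprintf("%.4f%s (%d)", r$statistic,
                            significance_stars(r$p_value),
                            r$lags_or_bandwidth),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Integration admissibility for a whole panel
#'
#' @param panel A `country_panel`.
#' @param max_lag Maximum ADF augmentation lag.
#' @param alpha Rejection level for the gate.
#' @return Named list of `integration_order` objects, one per variable.
#' @export
panel_integration <- function(panel, max_lag = 2, alpha = 0.10) {
  out <- list()
  for (v in panel_variables()) {
    x <- panel_series(panel, v)
    lev <- list(adf_test(x, "intercept", max_lag),
                adf_test(x, "trend_intercept", max_lag),
                pp_test(x, "intercept"))
    dif <- list(adf_test(diff(x), "intercept", max_lag, differenced = TRUE),
                adf_test(diff(x), "trend_intercept", max_lag, differenced = TRUE),
                pp_test(diff(x), "intercept", differenced = TRUE))
    out[[v]] <- classify_integration(lev, dif, label = v, alpha = alpha)
  }
  out
}
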