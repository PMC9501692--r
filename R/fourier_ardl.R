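# The Fourier ARDL regression: a conditional error-correction equation
# for one dependent variable with the other two panel variables as
# regressors, augmented by a single-frequency sin/cos pair that proxies
# an unknown number of smooth structural breaks. Frequency chosen by SSR
# grid search, lag orders by AIC.

#' Fourier deterministic term
#'
#' `d(t) = gamma1 sin(2 pi k t / T) + gamma2 cos(2 pi k t / T)` with unit
#' amplitudes as regressors. The time index runs 1..T over the levels
#' sample, before any lag trimming.
#'
#' @param T Sample length of the levels series.
#' @param k Fourier frequency.
#' @return T x 2 matrix with columns `sin` and `cos`.
#' @export
fourier_term <- function(T, k) {
  t <- seq_len(T)
  cbind(sin = sin(2 * pi * k * t / T), cos = cos(2 * pi * k * t / T))
}

#' ARDL specification
#'
#' Lag orders follow the convention (p; q1, q2): `p` lagged differences
#' of the dependent variable and `q1`/`q2` of the two independents, all
#' in 0..2; 0 means the pure bounds regression with no short-run term for
#' that variable.
#'
#' @param dependent One of `"LGDP"`, `"LHEP"`, `"EMP"`.
#' @param p,q1,q2 Lag orders (non-negative, <= 2 by convention).
#' @param k Fourier frequency, or `NULL` for no Fourier term.
#' @param dummies Optional `break_set` whose level-shift dummies enter
#'   the deterministic part (default `NULL`: Fourier-only estimation).
#' @return An `ardl_spec`; `independents` are the remaining two
#'   variables in canonical order.
#' @export
ardl_spec <- function(dependent, p = 1, q1 = 1, q2 = 1, k = NULL,
                      dummies = NULL) {
  dependent <- match.arg(dependent, panel_variables())
  stopifnot(p >= 0, q1 >= 0, q2 >= 0)
  structure(list(dependent = dependent,
                 independents = setdiff(panel_variables(), dependent),
                 p = as.integer(p), q1 = as.integer(q1), q2 = as.integer(q2),
                 k = k, dummies = dummies),
            class = "ardl_spec")
}

#' Build the ARDL regression system
#'
#' Dependent: the first difference of the spec's dependent variable.
#' Regressor columns, in fixed order: intercept, Fourier sin/cos (if a
#' frequency is set), optional break dummies, lagged levels (dependent
#' then independents), then lagged differences per variable. Rows are
#' aligned with no look-ahead; the effective sample is
#' `T - 1 - trim_lag` observations, where `trim_lag` defaults to the
#' spec's maximum lag order but can be fixed (e.g. at `max_lag`) so that
#' fits with different lag orders share a common sample for AIC
#' comparison.
#'
#' @param panel A `country_panel`.
#' @param spec An `ardl_spec`.
#' @param trim_lag Number of initial observations (beyond the first)
#'   dropped for lags; default `max(p, q1, q2)`.
#' @return List with `y`, `X` (named columns), `t_index` (time indices
#'   of the rows on the 1..T levels scale), `spec`, `T`.
#' @export
build_design <- function(panel, spec, trim_lag = NULL) {
  T <- panel_length(panel)
  if (is.null(trim_lag)) trim_lag <- max(spec$p, spec$q1, spec$q2)
  series <- lapply(c(spec$dependent, spec$independents),
                   function(v) panel_series(panel, v))
  names(series) <- c(spec$dependent, spec$independents)
  idx <- (trim_lag + 2):T          # time indices of the dependent rows
  n <- length(idx)
  if (n < 3) stop("sample too short for the requested lags")
  y <- diff(series[[1]])[idx - 1]
  X <- cbind(const = rep(1, n))
  if (!is.null(spec$k)) {
    X <- cbind(X, fourier_term(T, spec$k)[idx, , drop = FALSE])
  }
  if (!is.null(spec$dummies)) {
    D <- breaks_to_dummies(spec$dummies, panel$years)
    if (ncol(D) > 0) X <- cbind(X, D[idx, , drop = FALSE])
  }
  for (v in names(series)) {
    lv <- series[[v]][idx - 1]
    X <- cbind(X, lv)
    colnames(X)[ncol(X)] <- paste0("L.", v)
  }
  qs <- c(spec$p, spec$q1, spec$q2)
  for (vi in seq_along(series)) {
    v <- names(series)[vi]
    dx <- diff(series[[v]])
    for (i in seq_len(qs[vi])) {
      X <- cbind(X, dx[idx - 1 - i])
      colnames(X)[ncol(X)] <- paste0("d.", v, ".l", i)
    }
  }
  if (ncol(X) >= n) stop("sample too short: ", ncol(X), " parameters for ",
                         n, " observations")
  list(y = y, X = X, t_index = idx, spec = spec, T = T)
}

#' Ordinary least squares fit of a regression system
#'
#' QR-based least squares with a hard full-rank requirement; collinear
#' designs are refused with the offending columns named. AIC is
#' `n log(SSR/n) + 2 npar` (Gaussian likelihood up to constants).
#'
#' @param y Response vector.
#' @param X Design matrix with named columns.
#' @param spec Optional `ardl_spec` stored in the fit.
#' @param t_index Optional time indices of the rows.
#' @param T Optional levels sample length.
#' @return An `ardl_fit`: `coefficients`, `se`, `tvalues`, `residuals`,
#'   `fitted`, `ssr`, `sigma2`, `aic`, `dof`, `n`, `XtXinv`.
#' @export
ols_fit <- function(y, X, spec = NULL, t_index = NULL, T = NULL) {
  n <- length(y)
  if (n < ncol(X) + 1) stop("sample too short: need rows >= columns + 1")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("collinearity error: rank-deficient design, offending column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  res <- y - drop(X %*% beta)
  ssr <- sum(res^2)
  dof <- n - ncol(X)
  sigma2 <- ssr / dof
  XtXinv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(sigma2 * diag(XtXinv))
  names(se) <- names(beta)
  structure(list(coefficients = beta, se = se, tvalues = beta / se,
                 residuals = res, fitted = y - res, ssr = ssr,
                 sigma2 = sigma2,
                 aic = n * log(ssr / n) + 2 * ncol(X),
                 dof = dof, n = n, XtXinv = XtXinv, X = X, y = y,
                 spec = spec, t_index = t_index, T = T),
            class = "ardl_fit")
}

#' @export
print.ardl_fit <- function(x, ...) {
  cat(sprintf("<ardl_fit> n = %d, npar = %d, SSR = %.6g, AIC = %.6f\n",
              x$n, ncol(x$X), x$ssr, x$aic))
  tab <- cbind(estimate = x$coefficients, se = x$se, t = x$tvalues)
  print(round(tab, 4))
  invisible(x)
}

#' Fit the Fourier ARDL regression for a spec
#'
#' @inheritParams build_design
#' @return An `ardl_fit`.
#' @export
fit_ardl <- function(panel, spec, trim_lag = NULL) {
  d <- build_design(panel, spec, trim_lag)
  ols_fit(d$y, d$X, spec = d$spec, t_index = d$t_index, T = d$T)
}

#' Select the Fourier frequency by SSR grid search
#'
#' Estimates the regression at every frequency on the grid (default
#' 0.1, 0.2, ..., 5.0) and returns the frequency with the smallest
#' residual sum of squares; ties break toward the smaller frequency.
#'
#' @param panel A `country_panel`.
#' @param dependent Dependent variable label.
#' @param lags Length-3 vector (p, q1, q2) used as the search template.
#' @param k_grid Frequency grid.
#' @return List with `k` (selected frequency), `fit` (the `ardl_fit` at
#'   `k`), and `profile` (data frame of k vs SSR).
#' @export
select_frequency <- function(panel, dependent, lags = c(1, 1, 1),
                             k_grid = seq(0.1, 5.0, by = 0.1)) {
  stopifnot(length(k_grid) >= 1, all(k_grid > 0))
  ssrs <- rep(NA_real_, length(k_grid))
  fits <- vector("list", length(k_grid))
  for (i in seq_along(k_grid)) {
    sp <- ardl_spec(dependent, lags[1], lags[2], lags[3], k = k_grid[i])
    fits[[i]] <- tryCatch(fit_ardl(panel, sp), error = function(e) NULL)
    if (!is.null(fits[[i]])) ssrs[i] <- fits[[i]]$ssr
  }
  if (all(is.na(ssrs))) stop("estimation error: no frequency could be fit")
  best <- which.min(ssrs)          # first minimum -> smaller k on ties
  list(k = k_grid[best], fit = fits[[best]],
       profile = data.frame(k = k_grid, ssr = ssrs))
}

#' Select ARDL lag orders by AIC
#'
#' Searches all (p, q1, q2) in `{0..max_lag}^3` that keep positive
#' residual degrees of freedom, with every candidate fit on the common
#' sample implied by `max_lag` so AICs are comparable. Ties break toward
#' fewer total lags, then lexicographically.
#'
#' @param panel A `country_panel`.
#' @param dependent Dependent variable label.
#' @param k Fourier frequency carried into every candidate.
#' @param max_lag Maximum per-variable lag order (default 2).
#' @return The AIC-minimal `ardl_spec`.
#' @export
select_lags <- function(panel, dependent, k = NULL, max_lag = 2) {
  stopifnot(max_lag >= 0)
  grid <- expand.grid(p = 0:max_lag, q1 = 0:max_lag, q2 = 0:max_lag)
  # lexicographic within total-lag ties: order by total, then p, q1, q2
  grid <- grid[order(grid$p + grid$q1 + grid$q2, grid$p, grid$q1, grid$q2), ]
  best <- NULL
  best_aic <- Inf
  for (r in seq_len(nrow(grid))) {
    sp <- ardl_spec(dependent, grid$p[r], grid$q1[r], grid$q2[r], k = k)
    fit <- tryCatch(fit_ardl(panel, sp, trim_lag = max_lag),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$aic < best_aic - 1e-12) {
      best <- sp
      best_aic <- fit$aic
    }
  }
  if (is.null(best)) stop("sample too short: no feasible lag combination")
  best
}
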