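# shared fixtures, all generated in code

# write a raw indicator CSV for one synthetic country and return its path
raw_csv_fixture <- function(years = 2000:2019, country = "BRA",
                            drop_year = NULL, unemp_override = NULL) {
  set.seed(11)
  n <- length(years)
  df <- data.frame(country = country, year = years,
                   gdp_pc = exp(8.5 + cumsum(c(0, rnorm(n - 1, 0.05, 0.03)))),
                   he_pc = exp(6.0 + cumsum(c(0, rnorm(n - 1, 0.05, 0.05)))),
                   unemp_pct = 8 + cumsum(c(0, rnorm(n - 1, 0, 0.4))))
  if (!is.null(unemp_override)) df$unemp_pct[1] <- unemp_override
  if (!is.null(drop_year)) df <- df[df$year != drop_year, ]
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

quick_panel <- function(seed = 5, T = 20, kind = "brics_like") {
  generate(dgp_config(kind, T = T, seed = seed))
}

# independent normal-equations OLS oracle (route independent of qr)
ols_oracle <- function(y, X) solve(crossprod(X), crossprod(X, y))

# Wald quadratic-form F statistic oracle for zero restrictions on
# named coefficients
wald_f_oracle <- function(fit, drop) {
  j <- match(drop, names(fit$coefficients))
  R <- matrix(0, length(j), length(fit$coefficients))
  R[cbind(seq_along(j), j)] <- 1
  rb <- R %*% fit$coefficients
  V <- fit$sigma2 * (R %*% fit$XtXinv %*% t(R))
  drop(t(rb) %*% solve(V, rb)) / length(j)
}

# exhaustive segmented-mean SSR search (oracle for the dynamic program)
exhaustive_break_ssr <- function(x, m, trim) {
  n <- length(x)
  h <- ceiling(trim * n)
  seg_ssr <- function(i, j) sum((x[i:j] - mean(x[i:j]))^2)
  best <- rep(Inf, m + 1)
  best[1] <- seg_ssr(1, n)
  starts_rec <- function(chosen, j) {
    if (j > 0) {
      lo <- if (length(chosen)) chosen[length(chosen)] + h else 1 + h
      hi <- n + 1 - h * j
      if (lo <= hi) {
        for (s in lo:hi) starts_rec(c(chosen, s), j - 1)
      }
    } else {
      b <- c(1, chosen, n + 1)
      lens <- diff(b)
      if (any(lens < h)) return()
      ssr <- sum(vapply(seq_len(length(b) - 1),
                        function(i) seg_ssr(b[i], b[i + 1] - 1), numeric(1)))
      k <- length(chosen)
      if (ssr < best[k + 1]) best[k + 1] <<- ssr
    }
  }
  for (j in seq_len(m)) starts_rec(integer(0), j)
  best
}
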