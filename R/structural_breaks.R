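# Sharp structural breaks by SSR-minimizing mean-shift segmentation
# (dynamic programming over all admissible break placements), plus the
# level-shift dummy construction used by the dummy-variable variant of
# the bounds regression.

seg_cost_matrix <- function(x) {
  # cost[i, j] = SSR of a constant fit on x[i..j]
  n <- length(x)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  cost <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    j <- i:n
    len <- j - i + 1
    s <- cs[j + 1] - cs[i]
    cost[i, j] <- (cs2[j + 1] - cs2[i]) - s^2 / len
  }
  cost
}

#' Locate sharp breakpoints by SSR-minimizing segmentation
#'
#' Global minimization of the segmented-mean sum of squared residuals
#' over all admissible placements of up to `m` breaks, by dynamic
#' programming. Each segment must contain at least `ceil(trim * T)`
#' observations. Breaks are retained sequentially: the j-th break is kept
#' only if it lowers the minimized SSR by more than `min_improve`
#' proportionally over the best (j-1)-break fit, so a constant series
#' yields an empty break set.
#'
#' @param x Numeric series.
#' @param years Integer year index aligned with `x` (default `1..T`);
#'   a break is labeled by the first year of the new regime.
#' @param m Maximum number of breaks.
#' @param trim Trimming fraction in \[0.1, 0.25\].
#' @param min_improve Proportional SSR-improvement retention threshold.
#' @param label Series label carried into the result.
#' @return A `break_set`: `break_years`, `break_index`, `m`, `trim`,
#'   `ssr` (minimized SSR at the retained break count),
#'   `ssr_by_breaks` (minimized SSR at exactly 0..m breaks), `label`.
#' @export
find_breaks <- function(x, years = seq_along(x), m = 3, trim = 0.15,
                        min_improve = 0.10, label = "") {
  n <- length(x)
  if (trim < 0.1 - 1e-12 || trim > 0.25 + 1e-12) stop("trim must lie in [0.1, 0.25]")
  h <- ceiling(trim * n)
  if (n < (m + 1) * h) stop("configuration error: infeasible m/trim for T = ", n)
  cost <- seg_cost_matrix(x)
  # dp[j+1, t] = minimal SSR of x[1..t] split into j+1 segments (j breaks)
  dp <- matrix(Inf, m + 1, n)
  dp[1, ] <- cost[1, ]
  back <- array(NA_integer_, dim = c(m + 1, n))
  for (j in seq_len(m)) {
    for (t in seq_len(n)) {
      if (t < (j + 1) * h) next
      # last segment starts at s, s-1 >= j*h, segment length t-s+1 >= h
      cand <- (j * h + 1):(t - h + 1)
      vals <- dp[j, cand - 1] + cost[cand, t]
      best <- which.min(vals)
      dp[j + 1, t] <- vals[best]
      back[j + 1, t] <- cand[best]
    }
  }
  # sequential retention; eps guards against counting floating-point
  # cancellation residue (e.g. on a constant series) as an improvement
  eps <- 1e-10 * max(1, sum(x^2))
  keep <- 0
  for (j in seq_len(m)) {
    if (!is.finite(dp[j + 1, n])) break
    if (dp[keep + 1, n] > eps &&
        dp[j + 1, n] < (1 - min_improve) * dp[keep + 1, n]) {
      keep <- j
    } else break
  }
  idx <- integer(0)
  if (keep > 0) {
    t <- n
    for (j in keep:1) {
      s <- back[j + 1, t]
      idx <- c(s, idx)
      t <- s - 1
    }
  }
  structure(list(label = label, break_years = years[idx], break_index = idx,
                 m = m, trim = trim, ssr = dp[keep + 1, n],
                 ssr_by_breaks = dp[, n]),
            class = "break_set")
}

#' @export
print.break_set <- function(x, ...) {
  cat("<break_set>", if (length(x$break_years) == 0) "(none)"
      else paste0("D", sprintf("%02d", x$break_years %% 100), collapse = ", "),
      sprintf(" [SSR %.6g]\n", x$ssr))
  invisible(x)
}

#' Level-shift dummy matrix from a break set
#'
#' One 0/1 column per break, equal to 1 from the break year onward
#' (level-shift convention; a break labeled 2007 starts the new regime
#' in 2007).
#'
#' @param breaks A `break_set` or a vector of break years.
#' @param years Integer year index of the sample.
#' @return Numeric matrix with `length(years)` rows and one column per
#'   break, named `D<yy>`.
#' @export
breaks_to_dummies <- function(breaks, years) {
  by <- if (inherits(breaks, "break_set")) breaks$break_years else breaks
  if (length(by) == 0) {
    return(matrix(numeric(0), nrow = length(years), ncol = 0))
  }
  if (any(by < min(years) | by > max(years))) stop("break year outside sample")
  out <- vapply(by, function(b) as.numeric(years >= b), numeric(length(years)))
  colnames(out) <- paste0("D", sprintf("%02d", by %% 100))
  out
}

#' Table of sharp breakpoints per panel variable
#'
#' @param panel A `country_panel`.
#' @param m Maximum breaks per series.
#' @param trim Trimming fraction.
#' @return Data frame with columns `variable` and `breakpoints`
#'   (formatted `"D07, D16"` strings, empty when no break is retained).
#' @export
panel_breaks <- function(panel, m = 3, trim = 0.15) {
  rows <- lapply(panel_variables(), function(v) {
    bs <- find_breaks(panel_series(panel, v), years = panel$years, m = m,
                      trim = trim, label = v)
    data.frame(variable = v,
               breakpoints = paste0("D", sprintf("%02d", bs$break_years %% 100),
                                    collapse = ", "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
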