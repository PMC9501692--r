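# Descriptive statistics and Jarque-Bera normality test.
# Skewness/kurtosis use the biased (population, 1/n) central-moment
# convention of the standard econometrics suites; kurtosis is non-excess.

#' Jarque-Bera statistic from skewness and kurtosis
#'
#' `JB = (n/6) (S^2 + (K - 3)^2 / 4)` with the p-value from the upper tail
#' of a chi-squared distribution with 2 degrees of freedom (for which the
#' survival function is exactly `exp(-JB/2)`).
#'
#' @param S Sample skewness (biased convention).
#' @param K Sample kurtosis, non-excess (normal = 3).
#' @param n Observation count (>= 4).
#' @return List with `statistic` and `p.value`.
#' @export
jarque_bera <- function(S, K, n) {
  if (n < 4) stop("need n >= 4")
  jb <- (n / 6) * (S^2 + (K - 3)^2 / 4)
  list(statistic = jb, p.value = stats::pchisq(jb, df = 2, lower.tail = FALSE))
}

#' Significance stars
#'
#' `***` below 1%, `**` below 5%, `*` below 10%, empty otherwise.
#'
#' @param p p-value (or vector).
#' @return Character vector of star marks.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.10, "*", "")))
}

#' Descriptive statistics for one series
#'
#' Mean, median, max, min, standard deviation (1/(n-1)), skewness and
#' kurtosis from biased central moments, and the Jarque-Bera normality
#' test.
#'
#' @param x Numeric series, n >= 4, nonzero variance.
#' @return A `descriptive_row` list: `mean, median, max, min, std_dev,
#'   skewness, kurtosis, jarque_bera, probability, n`.
#' @export
describe_series <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4) stop("need n >= 4")
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 <= 0 || !is.finite(m2) || m2 < 1e-30) {
    stop("degenerate series: zero variance")
  }
  S <- mean(d^3) / m2^1.5
  K <- mean(d^4) / m2^2
  jb <- jarque_bera(S, K, n)
  structure(list(mean = m, median = stats::median(x), max = max(x),
                 min = min(x), std_dev = stats::sd(x), skewness = S,
                 kurtosis = K, jarque_bera = jb$statistic,
                 probability = jb$p.value, n = n),
            class = "descriptive_row")
}

#' @export
print.descriptive_row <- function(x, ...) {
  cat(sprintf("mean %.6f  sd %.6f  S %.6f  K %.6f  JB %.6f%s (p = %.6f), n = %d\n",
              x$mean, x$std_dev, x$skewness, x$kurtosis, x$jarque_bera,
              significance_stars(x$probability), x$probability, x$n))
  invisible(x)
}

#' Descriptive table for a country panel
#'
#' One column per analysis variable, rows in the conventional order
#' Mean, Median, Max, Min, Std. Dev, Skewness, Kurtosis, Jarque-Bera,
#' Probability, Observations. The Jarque-Bera entry carries significance
#' stars at 10/5/1%.
#'
#' @param panel A `country_panel`.
#' @return Data frame with a `statistic` column plus one column per variable.
#' @export
describe_panel <- function(panel) {
  rows <- c("Mean", "Median", "Max", "Min", "Std. Dev", "Skewness",
            "Kurtosis", "Jarque-Bera", "Probability", "Observations")
  out <- data.frame(statistic = rows, stringsAsFactors = FALSE)
  for (v in panel_variables()) {
    d <- describe_series(panel_series(panel, v))
    out[[v]] <- c(
      sprintf("%.6f", c(d$mean, d$median, d$max, d$min, d$std_dev,
                        d$skewness, d$kurtosis)),
      paste0(sprintf("%.6f", d$jarque_bera), significance_stars(d$probability)),
      sprintf("%.6f", d$probability),
      as.character(d$n))
  }
  out
}
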