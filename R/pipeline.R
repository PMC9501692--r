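# Per-country orchestration: descriptives -> unit-root admissibility ->
# breaks -> Fourier frequency and lag selection -> bootstrap
# cointegration classification -> causality (long-run when cointegrated,
# short-run Granger otherwise) -> table-shaped reports.

#' Run configuration for the full per-country analysis
#'
#' @param k_grid Fourier frequency grid (default 0.1 .. 5.0 by 0.1).
#' @param max_lag Maximum ARDL lag order (default 2).
#' @param n_boot Bootstrap replications per null (default 5000; reduce
#'   for exploratory runs).
#' @param alpha Classification significance level, one of 0.01/0.05/0.10.
#' @param seed Master seed; per-(country, rotation, purpose) seeds are
#'   derived from it, so adding a country never perturbs existing
#'   results.
#' @param gate_alpha Significance level of the I(0)/I(1) admissibility
#'   gate (default 0.10).
#' @param force Skip the admissibility gate.
#' @return A `run_config` list.
#' @export
run_config <- function(k_grid = seq(0.1, 5.0, by = 0.1), max_lag = 2,
                       n_boot = 5000, alpha = 0.05, seed = 1,
                       gate_alpha = 0.10, force = FALSE) {
  stopifnot(length(k_grid) >= 1, alpha %in% c(0.01, 0.05, 0.10))
  structure(list(k_grid = k_grid, max_lag = max_lag,
                 n_boot = as.integer(n_boot), alpha = alpha,
                 seed = as.integer(seed), gate_alpha = gate_alpha,
                 force = force),
            class = "run_config")
}

#' Full analysis of one country panel
#'
#' Runs the complete pipeline: descriptive statistics; unit-root
#' admissibility (every series must be I(0) or I(1), or the run stops
#' unless `force`); sharp breakpoints (reported, not estimated in the
#' Fourier models); then, for each of the three dependent-variable
#' rotations: Fourier frequency by SSR grid search, lag orders by AIC,
#' bounds-test statistics, bootstrap critical values and classification.
#' A rotation classified as cointegrated triggers the long-run causality
#' test for each regressor and suppresses short-run tests for that
#' rotation; otherwise short-run Granger tests run at lag 1 with the
#' rotation's selected frequency.
#'
#' @param panel A `country_panel`.
#' @param config A `run_config`.
#' @return A `country_run` list: `country`, `descriptives`,
#'   `integration`, `breaks`, `rotations` (one entry per dependent
#'   variable), `config`.
#' @export
run_country <- function(panel, config = run_config()) {
  stopifnot(inherits(panel, "country_panel"), inherits(config, "run_config"))
  seed_for <- function(rotation, purpose) {
    derive_seed(config$seed, paste(panel$country, rotation, purpose, sep = "|"))
  }
  integ <- panel_integration(panel, max_lag = config$max_lag,
                             alpha = config$gate_alpha)
  orders <- vapply(integ, function(o) o$order, character(1))
  if (any(orders == "inadmissible") && !config$force) {
    stop("gate error: series not I(0)/I(1): ",
         paste(names(orders)[orders == "inadmissible"], collapse = ", "),
         " (use force to override)")
  }
  rotations <- list()
  for (dep in panel_variables()) {
    sel <- select_frequency(panel, dep, lags = c(1, 1, 1),
                            k_grid = config$k_grid)
    spec <- select_lags(panel, dep, k = sel$k, max_lag = config$max_lag)
    fit <- fit_ardl(panel, spec)
    stats_ <- compute_statistics(fit)
    cvs <- bootstrap_all_cvs(panel, spec, n_boot = config$n_boot,
                             alpha = config$alpha,
                             seed = seed_for(dep, "cv"))
    cls <- classify(stats_, cvs)
    long_run <- NULL
    short_run <- NULL
    if (cls$status == "cointegration") {
      long_run <- lapply(spec$independents, function(cz) {
        long_run_causality(panel, spec, cz, cls, n_boot = config$n_boot,
                           seed = seed_for(dep, paste0("lr:", cz)))
      })
      names(long_run) <- spec$independents
    } else {
      short_run <- lapply(spec$independents, function(cz) {
        granger_short_run(panel, effect = dep, cause = cz,
                          control = setdiff(spec$independents, cz),
                          lag = 1, k = sel$k)
      })
      names(short_run) <- spec$independents
    }
    rotations[[dep]] <- list(dependent = dep, k = sel$k, spec = spec,
                             fit = fit, statistics = stats_, cvs = cvs,
                             classification = cls, long_run = long_run,
                             short_run = short_run)
  }
  structure(list(country = panel$country, panel = panel,
                 descriptives = describe_panel(panel), integration = integ,
                 breaks = panel_breaks(panel), rotations = rotations,
                 config = config),
            class = "country_run")
}

#' @export
print.country_run <- function(x, ...) {
  cat(sprintf("<country_run> %s\n", x$country))
  for (r in x$rotations) {
    cat(sprintf("  %s | %s : k = %.1f, lags (%d,%d,%d), %s\n", r$dependent,
                paste(r$spec$independents, collapse = " | "), r$k, r$spec$p,
                r$spec$q1, r$spec$q2, status_label(r$classification$status)))
  }
  invisible(x)
}

fmt_fp <- function(F, p) sprintf("%.6f%s/[%.4f]", F, significance_stars(p), p)

#' Render table-shaped reports from a country run
#'
#' Produces the conventional report blocks: descriptive statistics,
#' level and first-difference unit-root grids, frequency/lag/breakpoint
#' summary, the cointegration table (frequency, AIC, F, F*, t1, t1*,
#' t2, t2*, status), and the causality section (long-run rows for
#' cointegrated rotations, short-run rows otherwise), each as a data
#' frame. With `dir` set, each block is also written as CSV and the
#' whole bundle as JSON.
#'
#' @param run A `country_run`.
#' @param dir Optional output directory.
#' @return Named list of data frames, invisibly when writing.
#' @export
render_tables <- function(run, dir = NULL) {
  stopifnot(inherits(run, "country_run"))
  coint <- do.call(rbind, lapply(run$rotations, function(r) {
    data.frame(
      country = run$country,
      period = paste0(min(run$panel$years), "-", max(run$panel$years)),
      rotation = paste(c(r$dependent, r$spec$independents), collapse = " | "),
      fourier_frequency = r$k,
      lag_spec = sprintf("(%d, %d, %d)", r$spec$p, r$spec$q1, r$spec$q2),
      AIC = r$fit$aic,
      F = r$statistics$F_overall, F_star = r$cvs$F_star,
      t1 = r$statistics$t1, t1_star = r$cvs$t1_star,
      t2 = max(abs(r$statistics$t2)), t2_star = r$cvs$t2_star,
      F2 = r$statistics$F2, F2_star = r$cvs$F2_star,
      status = status_label(r$classification$status),
      stringsAsFactors = FALSE)
  }))
  rownames(coint) <- NULL
  freq <- do.call(rbind, lapply(run$rotations, function(r) {
    data.frame(country = run$country,
               rotation = paste(c(r$dependent, r$spec$independents),
                                collapse = " | "),
               fourier_frequency = r$k,
               lag_spec = sprintf("(%d, %d, %d)", r$spec$p, r$spec$q1,
                                  r$spec$q2),
               stringsAsFactors = FALSE)
  }))
  rownames(freq) <- NULL
  caus <- list()
  for (r in run$rotations) {
    if (!is.null(r$long_run)) {
      for (cz in names(r$long_run)) {
        lr <- r$long_run[[cz]]
        caus[[length(caus) + 1]] <- data.frame(
          country = run$country, horizon = "long-run", effect = r$dependent,
          cause = cz, F = lr$F, p = lr$p, sign = NA_character_,
          display = fmt_fp(lr$F, lr$p), stringsAsFactors = FALSE)
      }
    }
    if (!is.null(r$short_run)) {
      for (cz in names(r$short_run)) {
        sr <- r$short_run[[cz]]
        caus[[length(caus) + 1]] <- data.frame(
          country = run$country, horizon = "short-run", effect = r$dependent,
          cause = cz, F = sr$F, p = sr$p, sign = sr$sign,
          display = fmt_fp(sr$F, sr$p), stringsAsFactors = FALSE)
      }
    }
  }
  caus <- if (length(caus)) do.call(rbind, caus) else
    data.frame(country = character(0), horizon = character(0),
               effect = character(0), cause = character(0), F = numeric(0),
               p = numeric(0), sign = character(0), display = character(0))
  tables <- list(descriptives = run$descriptives,
                 unit_root_level = unit_root_grid(run$panel),
                 unit_root_diff = unit_root_grid(run$panel, differenced = TRUE),
                 frequency = merge(freq, run$breaks, by = NULL)[
                   , c("country", "rotation", "fourier_frequency", "lag_spec",
                       "variable", "breakpoints")],
                 breaks = run$breaks,
                 cointegration = coint,
                 causality = caus)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      utils::write.csv(tables[[nm]],
                       file.path(dir, paste0(run$country, "_", nm, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(run_to_json_list(run, tables),
                         file.path(dir, paste0(run$country, "_bundle.json")),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(tables))
  }
  tables
}

# serializable summary of a run (used for the JSON bundle and the
# byte-identical determinism contract)
run_to_json_list <- function(run, tables = NULL) {
  rot <- lapply(run$rotations, function(r) {
    list(dependent = r$dependent, k = r$k,
         lags = c(r$spec$p, r$spec$q1, r$spec$q2),
         AIC = r$fit$aic,
         statistics = list(F = r$statistics$F_overall, t1 = r$statistics$t1,
                           F2 = r$statistics$F2,
                           t2 = as.list(r$statistics$t2)),
         critical_values = list(F_star = r$cvs$F_star,
                                t1_star = r$cvs$t1_star,
                                F2_star = r$cvs$F2_star,
                                t2_star = r$cvs$t2_star),
         status = status_label(r$classification$status),
         long_run = lapply(r$long_run, function(l) list(F = l$F, p = l$p)),
         short_run = lapply(r$short_run, function(s)
           list(F = s$F, p = s$p, sign = s$sign)))
  })
  list(country = run$country,
       period = paste0(min(run$panel$years), "-", max(run$panel$years)),
       seed = run$config$seed, n_boot = run$config$n_boot,
       alpha = run$config$alpha, integration =
         lapply(run$integration, function(o) o$order),
       rotations = rot)
}

#' Serialize a country run to a JSON string
#'
#' Deterministic under a fixed seed and configuration: identical runs
#' produce byte-identical JSON.
#'
#' @param run A `country_run`.
#' @return JSON string.
#' @export
run_to_json <- function(run) {
  jsonlite::toJSON(run_to_json_list(run), auto_unbox = TRUE, digits = NA)
}
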