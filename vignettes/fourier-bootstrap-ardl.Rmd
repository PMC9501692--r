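---
title: "Fourier bootstrap ARDL: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fourier bootstrap ARDL: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fardl)
```

## The problem

Annual indicators of economic activity, health expenditure and
employment are typically available for about twenty years per country.
At that scale the standard cointegration toolbox fails in three ways:
asymptotic bounds critical values are unreliable; structural change —
financial crises, health-system reforms — is almost certain within the
window but cannot be dated with confidence; and none of the three
variables can credibly be treated as exogenous to the others. The
package combines three remedies that the applied literature has
converged on: an ARDL bounds regression (robust to mixed I(0)/I(1)
regressors), bootstrap critical values (valid at small T and under
feedback between variables), and a low-frequency Fourier term (a
parsimonious proxy for an unknown number of smooth breaks).

## Model

For dependent variable $y$ and regressors $x_1, x_2$ the estimated
equation is

$$\Delta y_t = \beta_0 + \gamma_1 \sin(2\pi k t/T) + \gamma_2 \cos(2\pi k t/T)
 + \beta_1 y_{t-1} + \beta_2 x_{1,t-1} + \beta_3 x_{2,t-1}
 + \sum_{i=1}^{p}\varphi_i \Delta y_{t-i}
 + \sum_{i=1}^{q_1}\delta_i \Delta x_{1,t-i}
 + \sum_{i=1}^{q_2}\phi_i \Delta x_{2,t-i} + e_t.$$

A single sin/cos pair is used rather than a cumulative Fourier sum:
with T ≈ 20, one frequency already captures the gradual level shifts
the term is meant to absorb, and additional frequencies cost degrees of
freedom the sample does not have. The time index runs 1..T over the
levels sample, before lag trimming, so the Fourier phase does not
depend on the chosen lag orders.

Three hypotheses drive the cointegration decision: the overall
$F$ on $(\beta_1,\beta_2,\beta_3)$, the one-sided $t_1$ on $\beta_1$
(negative under error correction), and the joint $F_2$ on
$(\beta_2,\beta_3)$. Requiring all three blocks the two *degenerate*
patterns in which the overall $F$ is significant but either the lagged
regressors ($F_2$ insignificant, case #1) or the error-correction term
($t_1$ insignificant, case #2) does not actually enter — patterns that
a bare bounds $F$ test would misreport as cointegration.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `k_grid` | 0.1–5.0 by 0.1 | Fourier frequency grid (cycles per sample); selected by minimum SSR, ties to the smaller k. Sub-integer k allows permanent (non-recurring) shifts. |
| `max_lag` | 2 | lag-order bound; with T = 20 annual points, longer lags exhaust the sample. Orders chosen by AIC = n·ln(SSR/n) + 2·npar on the common sample implied by `max_lag`. |
| `n_boot` | 5000 | bootstrap replications for final tables; studies below use 199 per the usual minimum for 5% inference. |
| `alpha` | 0.05 | classification significance level (the reporting convention never states one; 5% is the conventional default and is exposed as a flag). |
| `gate_alpha` | 0.10 | level of the I(0)/I(1) admissibility gate — the most permissive conventional mark, since the gate exists to *exclude* I(2)-like series, not to adjudicate borderline ones. |
| `trim` | 0.15 | breakpoint segmentation trimming (minimum segment ≈ 3 years at T = 20). |

## The bootstrap

Critical values are empirical quantiles from a residual bootstrap under
each null. The null-restricted equation (tested level coefficients set
to zero, everything else retained) is estimated; its centered residuals
are resampled i.i.d.; the dependent variable is rebuilt recursively
from the restricted equation, observed initial values and the same
Fourier term. The regressors are not held fixed: each is regenerated
from its own marginal fit (intercept, Fourier pair, one lagged
difference). This *system* bootstrap preserves the feedback between
variables that the method is explicitly designed to allow; a
fixed-regressor bootstrap would quietly reimpose the exogeneity
assumption the approach exists to drop.

Numerical details: replicate seeds are indexed by replicate number, so
a failed replicate is dropped and counted without shifting later draws
(more than 5% failures aborts with an error); $F$-type critical values
are upper $(1-\alpha)$ quantiles, $t_1$ is lower-tail; the reported
$t_2^*$ is the $(1-\alpha)$ quantile of the max-|t| over the two lagged
regressors under the corresponding null, while classification uses the
joint $F_2$ — a per-coefficient t cannot distinguish "neither
regressor enters" from "their contributions overlap".

## The synthetic generator

`dgp_config()`/`generate()` produce the structures the method assumes:
independent driftful random walks (the no-cointegration null), an ECM
with adjustment $\lambda \in (-1,0)$ toward $\theta'x$, random walks
plus a level Fourier term, the two degenerate patterns, and a
`brics_like` kind whose drifts and innovation scales are set once to
the magnitudes of desk-scale annual data (log-GDP sample sd ≈ 0.5,
employment-rate sd ≈ 0.02 over T = 20; employment is generated as a
small-increment bounded walk started near its historical level).
Innovations are Gaussian throughout, consistent with the Jarque–Bera
framing of the descriptive stage. What the generator does **not**
emulate: cross-country correlation, measurement revisions,
heavy-tailed crisis innovations, or true World Bank values — passing
tests on these panels demonstrates that the machinery is calibrated
under its own assumptions, not that any particular country's data
satisfies them.

## Calibration studies and problem sizes

The test suite and `scripts/acceptance.R` recompute, from scratch:

* **size** of the bootstrap overall-F test on independent random walks —
  T = 50, 200 trials × 199 replications at α = 0.05;
* **power and recovery** under a cointegrated ECM (λ = −0.5, θ = (1, 0.5),
  T = 100, 100 trials): classification rate and the share of trials in
  which the long-run ratio $-\hat\beta_2/\hat\beta_1$ lands within
  ±0.15 of the planted coefficient;
* **frequency recovery** with a planted k = 2 level break at amplitude
  3σ, at the generator's native T = 20. The break enters the *levels*,
  so the differenced signal has amplitude ≈ 2·sin(πk/T)·γ, which
  *shrinks* as T grows — desk-scale samples are where the Fourier proxy
  is both needed and detectable, and a longer panel would weaken, not
  strengthen, this check;
* **Granger size** under an independent cause (T = 100, 200 trials);
* exact **oracle equivalences**: QR least squares vs. the
  normal-equations solution, dynamic-programming break SSR vs.
  exhaustive enumeration, SSR-form F vs. the Wald quadratic form.

These sizes keep each study to roughly a minute on one CPU while
leaving the binomial noise of the estimated rates well inside the
asserted bands.

## Numerical choices and degenerate inputs

* OLS is QR-based with a hard full-rank requirement; collinear designs
  are refused naming the offending columns rather than silently
  dropped.
* Frequency ties break toward the smaller k; lag-order ties toward
  fewer total lags, then lexicographically — deterministic output under
  a fixed seed is a contract (`run_to_json()` is byte-stable).
* AIC comparisons across lag orders are made on the common sample
  implied by `max_lag`; the winning spec is refit on its maximal
  sample. With AIC's 2-per-parameter penalty and 26 richer candidates,
  the no-lag model under white-noise differences is the modal but not
  near-certain choice (≈ 40%); a BIC-style penalty would be more
  parsimonious but the AIC rule is the convention this literature
  follows.
* Breakpoint retention requires a 10% proportional SSR improvement
  *and* an absolute improvement above a scale-relative epsilon, so a
  constant series yields no breaks despite floating-point cancellation.
* MacKinnon response-surface p-values are clamped to
  [10⁻⁶, 1 − 10⁻⁶]: outside the table range the decision is
  unambiguous and an interior p keeps downstream star logic total.
* A zero-variance series is refused by `describe_series()`; years with
  gaps are refused by `read_panel()` (no interpolation at T = 20).

## Design decisions that were genuinely open

* **Breaks vs. Fourier in estimation.** Sharp breakpoints (SSR-minimizing
  mean-shift segmentation) are located and reported, but the estimated
  models use the Fourier term only — the Fourier function is introduced
  precisely to replace the dummy-variable approach, and at T = 20
  spending one column per dummy is the worse bargain. `ardl_spec()`
  accepts a `dummies` argument for users who want the dummy variant.
* **Full Bai–Perron inference was deliberately not implemented**: with
  breakpoints serving as descriptive reporting, sup-F asymptotics on 20
  observations would lend the dates more authority than they can bear.
* **Admissibility level.** The I(0)/I(1) gate uses 10%: the gate's
  purpose is excluding clearly I(2) series, and the most permissive
  printed level does that with the fewest false exclusions.
* **Long-run causality exclusion set** defaults to the lagged level
  *plus* the cause's lagged differences (`levels_only = FALSE`): a
  variable whose level is excludable but whose differences still enter
  is not "non-causal" in any economically meaningful sense.
* **Short-run Granger p-values** come from the F distribution by
  default (the conventional reporting), with `bootstrap_p = TRUE`
  available for coherence with the rest of the inference.

## Known limitations

The method handles exactly three variables — the rotation structure and
the degenerate-case taxonomy do not generalize beyond one dependent and
two regressors without reworking the hypotheses. Fourier frequency is
selected by SSR on a discrete grid, not estimated with uncertainty; the
reported k inherits no standard error. At T = 20 every test in the
pipeline is low-powered, and the bootstrap corrects size, not power.
The unit-root pre-tests use asymptotic MacKinnon p-values, which at
T = 20 are themselves approximations — this is why the gate is
deliberately permissive.

## A complete run

```{r example, eval = FALSE}
panel <- fixture_brics()[["BRA"]]
run <- run_country(panel, run_config(n_boot = 5000, seed = 1))
tabs <- render_tables(run, dir = "report")
tabs$cointegration
```
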