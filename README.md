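# fardl — Fourier bootstrap ARDL cointegration and causality analysis

`fardl` is an R package for small-sample cointegration and causality
analysis of annual macro-health time series: log GDP per capita (LGDP),
log health expenditure per capita (LHEP) and the employment rate
(EMP = 1 − unemployment rate). It is aimed at health-economics and
applied time-series researchers who face the classic problem of this
literature: roughly twenty annual observations per country, likely
structural change, and regressors that cannot be assumed exogenous.

## The method

For a dependent variable (say HEP) and two regressors, the package
estimates the conditional error-correction regression with a
single-frequency Fourier term standing in for an unknown number of
smooth structural breaks:

```
ΔHEPₜ = β₀ + γ₁ sin(2πkt/T) + γ₂ cos(2πkt/T)
        + β₁ HEPₜ₋₁ + β₂ GDPₜ₋₁ + β₃ EMPₜ₋₁
        + Σ φᵢ ΔHEPₜ₋ᵢ + Σ δᵢ ΔGDPₜ₋ᵢ + Σ ∅ᵢ ΔEMPₜ₋ᵢ + eₜ
```

* the frequency k is chosen on the grid 0.1, 0.2, …, 5.0 by minimum SSR;
* lag orders (p; q₁, q₂) are chosen by minimum AIC;
* three bounds-test statistics are computed — the overall F on
  (β₁, β₂, β₃), the t ratio t₁ on β₁, and the joint F₂ on (β₂, β₃);
* their critical values come from a residual bootstrap under each null
  (the dependent variable is regenerated recursively from the restricted
  equation; the regressors from their own marginal fits, so feedback
  between variables is preserved);
* the pattern of significance classifies the relation: all three
  significant → cointegration; F and t₁ only → degenerate case #1;
  F and F₂ only → degenerate case #2; anything else → no cointegration.

When a rotation is cointegrated, long-run causality is tested by
bootstrap exclusion of a regressor's level and lagged differences from
the error-correction equation; otherwise short-run Granger causality is
tested in first differences with the Fourier term retained.

Around that core the package provides descriptive/Jarque–Bera tables,
DF/ADF/Phillips–Perron unit-root pre-tests (MacKinnon response-surface
p-values) with the I(0)/I(1) admissibility gate, SSR-minimizing sharp
breakpoint location, and a synthetic-data generator so the whole
pipeline runs without any external download.

## Worked example

```r
library(fardl)

panel <- fixture_brics()[["BRA"]]          # synthetic, T = 20, 2000-2019
run   <- run_country(panel, run_config(n_boot = 199, seed = 42))
print(run)
```

```
<country_run> BRA
  LGDP | LHEP | EMP : k = 5.0, lags (1,1,2), Cointegration
  LHEP | LGDP | EMP : k = 2.5, lags (1,2,0), No-cointegration
  EMP | LGDP | LHEP : k = 1.4, lags (2,1,2), Cointegration
```

Each line is one dependent-variable rotation: the selected Fourier
frequency, the AIC-chosen lag orders, and the bootstrap classification.
`render_tables(run)` expands this into the full report blocks —
descriptives, unit-root grids, frequency/breakpoint summary, the
cointegration table (F, F*, t₁, t₁*, t₂, t₂*, status) and the causality
section with `F***/[p]` formatting:

```r
tabs <- render_tables(run)
tabs$cointegration[, c("rotation", "fourier_frequency", "F", "F_star", "status")]
```

```
           rotation fourier_frequency         F    F_star           status
1 LGDP | LHEP | EMP               5.0  7.610621  6.413261    Cointegration
2 LHEP | LGDP | EMP               2.5  5.160769  9.445937 No-cointegration
3 EMP | LGDP | LHEP               1.4 15.747408 11.113596    Cointegration
```

An F above its bootstrap critical value F* (together with significant
t₁ and F₂) supports a long-run equilibrium among the three series; the
causality block then reports which regressor drives it, or — absent
cointegration — which short-run Granger effects are present.

Synthetic data on the raw indicator schema (so it is interchangeable
with real CSV input of columns `country,year,gdp_pc,he_pc,unemp_pct`):

```r
write_raw_csv(fixture_brics(), "panel.csv")
panel <- build_panel(read_panel("panel.csv", "CHN"))
```

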