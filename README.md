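# pippk

Population pharmacokinetics and dosing simulation for piperacillin in
patients with Gram-negative bloodstream infection.

Beta-lactam efficacy tracks the fraction of the dosing interval with
unbound drug concentration above the pathogen's MIC (fT>MIC; ≥50% is the
classic piperacillin target), while sustained high unbound troughs are
associated with neurotoxicity and nephrotoxicity. Piperacillin is renally
cleared, so the same dose can under-expose a patient with preserved renal
function and accumulate dangerously in renal impairment. `pippk` provides
the complete analysis pipeline for this problem, for pharmacometricians
and infectious-disease researchers working from sparse
therapeutic-drug-monitoring data:

* **Structural model** — one-compartment kinetics with zero-order infusion
  input and a renal covariate on clearance,
  `CL (L/h) = intercept + slope × CrCl (L/h)`, `ke = CL/Vc`, solved in
  closed form by superposition; exact analytic time-above-threshold and
  window minima (no grids).
* **Nonparametric population estimation** (`npag_fit()`) — an
  adaptive-grid nonparametric maximum-likelihood estimator of the mixing
  distribution (weighted support points) with the piperacillin assay-error
  model `SD = γ(0.4388 + 0.027·C)` mg/L, γ re-estimated by likelihood;
  posterior (Bayesian-step) individual estimates; forward-inclusion
  covariate screening by ΔLL.
* **Diagnostics** — observed/predicted tables and R², bias and
  imprecision, weighted residuals, normalised prediction distribution
  errors (NPDE) with Shapiro–Wilk summary, and visual predictive check
  bands.
* **Monte Carlo dosing simulation** (`simulate_pta()`) — six 4 g regimens
  (0.5 h and 4 h infusions, with and without a loading dose, q8h and
  q12h) evaluated across doubling MIC dilutions 0.0625–256 mg/L in
  normal (CrCl 90–129 mL/min) and severe/kidney-failure (5–29 mL/min)
  cohorts, plus day-2 unbound-trough toxicodynamics against published
  thresholds (157.2 / 361.4 / 452.65 mg/L).
* **Synthetic cohorts** (`generate_cohort()`, `simulate_dataset()`) — a
  generator emulating the sparse sampling design (1, 4, 6, 8 h after the
  infusion start at steady state, LLOQ 1 mg/L) so every stage is testable
  without patient data.
* **Renal arithmetic** — Cockcroft–Gault, CKD-EPI (2009) and KDIGO GFR
  categories.

Functions take data frames first and return tibbles; fitted objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

A bundled synthetic dataset (27 virtual subjects, 108 sparse samples,
generated by the package's own cohort simulator — no patient data) runs
the whole pipeline:

```r
library(pippk)

dat <- read_dataset(system.file("extdata", "synthetic_cohort27.csv",
                                package = "pippk"))
#> read 269 rows, 27 subjects, 108 observations

fit <- npag_fit(dat, control = npag_control(n_grid = 256))
fit
#> Nonparametric population PK fit
#>   subjects: 27, observations: 104
#>   support points: 33, gamma: 0.5989
#>   log-likelihood: -265.7734 (16 cycles, converged: TRUE)

weighted_summary(fit$distribution)
#> # A tibble: 3 × 4
#>   parameter  mean    sd median
#>   <chr>     <dbl> <dbl>  <dbl>
#> 1 intercept  3.11  2.50   1.96
#> 2 slope      2.00  2.35   1.59
#> 3 vc        29.4  21.4   23.2
```

The fit summarises the population as weighted support points: here the
typical clearance intercept is ≈3 L/h with a slope of ≈2 on CrCl (L/h),
and a central volume around 29 L (104 of 108 observations entered the
likelihood; the rest fell below the 1 mg/L quantification limit). Dosing
consequences, simulated semi-parametrically from the fitted model:

```r
sim <- simulate_pta(population = fit$distribution, n = 2000, seed = 1)
dplyr::filter(sim$pta, mic %in% c(8, 32))
#> # A tibble: 12 × 5
#>    regimen category   mic pta_pct band
#>    <chr>   <chr>    <dbl>   <dbl> <chr>
#>  1 d1      normal       8    66.5 intermediate
#>  2 d1      normal      32    28.5 poor
#>  3 d2      normal       8    94.8 optimal
#>  4 d2      normal      32    42.4 poor
#>  5 d3      normal       8    96.6 optimal
#>  6 d3      normal      32    59.6 intermediate
#>  ...
```

At the susceptibility breakpoint (MIC 8 mg/L) the short 0.5 h infusion
(`d1`) attains the 50% fT>MIC target in only 66% of normal-renal-function
patients, while the 4 h extended infusion (`d2`) and its loading-dose
variant (`d3`) are optimal (≥90%) — the extended-infusion advantage that
motivates this kind of analysis. `sim$toxicity` tabulates the day-2
probability that the unbound trough exceeds each toxicity threshold, and
`autoplot(sim)` draws the banded attainment heatmap.

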