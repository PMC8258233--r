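# duosurvey

Dual-method bird survey analysis: coverage-standardised diversity,
family-level detection modelling, method-bias tests and protocol
cost-efficiency — for monitoring programs that pair **point counts (PC)**
with **autonomous recording units (ARUs)**.

## The problem

Point counts and ARUs do not sample a bird community identically: a
trained observer sees silent raptors and ground-tyrants that a recorder
can never detect, while a recorder in dense montane forest calmly
transcribes the dawn chorus that overwhelms an observer. When survey
methods are biased differently across communities, diversity comparisons
and monitoring designs built on a single method can mislead. `duosurvey`
implements a complete comparative framework around the *site-survey*
(one 6-min PC or one analysed 6-min ARU window):

- **Diversity** (`build_incidence`, `estimate_at_coverage`, `chao2`):
  incidence-based Hill numbers (richness `q = 0`, exponential Shannon
  `q = 1`) rarefied/extrapolated to equal sample coverage (default 97%),
  with Chao2 asymptotes, unit-resampling bootstrap SEs, and the 84%-CI
  overlap rule (`z = 1.4051`) for method differences. Estimators follow
  the incidence-frequency rarefaction/extrapolation framework of Chao &
  Jost and Chao et al.; see `vignette("methods")` for the formulas.
- **Occupancy/detection** (`build_history`, `occ_fit`, `select_model`):
  single-season occupancy models per family —
  `psi ~ elevation + canopy residual`,
  `p ~ wind + hour + hour² + date + date² + canopy + canopy² + Markov lag`
  plus method effects — ranked by `QAIC = −2 logL/ĉ + 2(K+1)` over a
  nine-model candidate set, with ĉ from a parametric goodness-of-fit
  bootstrap and √ĉ-inflated prediction intervals.
- **Method bias** (`single_method_species`, `fisher_exact`,
  `method_bias`): exact two-sided tests of detection frequency by method
  for species only one method records.
- **Protocol efficiency** (`protocol_effort_hours`,
  `bootstrap_protocol_richness`, `efficiency_frontier`): a shared-visit
  time-cost model (ARU 40 min/site + 9 min/sample; PC 20 + 7; up to two
  PCs free during ARU visits) and bootstrapped species returns for every
  protocol from 1 PC to 3 PC + 15 ARU samples per site, with the Pareto
  frontier of percent-of-community per hour.
- **Synthetic data** (`design_config`, `species_profiles`,
  `generate_dataset`, `generate_scenario`): a generator reproducing a
  two-region mountain study design (montane/subalpine/alpine transects,
  3 PC rounds, 2–4 ARU days × 5 hourly windows) down to its exact
  site-survey tallies, with zero-vocalisation species, quadratic
  covariate effects and within-day Markov autocorrelation.
- **Pipeline** (`run_pipeline`, `inst/cli/duosurvey.R`): one-command
  simulate → diversity → occupancy → compare → efficiency with per-stage
  seeds, CSV outputs and a byte-stable `summary.json`.

## Worked example

```r
library(duosurvey)
d <- generate_scenario("Chile", seed = 1)
d
#> <survey_dataset>
#>   sites:      150 (Chile)
#>   surveys:    900 site-surveys (PC 450, ARU 450)
#>   detections: 1372 records, 36 species, 16 families

inc_pc  <- build_incidence(d, "alpine", pooling = "pc")
inc_aru <- build_incidence(d, "alpine", pooling = "pooled_morning")
est_pc  <- estimate_at_coverage(inc_pc,  0, 0.97, B = 200, seed = 2)
est_aru <- estimate_at_coverage(inc_aru, 0, 0.97, B = 200, seed = 2)
est_pc
#> <hill_estimate> alpine/PC q=0: 24.30 (se 2.90) at t=76 (extrapolated, coverage 0.970)
#>   84% CI [20.23, 28.37]  95% CI [18.62, 29.98]
est_aru
#> <hill_estimate> alpine/ARU(pooled) q=0: 15.06 (se 0.97) at t=155 (extrapolated, coverage 0.970)
#>   84% CI [13.70, 16.43]  95% CI [13.16, 16.97]
compare_methods(est_pc, est_aru)
#> [1] TRUE
```

At equal 97% coverage, point counts see significantly more alpine
species than pooled ARUs in this southern-community scenario — the 84%
intervals are disjoint. The mechanism is the silent guild:

```r
nrow(single_method_species(d)$pc_only)   # species ARUs never record
#> [1] 11
capture_summary(d, "pooled_morning")$mean_pct  # % of known community, ARU
#> [1] 59.4...
capture_summary(d, "pc")$mean_pct              # % of known community, PC
#> [1] 65.3...
```

And the time-cost model shows why a couple of point counts are cheap to
add: one PC round at 10 sites costs 4.5 h, while ten ARU samples/site
cost 22 h.

```r
protocol_effort_hours(1, 0, 10)                        # 4.5
format_effort_hours(protocol_effort_hours(0, 10, 10))  # 22
```

Full run with outputs under `out/`:

```r
run_pipeline(run_config(scenario = "Chile", out_dir = "out"))
```

or from the shell:

```sh
Rscript inst/cli/duosurvey.R pipeline --scenario Chile --out out --seed 1
```

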