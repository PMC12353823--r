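# excohort

External-control cohort analysis for single-arm trials, built around the
functional-outcome methodology of a phase 1b gene-therapy study in
ambulatory Duchenne muscular dystrophy (DMD).

When a trial has no concurrent placebo arm, placebo participants from
earlier interventional trials can serve as an external comparator — after
eligibility filtering and propensity-score reweighting. `excohort`
implements that chain end to end:

* **Cohort derivation** — the eligibility rules (age 4–12 y inclusive,
  NSAA-item ambulation, rise-from-floor ≤ 7 s, LVEF ≥ 55% data permitting,
  ≥ 6 months stable steroids, non-missing NSAA totals at baseline and
  1 year), plus the imputation conventions (missing steroid start = 6
  months before screening; assay values below LLOQ = LLOQ/2).
* **IPTW-ATT weighting** — logistic propensity score on four prespecified
  covariates; treated weight 1, external weight the odds of treatment
  `P/(1−P)`; external weights capped at their 95th percentile and
  renormalized; standardized-mean-difference balance diagnostics.
* **Effect estimation** — weighted least squares of the 1-year change on
  treatment (IPTW), a doubly robust variant adding the propensity
  covariates to the weighted outcome model (AIPW-style), and a stratified
  bootstrap that refits the whole pipeline per replicate: bootstrap s.e.,
  bias-corrected 95% percentile interval, one-sided empirical p-value.
* **NSAA skill analytics** — skills gained (baseline 0 → 1/2 at 1 year) and
  skills improved-or-maintained per participant and per arm.
* **Dystrophin quantification** — 99th-percentile positivity threshold over
  pooled baseline fiber stain densities, strict-exceedance positive-fiber
  percentages, two-section biopsy averaging, LC–MS percent-of-normal.
* **Synthetic data** — a generator with known ground truth (`sim_config()`,
  `generate_study()`) emulating the trial's structure: 16 treated, a
  156-participant external pool of whom ≈ 59 pass selection, confounded
  baseline covariates, true ATT 3.4 NSAA points over a −2.7 control drift.

The model, in brief: for participant *i* with baseline covariates *x*
(age, NSAA total, rise velocity, 10-m velocity), the propensity
*P(treated | x)* is logistic; ATT weights are W = 1 (treated) or
P/(1−P) (external); the effect is the treated-vs-external difference of
weighted mean 1-year changes, with inference from B within-arm bootstrap
resamples of the full pipeline.

## Worked example

```r
library(excohort)

# the in-built deterministic item-level example
fx <- worked_example_fixture()
skill_summary(fx$nsaa_items)
#> <skill_summary>
#>           arm  n n_with_baseline_zero n_gained_ge1 pct_gained median_improved_or_maintained
#>      external 59                   17            5      29.41                            12
#>  treated_high 16                    7            5      71.43                            16

# a synthetic study through the full pipeline
study <- generate_study(sim_config(seed = 1))
report <- run_pipeline(study, seed = 1, B = 500)
report$balance
#> <balance_table> standardized mean differences
#>            covariate smd_unweighted smd_weighted
#>        age_screening        -0.0147      -0.0009
#>  nsaa_total_baseline         0.4432       0.0138
#>        rise_velocity         0.2705       0.0927
#>       run10_velocity         0.5150       0.1164
#>   max |SMD|: unweighted 0.5150, weighted 0.1164
```

Reading the output: 71.4% of treated participants with at least one
baseline-zero NSAA item gained a skill versus 29.4% of external controls;
weighting shrinks the covariate imbalance (|SMD|) from ≈ 0.5 to ≈ 0.1. The
battery table in `report$battery` lists, per endpoint, the unadjusted
per-arm changes and the weighted LS means, difference, bootstrap s.e.,
bias-corrected CI and one-sided p.

A thin CLI over the same functions lives at
`inst/scripts/excohort-cli.R` (`simulate`, `run-all`).

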