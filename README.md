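# progenrich

Progression subtyping and prognostic enrichment analysis for dementia
trials, in R.

Early Alzheimer's-disease dementia patients progress at very different
rates, which dilutes treatment effects and inflates the sample sizes of
trials with cognitive endpoints. This package implements, end to end, the
statistical pipeline behind classifier-based *prognostic enrichment*:

1. **Trajectory clustering** — a variational deep-embedding model (dense
   encoder/decoder, mixture-of-Gaussians latent prior, masked Gaussian
   likelihood) clusters multivariate symptom trajectories (MMSE, CDR-SB,
   FAQ on a 0–36 month grid) into *slow* and *fast* progressors while
   imputing missing visits implicitly. The cluster number is selected by
   prediction strength against a profile-matched random-clustering null,
   and assignments are stabilized by consensus over repeated runs.
2. **External validation** — a trained model transfers to an independent
   cohort (shared scaler, mask padding), and assignment concordance is
   quantified after semantic or optimal label alignment.
3. **Baseline classification** — XGBoost predicts the progression
   subgroup from cross-sectional data at diagnosis under 10×-repeated
   nested stratified cross-validation (AUC-ROC / AUC-PR).
4. **Enrichment emulation** — recruiting only patients whose predicted
   probability of fast progression exceeds a threshold τ enriches the
   trial cohort; a uniform 27% relative treatment effect on the 24-month
   CDR-SB change of worseners yields Cohen's d, and the required sample
   size per arm solves the two-sided two-sample t-test power condition
   (90% power, α = 0.05) via the noncentral-t distribution:
   the reduction is `1 − n(τ)/n(unselected)`.
5. **Trial economics** — screening ($6,957/patient), treatment
   ($26,500/patient/year, 2 years, half the cohort), and ARIA monitoring
   ($128 + 4 × $353 per case) costs compare a conventional against an
   enriched trial, with adverse events scaled by recruitment under
   ceiling rounding.

Because the underlying cohort studies (ADNI, NACC) are access-restricted,
the package ships a synthetic-cohort generator (`generate_cohort()`,
`apply_dropout()`, `inject_missingness()`) that reproduces the published
subgroup structure — 63%/37% fast/slow prevalence, the printed 36-month
score changes and baseline distributions, a 9.33 percentage-point APOE ε4
carrier enrichment in fast progressors, and a median 2-year follow-up —
so the whole pipeline is testable offline. See the methods vignette
(`vignettes/methods.Rmd`) for the models, defaults and their rationale.

## Worked example

```r
library(progenrich)

# a synthetic cohort at the published effect sizes
cfg <- cohort_config(n_patients = 300, seed = 42)
gen <- generate_cohort(cfg)
cohort <- inject_missingness(gen$cohort, 0.1, seed = 43)

# cluster trajectories, consensus over repeats
tensor <- as_trajectory_tensor(cohort)
cc <- consensus_cluster(tensor, k = 2, training_config(seed = 5),
                        repeats = 10)
cc$assignment
#> <assignment> 300 patients, k=2 (fast=193, slow=107)
adjusted_rand_index(cc$assignment$label, gen$cohort$truth$true_label)
#> [1] 1

# the published APOE e4 carrier gap from its printed inputs
prop_diff_ci(0.4842, 1078, 0.5775, 1716)
#> # A tibble: 1 x 6
#>   variable   estimate ci_low ci_high significant degenerate
#>   <chr>         <dbl>  <dbl>   <dbl> <lgl>       <lgl>
#> 1 proportion     9.33   5.54    13.1 TRUE        FALSE

# power analysis: patients per arm at d = 0.5, 90% power, alpha 0.05
required_n_per_arm(0.5)
#> [1] 86

# the enrichment-trial cost ledger from published unit costs and counts
arms <- clarity_ad_arms()
build_cost_report(arms$conventional, arms$enriched)
#> <cost_report>
#> # A tibble: 9 x 4
#>   item                   conventional enriched difference
#>   <chr>                         <dbl>    <dbl>      <dbl>
#> 1 screened_patients              5967     6834        867
#> 2 screening_costs            41512419 47544138    6031719
#> 3 recruited_patients             1796     1135       -661
#> 4 treatment_costs            47594000 30077500  -17516500
#> 5 total_adverse_events            593      375       -218
#> 6 serious_adverse_events          227      144        -83
#> 7 aria_cases                      278      176       -102
#> 8 aria_monitoring_costs        428120   271040    -157080
#> 9 total_costs                89534539 77892678  -11641861
#> percent saving: 13.0%
```

The consensus assignment recovers the planted subgroups exactly at these
conditions (adjusted Rand index 1) with their ~63% fast-progressor
share; the cost ledger shows
an enrichment trial recruiting 1,135 instead of 1,796 patients saves
about 13% of total costs despite screening 867 additional people.

`run_pipeline(pipeline_config(out_dir = "out"))` chains every stage
(simulate → cluster → characterize → classify → enrich → economics) and
writes CSV/JSON artifacts plus a manifest.

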