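# adherekit

Medication adherence and persistence phenotyping from pharmacy purchase
registers, for pharmacoepidemiologists working with dispensing data
(statins, blood-pressure medications, antiplatelets, direct oral
anticoagulants, breast cancer endocrine therapy).

Dispensing registers record purchases, not consumption. `adherekit`
reconstructs per-person purchase trajectories and derives the two standard
refill-based drug-taking phenotypes:

* **Adherence** — the medication possession ratio

  ```
  MPR = days of supply during observation period / days in observation period
  ```

  with the full trajectory rule set: last-purchase exclusion, treatment-break
  exclusion (≥ 150 tablet-free days), leftover-tablet truncation at
  formulation switches, dose-distribution-service removal, ≥ 1-year
  eligibility, and the MPR > 1.1 stockpiling cap. Finnish-register and
  Estonian-register rule dialects are both implemented.

* **Persistence** — a binary early-discontinuation phenotype: ≥ 12 months of
  purchases versus stopping after the first purchase, with a 2-year
  right-censoring buffer before end of follow-up (death, emigration, or end
  of registry), plus a sensitivity definition (stopping within one year,
  any number of purchases).

Around the phenotypes sit the pieces of a full register study: a synthetic
register generator with known ground truth (behavioural archetypes, injected
covariate effects), baseline risk-factor derivation (secondary prevention,
Quan/Charlson comorbidity index, polytherapy), multivariable logistic and
linear association models reported as odds ratios and percentage change in
adherence (coefficient × 100/1.1), and an analytic power calculation for
single-variant genetic association tests.

## Worked example

Simulate a statin cohort with a known disadvantage injected on the
social-assistance covariate (−0.03 MPR, −0.5 persistence log-odds,
prevalence 0.3), phenotype it, and fit the association models:

```r
library(adherekit)

cfg <- sim_config(n_persons = 2000, seed = 7,
                  covariate_effects = list(
                    social_assistance = c(adherence_effect = -0.03,
                                          persistence_logodds_effect = -0.5)),
                  covariate_prevalences = c(social_assistance = 0.3))
coh <- simulate_cohort(cfg)
ph  <- build_phenotypes(coh$purchases, coh$persons, coh$diagnoses,
                        "statins", adherence_ruleset())
summarize_cohort(ph, coh$purchases)
#>   medication_class n_individuals total_purchases prop_persistent mean_adherence
#> 1          statins          1844           56738       0.9387202      0.9120206
#>   sd_adherence prop_good_adherers mean_treatment_length_years
#>   0.05359908          0.9861352                    8.635355

d <- merge(ph, coh$persons, by = "person_id")
d$year_of_birth <- as.integer(format(as.Date(d$birth_date), "%Y"))

fit_persistence(d, c("social_assistance", "urban", "language_fi_sv"))
#> Multivariable logistic (persistence) model, n = 1844
#>               term odds_ratio ci_low ci_high p_value
#>  social_assistance      0.592  0.402   0.872 0.00799
#>              urban      0.972  0.634   1.490 0.89600
#>     language_fi_sv      1.000  0.429   2.350 0.99500
#>      year_of_birth      1.010  0.995   1.020 0.25700
#> McFadden pseudo-R2: 0.0094

fit_adherence(d, c("social_assistance", "urban", "language_fi_sv"))
#> Multivariable linear (adherence) model, n = 1731
#>               term pct_change ci_low ci_high  p_value
#>  social_assistance   -2.85000 -3.330 -2.3700 4.06e-30
#>              urban   -0.23700 -0.732  0.2580 3.48e-01
#>     language_fi_sv   -0.12100 -1.090  0.8520 8.08e-01
#>      year_of_birth    0.00143 -0.013  0.0158 8.45e-01
#> adjusted R2: 0.0709
```

Reading the output: the cohort looks like a register statin cohort (94%
persistent, mean adherence 0.91, 9-year treatments). The fitted odds ratio
0.59 [0.40–0.87] covers the injected exp(−0.5) = 0.61, and the fitted
−2.85% [−3.33, −2.37] change in adherence covers the injected
100 × (−0.03)/1.1 = −2.73% — the pipeline recovers ground truth end to end,
from raw purchase dates through trajectory rules to model coefficients.

The one-shot pipeline does all of the above plus covariate derivation and a
run manifest:

```r
run_pipeline(list(n_persons = 2000, seed = 7), "out/")
```

A thin CLI wrapper lives at `inst/cli/adherekit.R`
(`run` / `simulate` / `phenotype` / `summarize` / `power` subcommands).

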