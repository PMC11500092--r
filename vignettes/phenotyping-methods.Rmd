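---
title: "Trajectory-based adherence and persistence phenotyping: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory-based adherence and persistence phenotyping: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adherekit)
```

## The problem

Pharmacy dispensing registers record every reimbursed purchase — person,
date, ATC code, packages — but not whether tablets were actually taken.
Refill-based phenotyping turns these purchase streams into two standard
drug-taking phenotypes for medications that require long-term, regular
therapy (statins, blood-pressure medications, antiplatelets, direct oral
anticoagulants, breast cancer endocrine therapy):

* **Adherence** — the medication possession ratio (MPR),
  $$\mathrm{MPR} = \frac{\text{days of supply during observation period}}
                        {\text{days in observation period}},$$
  where days of supply is total tablets purchased divided by an assumed
  daily dose (one tablet/day for all five classes), and the observation
  period is the sum of intervals between consecutive purchases considered
  in the trajectory.
* **Persistence** — a binary early-discontinuation phenotype: continuing
  the treatment for at least 12 months versus stopping after the first
  purchase.

## Trajectory reconstruction rules

`build_trajectory()` and friends implement the reconstruction as a single
pooled ratio per person and medication class:

* Purchases are sorted by date; same-day purchases of the same formulation
  (full 7-character ATC code) are merged by summing tablets; same-day
  purchases of different formulations are ordered lexicographically by ATC
  code — a deterministic tie-break.
* The **last purchase** is always excluded: its consumption interval is
  unobserved.
* A purchase followed by at least **150 tablet-free days**
  (interval minus days of supply) is a **treatment break**. Break purchases
  are excluded from both the numerator and the denominator; the trajectory
  is not split into separately averaged segments. The pooled-ratio reading
  is the simplest one consistent with dropping breaks from the calculation,
  and it makes the exclusion exactly "this purchase contributes neither
  tablets nor time".
* At a **formulation switch** arriving before supply exhaustion, leftover
  tablets of the previous formulation are discarded
  (`effective_tablets = interval × daily dose`). Same-formulation surplus
  carries over — which is why the MPR can exceed 1.
* **Dose-distribution-service** purchases (biweekly machine-dispensed
  batches) distort refill intervals and are dropped with their own audit
  reason.
* Eligibility for the adherence analysis: first-to-last purchase span of at
  least 365 days (computed before the last-purchase exclusion — "at least
  one year of purchases" reads most naturally on the raw trajectory), at
  least two included purchases, and MPR ≤ 1.1. Values above 1.1 indicate
  stockpiling/overbuying and exclude the person. Reason precedence when
  several apply: span, then purchase count, then the cap — precedence
  affects the audit label only, never membership.

Two **rule dialects** are provided. The Finnish-register dialect is the
default. The Estonian-register dialect differs in documented ways: no break
exclusion (the Estonian system has no unrecorded hospital dispensing, so
every gap is a true treatment gap and stays in the denominator), a minimum
of 150 tablets purchased, and a stricter single-purchase rule for
non-persistence (fewer than 3 packages *and* fewer than 100 tablets, made
before 2022-01-01 and at least a year before death). The package reports the
Estonian minimum-tablet failure under the `too_few_purchases` audit label,
which keeps the closed reason vocabulary shared across dialects.

## Persistence definitions

**Primary** (`classify_persistence_primary()`): persistent = adherence-
eligible (the ≥ 12-month, MPR-capped set); non-persistent = exactly one
purchase made at least 730 days before end of follow-up
(min of death, emigration, end of registry, 2020-01-01 by default). A single
purchase inside that buffer is `excluded_censored` — a later refill cannot
be ruled out. Two or more purchases without adherence eligibility are
`excluded_intermediate`. The persistent/non-persistent contrast is therefore
between clean one-year continuers and clean one-purchase discontinuers,
without overbuying behaviours on either side.

**Sensitivity** (`classify_persistence_sensitivity()`): non-persistent =
stopping within one year of the first purchase, whatever the number of
purchases, with no stockpiling exclusions. The definition needs an
observability window; we require the first purchase to precede end of
follow-up by at least 365 days, since without it the definition is biased
towards non-persistence near the registry end. The window length is a
package choice (the natural one — a person must be observable for the full
year they are being classified over).

Antiplatelets are a special case: the class is commonly prescribed for
planned 6–12-month courses, so persistence is emitted as `not_applicable`
and only adherence is analyzed.

## Baseline risk factors

`derive_covariates()` computes, at treatment initiation: sex, age, secondary
prevention (a class-qualifying ICD-10 diagnosis strictly before the first
purchase; undefined for the broad blood-pressure class), the Charlson
comorbidity index over all prior diagnoses, years of education, urban
living, Finnish/Swedish mother tongue, social assistance in the prior year,
and the polytherapy count (other study classes purchased within ±365 days of
initiation).

The CCI uses the Quan (2005) ICD-10 coding algorithm with the original
Charlson weights (1/2/3/6) and the standard severity hierarchy (complicated
diabetes over uncomplicated, moderate/severe liver disease over mild,
metastatic over non-metastatic cancer). Which weight revision registry
studies use is often left implicit; this package states its choice and tests
it against hand-computed weight sums.

`encode_covariates()` offers the two reporting encodings: dichotomized
(age > 60, CCI > 5, university degree or higher — all strict inequalities)
and continuous (age, CCI, education standardized to mean 0, SD 1 within the
analysis cohort). Education level classes are not available in the synthetic
schema, so "university or higher" is a threshold on education years
(default ≥ 16, configurable). Complete-case analysis throughout; dropped
rows are counted, never silently removed.

## Association models

`fit_persistence()` is a maximum-likelihood logistic regression of
persistent vs non-persistent on all factors jointly, always adjusting for
year of birth; effects are odds ratios with Wald 95% CIs and two-sided
p-values from the normal reference. `fit_adherence()` is OLS on the MPR
scale; coefficients and CIs are rescaled by $100/1.1$ to the **percentage
change in adherence** (1.1 being the maximum admissible adherence), with
p-values from the t reference. The rescaling is applied to the linear-model
coefficient — linear models have no odds ratios, so the "rescaled log(OR)"
phrasing sometimes seen for this quantity can only mean the coefficient.
Wald rather than profile-likelihood intervals match the SE-based p-value
definition. No multiple-testing adjustment is applied. Variance explained is
adjusted R² (linear) or McFadden pseudo-R² (logistic), always labelled.

`fit_categorical_phenotype()` runs the same machinery with one indicator per
non-reference level of an externally supplied categorical phenotype (e.g.
metabolizer status from a star-allele caller — calling diplotypes is out of
scope). Levels with fewer than five individuals in the analysis set are
suppressed with a logged reason rather than estimated.

Degenerate inputs are errors or flags, never silent: a single-class outcome
errors; separation and collinearity flag the fit as not converged.

## Analytic GWAS power

`gwas_power()` computes single-variant additive-model power from the
noncentral chi-square (1 df): noncentrality
$\lambda = n \cdot 2\,\mathrm{maf}(1-\mathrm{maf})\,(\beta/\sigma)^2$
under Hardy–Weinberg genotype variance, power = upper-tail probability
beyond the central critical value at $\alpha$ (default $5\times10^{-8}$;
$1\times10^{-8}$ is the other conventional threshold). Covariate adjustment
is ignored (standardized-residual approximation). At the statin-cohort scale
(n = 116,439, maf 0.3, effect 0.027 on a trait with SD 0.118) power is
effectively 1, comfortably above 80%; the closed form is verified against a
Monte-Carlo Wald-test oracle at small n in the test suite.

## The synthetic register generator

No individual-level purchase register is publicly available, so
`simulate_cohort()` generates one with known ground truth. Design choices:

* **Adherence is induced mechanistically, not drawn.** Each person has a
  latent target MPR (default mean 0.92, person SD 0.05 — register-scale
  statin adherence sits around 0.9) and refills a `supply`-day package after
  `supply / MPR` days plus Normal(0, 10 d) jitter. The phenotyping stage
  must therefore reproduce the target from raw purchase streams; labels are
  never passed through.
* **Archetypes** give every exclusion rule a population that triggers it:
  regular refillers; early discontinuers (one purchase); break takers (one
  ≥ 150-tablet-free-day gap); stockpilers (refilling at 0.60–0.72 of supply
  exhaustion, MPR ≈ 1.4–1.7, above the cap); switchers (one formulation
  change with overlapping supply); short courses (2–3 purchases, stop within
  a year). The default mix (80/5/5/5/3/2%) keeps the cohort
  dominated by regular users, as register cohorts are, while giving minority
  behaviours enough mass to test against.
* **Injected covariate effects** shift the target MPR additively
  (adherence) and the log-odds of the early-discontinuer archetype
  (persistence), with the other archetypes keeping their relative
  proportions — so a fitted logistic model of persistent vs non-persistent
  recovers the injected log-odds asymptotically.
* **Censoring**: a configurable fraction of persons receive death (4%) or
  emigration (1%) dates; everyone else is censored at the registry end
  (2020-01-01). First purchases fall in a 2-year initiation window from the
  study start (2010), giving 8–10 years of follow-up, comparable to
  register treatment lengths of ~9 years for statins.
* **Diagnoses**: a configurable fraction receives a class-qualifying
  secondary-prevention code before the first purchase, and comorbidity
  burden draws nine non-hierarchical Charlson conditions (total weight 12)
  independently with probability `cci_burden/12`, so the expected CCI
  equals `cci_burden` exactly — a closed-form oracle for the Monte-Carlo
  tests.
* Inter-purchase interval distributions in real registers are not publicly
  documented; the jitter SD, initiation window, and package sizes (100
  tablets) are free parameters of the generator, documented as such and
  fixed once.

What the generator does **not** emulate: seasonal purchasing, dose
titration, prescription changes mid-therapy, pharmacy stock-outs,
reimbursement-tier behaviour, or correlated covariates. Passing tests show
the pipeline recovers known effects under the generative model's
assumptions, not that real registry estimates are unbiased.

## Numerical choices

Dates are whole days; intervals are integer date differences; no
time-of-day. MPR arithmetic is double precision on integer tablet/day
counts, so the interval formula and the day-by-day ledger oracle agree to
1e-12. Ties (same-day purchases) are broken by ATC code. The MPR is reported
even for ineligible persons by `compute_mpr()` (for inspection), but
phenotype records null it, so no emitted adherence value ever exceeds the
cap. Problem sizes in the test suite are chosen for CI-scale runs: 1,000
trajectories for the oracle-equivalence sweep, 100 replicates of 20,000
persons for parameter-recovery coverage, 200 replicates of 4,000 persons
for null calibration.

## Known limitations

* The one-tablet-per-day dose convention misestimates supply for titrated
  regimens; `daily_dose` is configurable per class but constant within one.
* The MPR denominator uses the interval sum over included purchases; when
  exclusions are not interval-contiguous this differs from
  last-minus-first-minus-gaps. The interval-sum reading is implemented
  because it makes "a purchase contributes neither tablets nor time" exact.
* Persistence compares one-year continuers with one-purchase discontinuers;
  intermediate behaviours are excluded by design, which inflates persistent
  proportions relative to survival-style definitions — the sensitivity
  definition quantifies that.
* The logistic/linear models assume independent persons; no family or
  regional clustering.
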