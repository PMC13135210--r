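# teleabx

Does a pediatric primary-care practice prescribe antibiotics differently
when it sees a child with an acute respiratory tract infection (ARTI —
viral upper respiratory infection, streptococcal pharyngitis, acute otitis
media, bacterial sinusitis) by telemedicine instead of in person? `teleabx`
is an R implementation of the full observational pipeline a biostatistician
needs to answer that question from EHR-style visit, prescription and
patient tables:

1. **Cohort construction** — classify visits with configurable symbolic
   code sets, find index visits (no ARTI visit in the previous 21 days),
   link follow-up visits (within 14 days) and systemic antibiotics (within
   2 days), flag exposure from billing modifiers GT/95, telehealth
   place-of-service codes or video metadata, and apply the exclusion and
   complete-case filters.
2. **Outcomes** — antibiotic prescription; guideline concordance of the
   linked drugs given the primary diagnosis (amoxicillin/penicillin for
   strep; amoxicillin or amoxicillin-clavulanate or nothing for otitis
   media and sinusitis; nothing for viral); follow-up visits and subsequent
   antibiotics in the 0–2 / 3–10 / 11–14 day windows.
3. **Propensity and weights** — logistic propensity model for telemedicine
   use with a practice-level random intercept (lme4) or fixed effects only,
   inverse-probability (ATE) or overlap (ATO) weights.
4. **Balance diagnostics** — signed standardized bias per covariate level
   before/after weighting, Love-plot data, prognostic-score balance.
5. **Estimation** — the nonparametric marginal estimator: difference of
   Hájek-weighted outcome percentages, with cluster-robust (practice-level
   linearization) SEs and Wald 95% CIs; subgroup analyses with per-subgroup
   propensity refits; diagnosis-conditional sensitivity analyses.
6. **Synthetic EHR generator** — practice-clustered, confounded data with
   both potential outcomes bookkept per visit, so the true average
   treatment effect is known exactly and every estimator property is
   testable.

The core estimator, for binary outcome `y`, exposure `Z` (1 =
telemedicine), propensity `e(x)` and weights `w = Z/e + (1−Z)/(1−e)`:

```
ATE = 100 · [ Σ w y Z / Σ w Z  −  Σ w y (1−Z) / Σ w (1−Z) ]   (percentage points)
```

with variance from the within-practice-aggregated influence functions of
the two Hájek ratios (see the methods vignette in `vignettes/`).

## Worked example

Generate a synthetic cohort with the default, deliberately approximate
marginals (84% of children under 12, 16% family-medicine clinics,
telemedicine share ≈ 2.5%, built-in prescribing effect ≈ −12 percentage
points), then run the full pipeline:

```r
library(teleabx)
cfg <- synth_config(n_practices = 400, mean_patients_per_practice = 300,
                    seed = 5)
res <- run_arti_pipeline(cfg, spec = propensity_spec(engine = "fixed"))

res$true_ate
#> [1] -11.86
res$effects$prescribed_antibiotic
#> ATE of telemedicine vs in-person care: prescribed_antibiotic
#>   in-person    47.9% (95% CI 47.6 to 48.2)  [n = 110511]
#>   telemedicine 33.6% (95% CI 28.2 to 39)  [n = 2175]
#>   ATE -14.2 percentage points (95% CI -19.7 to -8.8), 400 practices
res$effects$concordant
#> ATE of telemedicine vs in-person care: concordant
#>   in-person    80.1% (95% CI 79.9 to 80.4)  [n = 110511]
#>   telemedicine 84.1% (95% CI 80.2 to 88.1)  [n = 2175]
#>   ATE 4 percentage points (95% CI 0 to 8), 400 practices
head(res$love, 3)
#>              covariate           level   asb_pre     asb_post
#> 21 clinician_specialty      pediatrics 0.8644366 0.0002100808
#> 20 clinician_specialty family_medicine 0.8644366 0.0002100808
#> 12     census_division         pacific 0.6805633 0.0138540940
```

Reading this output: the generator built in a true effect of −11.9
percentage points; the unweighted arms are heavily confounded (clinic
specialty standardized bias 0.86 before weighting), yet the IPTW estimate
−14.2 (95% CI −19.7 to −8.8) covers the truth and the post-weighting biases
collapse below 0.1. The concordance effect is positive here because
telemedicine shifts the diagnosis mix toward viral ARTI, for which "no
antibiotic" is concordant — the diagnosis-shifting pattern the diagnosis-mix
output (`res$diagnosis_mix`) makes visible. With only ~2% of visits by
telemedicine, the treated arm is small and its CI wide; that is a property
of the design, not the estimator.

Subgroup and sensitivity analyses:

```r
subgroup_analysis(res$episodes, "payer", "prescribed_antibiotic",
                  propensity_spec(engine = "fixed"))
diagnosis_conditional(res$episodes, "strep_pharyngitis",
                      propensity_spec(engine = "fixed"))
```

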