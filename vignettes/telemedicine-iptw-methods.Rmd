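---
title: "Methods: propensity-weighted comparison of antibiotic prescribing by visit modality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: propensity-weighted comparison of antibiotic prescribing by visit modality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teleabx)
```

## The question and the estimand

Pediatric acute respiratory tract infections (ARTI) — viral upper
respiratory infection, streptococcal pharyngitis, acute otitis media and
bacterial sinusitis — drive most outpatient antibiotic prescriptions in
children. When a primary-care practice sees such a child by video instead of
in person, does the child end up more or less likely to receive a systemic
antibiotic, and is the antibiotic management still concordant with
diagnosis-specific first-line guidelines?

Because visit modality is not randomized, `teleabx` estimates the average
treatment effect (ATE) of telemedicine vs in-person care on binary episode
outcomes by inverse probability of treatment weighting (IPTW): a propensity
model for modality given baseline covariates, weights `Z/e + (1-Z)/(1-e)`,
and a nonparametric marginal estimator — the difference of Hájek-weighted
outcome percentages between arms. An overlap-weight variant (`w = Z(1-e) +
(1-Z)e`) targets the ATO, the effect in the population of children who
plausibly could have received either modality; it is the package's answer to
extreme weights, in preference to trimming.

## Episodes of care

Analysis units are episodes, not visits:

* **Index visit** — an ARTI visit with no ARTI visit by the same patient in
  the previous 21 days (day offsets −21..−1, inclusive).
* **Follow-up visits** — ARTI visits 1–14 days after the index, plus later
  same-day visits (tie-break: stable sort by day then visit id; the earliest
  same-day visit is the candidate index).
* **Linked antibiotics** — systemic prescriptions 0–2 days after the index
  ("within 2 days", inclusive, accommodating watchful waiting).
* **Orphan visits** — ARTI visits 15–21 days after their most recent index
  belong to no episode but still block index eligibility through the 21-day
  rule. The handling of this stratum is a package convention; the day
  windows themselves follow the usual inclusive claims-analytics counting
  and are all overridable arguments of `build_episodes()`.

Episodes are excluded, in fixed order with per-reason tallies, when the
index visit carries (1) an excluded diagnosis (pneumonia, bronchiolitis,
COVID-19, influenza — presentations with different care-seeking dynamics),
(2) a well-child visit type, or (3) a codiagnosis that independently
warrants antibiotics (e.g. urinary tract infection). Exclusion diagnoses are
assessed at the index visit only: the rationale for the exclusions concerns
care-seeking at presentation, not events later in the episode. A
complete-case filter then drops episodes missing census division or race
and ethnicity.

All classification is driven by a symbolic `code_registry()`; no real
ICD-10 strings are parsed. Unknown codes are counted and ignored.

## Outcomes

* **Antibiotic prescription** — any linked systemic antibiotic.
* **Guideline concordance**, by primary diagnosis under the hierarchy
  strep > otitis media > sinusitis > viral (a bacterial code governs the
  appropriateness judgment when codes are mixed; the hierarchy is a package
  decision, configurable in principle through the registry):
  * strep pharyngitis: an antibiotic is *required* and every linked drug
    must be amoxicillin or penicillin. An episode with no antibiotic is
    scored non-concordant — the concordant options for strep are drugs
    only, unlike otitis media/sinusitis whose rule explicitly admits "no
    systemic antibiotic". This is a deliberate reading of an ambiguous
    rule; it is what makes reduced strep prescribing reduce strep
    concordance.
  * otitis media / sinusitis: no antibiotic, or exclusively
    amoxicillin / amoxicillin-clavulanic acid.
  * viral: no systemic antibiotic. Concordance for viral episodes is
    definitionally `100 − antibiotic%`, an identity the tests assert.
  * any non-first-line drug anywhere in the linked set breaks concordance
    (monotone rule).
* **Follow-up outcomes** — follow-up visits in day windows 0–2, 3–10,
  11–14 and their union; subsequent antibiotics in windows 3–10, 11–14,
  3–14. Subsequent-antibiotic windows start at day 3 because days 0–2 are
  index-linked by construction; starting earlier would double-count.

## Propensity model and weights

The default propensity model is a logistic regression of telemedicine use
on race and ethnicity, age group, census division, season, clinic
specialty, medical complexity, and prior-12-month utilization (well visits,
problem visits, telemedicine, antibiotics), with a practice-level random
intercept (Laplace approximation, `lme4::glmer`) and a season × region
interaction, added because season and region balance is otherwise the
hardest to achieve. A fixed-effects-only engine (`stats::glm`) is a
first-class option, not a degraded mode: patient- or practice-level random
effects mainly capture treatment-side clustering that is independent of the
outcome mechanism, so the fixed engine remains consistent for the ATE and
is much faster inside replicated experiments and subgroup refits.

Decisions worth knowing:

* Predictions use the practice's estimated (shrunken) intercept; unseen
  practices receive the population intercept 0. Whether to predict
  conditionally or marginally is genuinely open; conditional is the
  documented default.
* Propensities are clipped to `[1e-6, 1 - 1e-6]`; no trimming by default
  (overlap weights are the sanctioned response to poor overlap).
* Weights are used unnormalized; the Hájek estimator downstream is
  invariant to their scale.
* Factor reference levels are the most frequent category, deterministically.
* Non-convergence is a hard error. Quasi-separation (some covariate cell
  containing no telemedicine visits) is reported as a loud warning rather
  than an error: the affected cells are all-control and receive weights
  near 1, so they distort nothing, and failing hard would make small
  subgroup refits unusable.

## Balance diagnostics

Standardized bias (telemedicine minus in-person; signed internally,
absolute for Love plots and thresholds): for a binary covariate
`(p_t - p_c) / sqrt((p_t(1-p_t) + p_c(1-p_c))/2)`, for a continuous one the
mean difference over the pooled standard deviation. After weighting, the
numerator uses weighted proportions but the denominator keeps the
*unweighted* dispersions, so pre- and post-weighting values share a scale —
the convention of the standard balance packages; the exact convention used
by any given published table is rarely stated, so this one is documented
rather than asserted. Thresholds: 0.10 strict, 0.25 pragmatic.

The prognostic score complements the propensity score on the outcome side:
a logistic outcome model fit on the in-person arm only, its predicted
probability computed for everyone, and the score's continuous-covariate ASB
reported before and after weighting.

## Effect estimation and inference

Arm percentages are Hájek ratios `100 · Σ w y 1[arm] / Σ w 1[arm]`; the
effect is their difference in percentage points, and the tests machine-check
that every reported effect equals the difference of its two reported arm
percentages. The variance is a linearization (sandwich) of the
ratio-difference: per-episode influence contributions

```
psi_i = 100 [ w_i Z_i (y_i - mu_t) / sum(w Z)  -  w_i (1-Z_i)(y_i - mu_c) / sum(w (1-Z)) ]
```

are summed within practice before the outer product, so the SE respects
both weighting and intra-practice correlation. The same linearization gives
each arm's CI. Wald intervals use z = 1.96 with no degrees-of-freedom
correction by default (an optional G/(G−1) small-cluster factor exists
behind a flag). The exact variance estimator behind published
survey-weighted analyses of this design is typically not fully specified;
this package's choice is documented here and verified in the tests against
an independently coded M-estimation sandwich to 1e-10, not asserted to be
identical to any other software's.

Subgroup analyses refit the propensity model within each subgroup level
*excluding* the subgroup-defining covariate, reweight, and re-estimate;
single-arm levels are skipped with a warning. Diagnosis-conditional
sensitivity analyses restrict to one primary diagnosis and repeat the full
refit-and-estimate cycle for both primary outcomes.

## The synthetic EHR generator

Real EHR-derived visit data of this kind cannot be redistributed, so
`generate_ehr()` produces tables with the statistical structure the
analysis assumes, plus ground truth that real data never has:

* practices with a random intercept (SD 0.4 by default — the practice-level
  variance of telemedicine uptake is a free parameter, not an empirical
  value) and a pediatrics/family-medicine specialty mix;
* children with categorical covariates approximating a large US pediatric
  primary-care cohort (84% under 12, 16% family medicine, telemedicine
  share ≈ 2.5%), deliberately labelled approximate;
* modality assigned by `logit(e) = β'x + b_practice`, with every
  `e` recorded as `true_propensity`;
* diagnosis drawn conditional on modality — telemedicine shifts diagnoses
  toward viral ARTI and sinusitis and away from otitis media, emulating
  modality-driven diagnosis shifting;
* antibiotic prescribing conditional on diagnosis, modality and covariates
  (`outcome_coefficients`; shared causes of modality and prescribing are
  what create confounding);
* **both** potential outcomes generated per visit from one shared uniform
  draw before one is revealed, so `true_ate` is the exact mean
  potential-outcome difference, not an estimate. The effect knob is
  declared on the risk-difference scale (`true_ate_knob = -0.07` by
  default; with the diagnosis-mix channel the default total built-in
  effect is ≈ −12 percentage points), with an optional per-diagnosis
  override. With a zero knob and modality-independent mechanisms the
  coupling makes the two potential outcomes identical, so the null is
  exact, not approximate.
* follow-up visit hazards per day window and modality, missingness
  injection (defaults chosen so the two-field union excludes ≈ 11.9% of
  episodes), exclusion-code noise, and dates as integer day offsets in one
  study year with seasons by quartile — calendar arithmetic without
  timezone hazards.

What the generator does *not* emulate: real ICD-10 coding practice, free
text, EHR vendor quirks, secular trends across years, or unmeasured
confounding. Passing tests therefore demonstrate that the pipeline is
correct *under its own assumptions* — they say nothing about residual
confounding in any real dataset.

## Validation experiments and problem sizes

The test suite's estimator experiments use a dedicated configuration
(`recovery_config` in the test helpers): built-in effect −12 points, strong
confounding (pre-weighting covariate ASBs around 0.5), practice intercept
SD 0.3, telemedicine share ≈ 14%, and propensity coefficients capped at
|β| ≤ 1.5 so propensities stay bounded away from 0 and 1. The positivity
cap matters: with the default (paper-like) coefficient extremes,
propensities reach ~0.003 and ATE weights ~300, and even weighting by the
*true* propensities leaves covariate ASBs near 0.15 at n = 20 000 — in that
near-violation regime the textbook balancing behaviour of IPTW is simply
not observable at desk scale, which is a property of the design, not of the
implementation.

Chosen problem sizes (all deterministic given seeds):

* parameter recovery: 20 replicates of ~10 000 episodes across 100
  practices; the IPTW estimate's mean is within Monte-Carlo error of the
  bookkept truth while the naive unweighted contrast is biased by a
  detectable margin in the predictable direction (more negative — the
  telemedicine-leaning covariates depress prescribing);
* CI coverage: 250 replicates of ~2 400 episodes across 60 practices;
  empirical coverage of the 95% cluster-robust Wald interval ≈ 94%;
* balance: one fixed-seed run of ~20 000 episodes across 200 practices;
  max post-weighting covariate |ASB| < 0.1 and prognostic-score ASB
  shrinkage;
* episode construction: 100 random visit streams (≤ 500 visits) against a
  brute-force pairwise window-predicate oracle; concordance against an
  exhaustive rule-table oracle; the sandwich SE against an independent
  M-estimation implementation at 1e-10.

## Worked example

```{r example, eval = FALSE}
cfg <- synth_config(n_practices = 100, mean_patients_per_practice = 150,
                    seed = 5)
res <- run_arti_pipeline(cfg, spec = propensity_spec(engine = "fixed"))
res$true_ate                       # exact built-in effect
res$effects$prescribed_antibiotic  # IPTW estimate with robust 95% CI
plot_love(res$love)                # balance before/after weighting
```

## Known limitations

* The linearization variance treats the estimated propensities as known;
  for the ATE this is conservative.
* The mixed engine uses the Laplace approximation; with very few patients
  per practice adaptive quadrature would be preferable, but lme4 does not
  offer it alongside the formula interface used here.
* Concordance ignores dose, duration and route, and does not distinguish
  delayed ("watchful waiting") prescriptions beyond the 2-day linkage
  window.
* Audio-only and audio-video telemedicine are not distinguished; the
  modality evidence model treats them as one exposure.
* Episode-wide (rather than index-only) exclusion-diagnosis assessment is
  not implemented; the index-only choice is documented above.
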