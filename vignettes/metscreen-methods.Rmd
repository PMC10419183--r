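---
title: "Screening for metabolic syndrome with obesity- and lipid-related indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for metabolic syndrome with obesity- and lipid-related indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metscreen)
library(dplyr)
```

## The problem

Metabolic syndrome (MetS) — the co-occurrence of at least three of central
obesity, elevated triglycerides, low HDL cholesterol, elevated blood pressure
and elevated fasting glucose — identifies people at sharply increased risk of
type 2 diabetes and cardiovascular disease. Diagnosing it requires a blood
draw and five separate criteria, which is impractical for large-scale
screening in primary care. A long line of epidemiological work therefore asks:
which single, cheaply computed index of adiposity or lipid burden best
*predicts* MetS, and at what cut-off?

`metscreen` implements that screening workflow end to end for the population
in which it is most often studied — middle-aged and elderly Chinese adults
(age 45+) — from the thirteen candidate indices through ROC-based cut-off
derivation to covariate-adjusted association estimates, together with a
calibrated synthetic cohort generator so that every stage can be exercised
and tested without access to restricted survey microdata.

## The thirteen indices

Waist circumference (WC, cm) is itself the first index. The remainder, with
the units each formula expects (conversions happen internally; the package
stores all analytes in mmol/L):

* **BMI** = weight / height², kg/m².
* **WHtR** = WC / height, both in cm.
* **VAI** (visceral adiposity index), sex-specific:
  men (WC/(39.68 + 1.88·BMI))·(TG/1.03)·(1.31/HDL);
  women (WC/(36.58 + 1.89·BMI))·(TG/0.81)·(1.52/HDL), TG and HDL in mmol/L.
* **ABSI** (a body shape index) = WC(m) / (BMI^(2/3)·height^(1/2)),
  reported ×100 so that population values land near 8. The scale constant is
  exported as `ABSI_SCALE`; screening cut-offs are scale-covariant, so the
  choice affects presentation only.
* **BRI** (body roundness index) =
  364.2 − 365.5·√(1 − (WC/2π)²/(0.5·height)²), lengths in m. The radicand is
  negative only for anatomically impossible waist/height pairs; such records
  get `NA` with a per-cohort count rather than aborting a batch run.
* **LAP** (lipid accumulation product) = (WC − 65)·TG for men,
  (WC − 58)·TG for women, cm·mmol/L. Values below the sex offset give a
  negative product which is *retained*: ROC analysis needs only the ordering,
  and truncation would create artificial ties.
* **CI** (conicity index) = WC(m) / (0.109·√(weight/height)). 0.109 is the
  standard normalization; published population means near 1.27 are consistent
  only with this constant.
* **CVAI** (Chinese visceral adiposity index), a sex-specific linear score of
  age, BMI, WC, log10 TG and HDL re-calibrated for Chinese physiques.
* **TyG** = ln(TG[mg/dL]·glucose[mg/dL]/2), the triglyceride-glucose
  insulin-resistance surrogate, and its anthropometric products
  **TyG-BMI**, **TyG-WC**, **TyG-WHtR**.

Note the unit clash these formulas embed: LAP and CVAI take triglycerides in
mmol/L while TyG takes mg/dL. The package resolves it by storing canonically
in mmol/L and converting per formula with the standard molar factors
(TG 88.57, glucose 18.016, HDL-C 38.67 mg/dL per mmol/L), exported in
`ANALYTE_MGDL_PER_MMOL`. The natural log is used in TyG and log10 in CVAI,
exactly as each formula is defined.

## The MetS definition

`mets_components()` applies the NCEP ATP III (2005) criteria with the Chinese
waist thresholds: WC ≥ 90 cm (men) / ≥ 80 cm (women); TG ≥ 150 mg/dL;
HDL-C < 40 mg/dL (men) / < 50 mg/dL (women); SBP ≥ 130 or DBP ≥ 85 mmHg *or*
antihypertensive therapy; FPG ≥ 100 mg/dL *or* antidiabetic medication *or*
diabetes history. MetS is ≥ 3 of 5. Two subtleties the tests pin down:

* boundary semantics are exactly as written — the cut-ins are inclusive
  (WC 90 counts) while the HDL criterion is a strict `<` (HDL 40 does not);
* therapy/history overrides attach to blood pressure and glucose only. No
  lipid-lowering-therapy override is modelled, because the definition used
  here has none.

The 126 mg/dL glucose threshold sometimes quoted in this literature is the
*diabetes* threshold; the MetS component uses 100 mg/dL. The generator uses
7.0 mmol/L (≈126 mg/dL) only to correlate antidiabetic medication and
diabetes history with true hyperglycaemia.

## ROC analysis and the Youden cut-off

For each index and sex stratum, `youden_cutpoint()` computes the empirical
ROC curve under the fixed rule *score ≥ cut-off → screen positive* (all
thirteen indices rise with risk; no automatic direction flip is performed).
Candidate cut-offs are the midpoints between consecutive distinct score
values plus ±∞ sentinels, the convention used by mainstream ROC packages.
The reported AUC is the tie-corrected Mann–Whitney statistic — the
probability a random case outscores a random control, ties half-weighted —
which equals the trapezoidal area under the empirical curve (a property the
test suite verifies against brute-force enumeration on hundreds of random
instances).

The optimal cut-off maximizes the Youden index J = sensitivity +
specificity − 1. Ties in J are broken toward the higher sensitivity (in a
screening context a missed case costs more than a false alarm), then toward
the lower cut-off, so results are deterministic. At the chosen cut-off the
full diagnostic row is reported: sensitivity, specificity, PPV, NPV, LR+ =
sens/(1−spec), LR− = (1−sens)/spec, with empty-denominator cells returned as
`NA` with a warning rather than silent NaN.

Two decisions here are assumptions, since the source analyses rarely state
them: the AUC standard error uses the Hanley–McNeil rank-based formula
(DeLong's placement-variance estimator is available via `se_method =
"delong"` and cross-checked against an independent implementation in the
tests), and the 95% CI is the Wald interval clipped to [0, 1]. AUC accuracy
bands follow the usual reading: > 0.9 high, 0.7–0.9 moderate, 0.5–0.7 low,
0.5 chance.

## Association estimates

`association_table()` dichotomizes each index at its sex-specific optimal
cut-off (`value ≥ cutoff`, the same rule as the ROC) and fits logistic
regressions against MetS and each of its four non-anthropometric components,
unadjusted and adjusted for age, education, marital status, residence,
smoking, drinking, social activities, exercise and chronic-disease count
band. Models run within sex strata, so sex is not in the adjustment set (a
different covariate list can be supplied). Estimation is maximum likelihood
by IRLS with tight convergence control; complete separation and
non-convergence are flagged per row instead of silently reported, and
missing covariates are handled complete-case with the exclusion count
carried along. CIs are Wald, exp(β ± 1.96·SE); p-values are Wald and print
as "<0.001" below that threshold. The unadjusted OR provably equals the 2×2
cross-product ratio — the tests assert this identity on random tables — and
categorical covariates use reference-level indicator coding with the first
listed level (e.g. education "Illiterate", smoking "No") as reference.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis assumes,
not any individual-level data. Per sex it draws:

1. age from the published band proportions ([45,55), [55,65), [65,75), 75+),
   uniform within band;
2. an 8-dimensional multivariate-normal latent vector — height, log BMI,
   waist residual, log TG, HDL, log FPG, SBP, DBP — with a fixed correlation
   matrix (`default_latent_corr()`): TG–HDL −0.40, BMI–TG 0.25, SBP–DBP
   0.70, and so on. No such matrix is published; these are documented,
   editable values chosen to reflect well-known cardiometabolic couplings;
3. physical scales by transformation: log-normal BMI, TG and FPG, truncated
   normal height, HDL and pressures; weight is BMI·height²; WC is a
   sex-specific linear function of BMI plus a correlated residual
   (corr(WC, BMI) ≈ 0.8);
4. covariates from the published categorical proportions, and
   medication/history flags with probabilities conditional on exceeding the
   relevant clinical threshold (e.g. antihypertensive use 28% among
   exceeders vs 4% otherwise).

The marginal parameters are anchored to the published sex-stratified
means/SDs: male WC 84.97 ± 9.82 cm, BMI 22.96 ± 3.65, TyG 8.62 ± 0.66;
female WC 85.65 ± 10.16, BMI 23.99 ± 4.05, TyG 8.72 ± 0.63; heights
1.65/1.54 m and blood pressures ~129/76 mmHg are standard values for this
population, which the source tables do not print. Derived-index means then
land within a few percent of their published anchors without further tuning,
and the emergent MetS prevalence — diagnosed through the real
`mets_components()` path, never drawn directly, so generator and classifier
cannot be circularly coupled — is ≈ 42% overall (≈ 30% male, ≈ 51% female),
matching the published stratified prevalence closely.

What the generator does *not* emulate: survey design and household
clustering, nonresponse, age trends in the latent variables (age is
independent of the biomarkers, so CVAI's age term only adds noise),
covariate–disease associations (covariates are drawn independently of the
latents, so adjusted ≈ unadjusted ORs on synthetic data), and the extreme
right tail of VAI (whose published summary row is internally inconsistent
across sex columns and is excluded from calibration checks). Passing tests
therefore demonstrate the correctness of the *machinery* and the
plausibility of the cohort's joint structure — not that results on real
survey data would be numerically identical.

## Numerical and design choices

* Problem sizes: calibration checks use cohorts of 10,000; oracle-equivalence
  properties use 200 random instances of n ≤ 50; logistic parameter recovery
  uses 200 replicates of n = 5,000 with a true adjusted OR of 5 (mean
  estimate within 5%, Wald coverage 0.95 ± 0.03).
* The conicity constant is 0.109. One widely circulated transcription prints
  0.019, which is inconsistent with any published population mean near 1.27;
  the package treats it as a typesetting artifact.
* Reported precision in written reports follows the field's tables:
  percentages to 2 decimals, AUC and J to 3, ORs to 3.
* `generate_cohort()` restores the caller's RNG state; all randomness flows
  from its `seed` argument.
* Rejection-resampling keeps emitted records inside the participant
  invariants (height, waist, weight ranges; positive analytes; DBP < SBP),
  with the rejected-draw count attached as an attribute.

## Limitations

The package estimates screening performance, not aetiology: odds ratios from
cross-sectional dichotomized exposures carry no causal interpretation, and
cut-offs derived on one population (real or synthetic) need external
validation before clinical use. Survey weights are not supported — the
analyses this package reproduces did not use them — and the synthetic
cohort, however well calibrated in its first two moments, cannot stand in
for real microdata when the question is a population estimate rather than
method correctness.
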