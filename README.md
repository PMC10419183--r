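# metscreen

Screening analytics for metabolic syndrome (MetS) in middle-aged and elderly
populations: which cheaply measured obesity- or lipid-related index best
predicts MetS, and at what cut-off?

`metscreen` is a tidyverse-native R package for epidemiologists and
biostatisticians running index-based MetS screening studies. It provides:

* **Thirteen index calculators** — WC, BMI, WHtR, VAI, ABSI, BRI, LAP,
  conicity index, CVAI, the TyG index and its TyG-BMI / TyG-WC / TyG-WHtR
  combinations — with the unit conversions each formula requires handled
  internally (canonical storage is mmol/L; TyG converts to mg/dL, LAP/CVAI
  stay in mmol/L).
* **NCEP ATP III diagnosis** with Chinese waist thresholds: MetS = at least
  3 of {WC ≥ 90/80 cm (M/F), TG ≥ 150 mg/dL, HDL-C < 40/50 mg/dL (M/F),
  BP ≥ 130/85 mmHg or antihypertensive therapy, FPG ≥ 100 mg/dL or
  antidiabetic therapy/history}.
* **ROC cut-point analysis** per index and sex: tie-corrected Mann–Whitney
  AUC with Hanley–McNeil (or DeLong) SE and 95% CI, the Youden-optimal
  cut-off J = max(sens + spec − 1), and the full diagnostic row
  (sens, spec, PPV, NPV, LR+, LR−).
* **Association tables**: each index dichotomized at its sex-specific
  cut-off, with unadjusted and covariate-adjusted logistic odds ratios
  (Wald CIs) against MetS and its components, with separation and
  convergence diagnostics.
* **A calibrated synthetic cohort generator** reproducing the sex-stratified
  moments, covariate mix and ~42% MetS prevalence of a large Chinese
  ageing-cohort population, so the whole pipeline runs and tests offline.

All user-facing functions take a data frame first and return tibbles, so
stages chain with the pipe; results carry `tidy()`/`glance()` and
`autoplot()` methods.

## Worked example

```r
library(metscreen)
library(dplyr)

cohort <- generate_cohort(n = 2000, seed = 42) |>
  compute_index_panel() |>
  mets_components()

mets_prevalence(cohort) |> filter(stratum %in% c("overall", "sex"))
#>   stratum sex    age_band     n n_mets prevalence_percent
#> 1 overall <NA>   <NA>      2000    894               44.7
#> 2 sex     female <NA>      1102    593               53.8
#> 3 sex     male   <NA>       898    301               33.5
```

Roughly 45% of this synthetic cohort meets the MetS definition — 34% of men
and 54% of women, the characteristic female excess of this age group. Now
rank candidate indices by how well they discriminate MetS in men and derive
each one's optimal screening cut-off:

```r
battery <- roc_battery(cohort, indices = c("tyg_wc", "lap", "cvai", "bmi", "absi"))
battery |> filter(sex == "male") |> arrange(auc_rank) |>
  select(index, auc, ci_lo, ci_hi, optimal_cutoff, youden_j, sens, spec)
#>   index    auc ci_lo ci_hi optimal_cutoff youden_j  sens  spec
#> 1 tyg_wc 0.876 0.85  0.903         761.      0.62  0.821 0.799
#> 2 lap    0.857 0.828 0.885          27.8     0.556 0.787 0.769
#> 3 cvai   0.831 0.8   0.862         113.      0.558 0.757 0.801
#> 4 bmi    0.764 0.73  0.799          23.1     0.402 0.744 0.658
#> 5 absi   0.573 0.533 0.613           7.88    0.124 0.797 0.327
```

TyG-WC leads (AUC 0.876: a randomly chosen case outscores a randomly chosen
control 87.6% of the time), LAP and CVAI follow closely, and ABSI is barely
better than chance — the ordering this literature consistently reports. A
man with TyG-WC ≥ 761 screens positive, catching 82% of cases while passing
80% of non-cases. Finally, the association strength after dichotomizing at
that cut-off:

```r
association_table(cohort, filter(battery, index == "tyg_wc"), outcomes = "mets") |>
  select(index, sex, or_unadj, or_adj, ci_adj_lo, ci_adj_hi)
#>   index  sex    or_unadj or_adj ci_adj_lo ci_adj_hi
#> 1 tyg_wc female     15.6   16.6      12.2      22.5
#> 2 tyg_wc male       18.2   19.3      13.4      27.8
```

Men above the TyG-WC cut-off have ~19-fold the odds of MetS of men below it,
after adjustment for age, education, marital status, residence, smoking,
drinking, activities, exercise and chronic-disease burden.

`run_full_analysis()` chains all stages (ingest or simulate → indices →
diagnosis → ROC battery → associations) and writes CSV reports plus a JSON
run manifest; `read_cohort_csv()` ingests external cohorts with explicit
per-analyte unit declarations (mg/dL or mmol/L). `plot_roc_curves()` and the
`autoplot()` methods draw the ROC, AUC-ranking and forest plots.

## Documentation

The methods vignette (`vignettes/metscreen-methods.Rmd`) describes the
statistical model behind each stage, the synthetic generator's calibration
and its limitations, and the numerical conventions (cut-off placement,
tie-breaking, SE estimators, unit constants).
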