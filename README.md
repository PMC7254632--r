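# doxadapt

Doxorubicin exposure simulation and model-based dose individualisation for
paediatric oncology.

Paediatric protocols dose doxorubicin per body surface area (BSA) but switch
to body-weight dosing or percentage reductions in infants, with thresholds
that differ between protocols. Because doxorubicin clearance changes with
age and size, these rules create large, discontinuous differences in
systemic exposure (AUC) across the age range — including sharp dose steps
the day a child crosses a weight threshold. `doxadapt` is for
pharmacometricians and paediatric-oncology methodologists who want to
quantify those differences and evaluate the model-based alternative.

At its core is a published covariate model for doxorubicin clearance,

    CL = 9.26 * (1 + (BSA - 0.77) * 1.30) * (1 + (age / 5.32)^0.286)  [L/h]

combined with the linear-kinetics identity AUC = Dose / CL, and the
a-priori dose-individualisation rule

    Dose_ind = Dose_18y * CL_model(child) / CL_model(18y)

which aims every child at the exposure a typical 18-year-old attains under
the regimen's reference dose (344 µg·L⁻¹·h per 10 mg/m²). The package
provides:

* **Growth references** — monthly LMS height/weight-for-age tables
  (synthetic emulations of the WHO 0–5 y and CDC 5–18 y charts), percentile
  lookups, BSA (Mosteller/DuBois), and threshold utilities such as
  `age_at_weight()`.
* **Regimen engine** — YAML-configured protocols with ordered,
  boundary-explicit dose-modification rules; three shipped regimens
  (NB Registry 2016 N4, CWS-SoTiSaR, AIEOP-BFM ALL 2017).
* **PK simulator** — closed-form (eigen decomposition) linear mammillary
  infusion profiles, typical AUC/c_max across age, seeded Monte-Carlo
  variability.
* **Dose adaptation and metrics** — adapted doses, normalised AUC, median
  prediction error (bias), median absolute prediction error (precision),
  80–125% target attainment, and exact binomial order-statistic confidence
  intervals for quantiles.
* **Synthetic cohorts** — virtual populations emulating the structure of
  the study cohort (n = 94, 4 infants, youngest 2.5 months) so the
  observed-vs-adapted evaluation runs without any patient data.

## Worked example

```r
library(doxadapt)

cws <- load_regimen("cws_sotisar")           # 20 mg/m2 over 3 h
curve <- typical_exposure_vs_age(cws)        # median boy, monthly grid

max(curve$auc)                               # 1009.8 ug/L*h ...
curve$age[which.max(curve$auc)] * 12         # ... at 14 months (10-kg crossing)
curve$auc[curve$age == 18]                   # 687.6 ug/L*h at age 18

reference_target("per_m2", 10)$target_auc    # 343.8 ug/L*h exposure target

res <- run_adaptation_evaluation(cws, seed = 1)
res$evaluation
#> Cohort evaluation (n = 94, target 688 ug/L*h)
#> -- conventional protocol dosing --
#> Exposure evaluation (n = 94, target 688 ug/L*h):
#>   bias (MPE):       17.0% [10.3, 25.4]
#>   precision (MAPE): 22.3% [17.4, 26.7]
#>   attainment 80-125%: 51.1%
#> -- model-based adapted dosing --
#> Exposure evaluation (n = 94, target 688 ug/L*h):
#>   bias (MPE):       3.1% [-1.7, 9.1]
#>   precision (MAPE): 18.1% [13.8, 21.8]
#>   attainment 80-125%: 58.5%
#> paired Wilcoxon p = 8.48e-14; McNemar (attainment) p = 0.31
```

Reading the output: under the protocol's own rules the median child in this
synthetic cohort is overexposed relative to the 18-year-old target (bias
+17%) with a median absolute error of 22%; the model-based adaptation
removes the age-driven bias (3%, CI spanning 0), tightens precision, and
lifts the share of children inside the 80–125% bioequivalence window.
`plot_exposure_vs_age(curve)`, `plot_dose_vs_age()` and
`autoplot(res$evaluation)` draw the corresponding figures, and
`tidy()`/`glance()` return the metrics as tibbles.

## Repository layout

* `R/` — implementation; `inst/extdata/` — growth tables and regimen
  configs; `data-raw/` — script that regenerates the growth tables.
* `vignettes/dose-individualisation.Rmd` — the methods vignette: model,
  assumptions, parameter choices, what the synthetic cohort does and does
  not show, limitations.
* `tests/testthat/` — unit, property and acceptance tests (closed-form
  solver vs ODE oracle, LMS round trips, lognormal attainment closed form,
  exact-CI coverage).
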