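# vascleak

Sepsis is characterized by vascular leak: fluid given to support the
circulation escapes through a permeable endothelium instead of staying in
the vessels, and a positive fluid balance is associated with organ failure
and death. Hematocrit offers a cheap window into this process — red cells
cannot leave the vasculature, so retained fluid dilutes the hematocrit
while leaked fluid does not. `vascleak` turns that observation into a
tested analysis pipeline for ICU researchers: it derives a **vascular leak
index (VLI)** per patient from raw event streams,

```
VLI = ((Hct_final − Hct_initial) / net fluid balance) × BSA × 1000
```

with the initial hematocrit taken as the earliest measurement in
[−12, 18] h around ICU admission, the final as the mean over (18, 36] h,
the net balance as intake minus urine output over [−6, 36] h (restricted
to patients with positive balance), and BSA from the Du Bois formula. It
then builds analysis cohorts through a documented exclusion cascade with
full attrition accounting, median-imputes the 5% distribution tails,
assigns quartiles, and quantifies the association of the index with
in-hospital death and with 36–84 h fluid balance using penalized-spline
additive models (mgcv) and quartile odds-ratio / mean-difference
contrasts. A seeded synthetic ICU generator with a known per-patient leak
fraction makes every stage verifiable without credentialed database
access.

## Worked example

```r
library(vascleak)

sim <- generate_dataset(sim_config(n_patients = 1000, seed = 42))
feats <- derive_features(sim$dataset)
sel <- select_cohorts(sim$dataset, features = feats)
print(sel)
#> <vli_cohorts> sepsis patients: 942
#> In-hospital-death cohort: 761
#> Attrition (first matching filter wins):
#>   bleeding_or_blood_products   removed     79  remaining    863
#>   excess_other_output          removed     10  remaining    853
#>   rrt                          removed     36  remaining    817
#>   erroneous_demographics       removed      0  remaining    817
#>   unreliable_fluid_data        removed     48  remaining    769
#>   missing_vli_data             removed      8  remaining    761
#>   nonpositive_balance          removed      0  remaining    761
#> 36-84 h fluid-balance cohort: 729
#> ...

rows <- build_cohort_rows(sim$dataset, feats, sel$death_ids)
fit <- fit_death_gam(rows)
print(fit)
#> <vli_gam> outcome: binary_death  n = 761
#>   smooth term: edf = 1  p = 0.00322
#>   covariates: severity_score, comorbidity_score, age, sex

fit_quartile_model(rows, "binary_death")
#> Quartile contrasts vs Q1 (odds ratio):
#>  quartile estimate conf_lo conf_hi     se  p_value
#>        Q1    1.000      NA      NA     NA       NA
#>        Q2    1.364  0.7499   2.481 0.3052 0.309166
#>        Q3    1.236  0.6397   2.390 0.3363 0.527922
#>        Q4    2.303  1.2838   4.133 0.2982 0.005148
```

Reading the output: 942 of 1000 simulated patients are septic; the
cascade removes 181 (bleeding/blood products, excess output, renal
replacement, unreliable charting, missing ingredients), leaving 761 for
the death analysis and 729 for the fluid-balance analysis. The smooth
term of the adjusted additive model is significant (p ≈ 0.003), and
patients in the top index quartile — the most-leak group — have about
2.3 times the odds of in-hospital death of the bottom quartile, adjusted
for severity, comorbidity, age and sex. `predict_partial_effect(fit)`
returns the fitted death-probability curve with its confidence band;
`plot()` draws it.

The same flow is available as file-based drivers — `cmd_simulate()`,
`cmd_analyze()`, `cmd_report()` — or from a shell via
`inst/cli/vascleak.R`.

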