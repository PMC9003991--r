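---
title: "Estimating vascular leak from hematocrit dilution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating vascular leak from hematocrit dilution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vascleak)
```

## The index and its physiology

Sepsis is characterized by increased capillary permeability: fluid and
plasma protein escape the vasculature, while red cells do not. When
intravenous fluid is retained intravascularly it expands plasma volume and
dilutes the hematocrit; when it leaks, the hematocrit falls more slowly or
even rises. The vascular leak index (VLI) exploits this: the change in
hematocrit per unit of net fluid balance, normalized by body size,

$$
\mathrm{VLI} \;=\; \frac{\mathrm{Hct}_{\mathrm{final}} -
\mathrm{Hct}_{\mathrm{initial}}}{\text{net fluid balance}}
\times \mathrm{BSA} \times 1000,
$$

with hematocrit in percent points, balance in ml over the resuscitation
window, and BSA in m². The factor 1000 puts typical values on a unit
scale. Strongly negative values indicate hemodilution (fluid retained);
values near zero or positive indicate leak (or hemoconcentration). Because
dividing by the balance is only meaningful when fluid is accumulating, the
analysis is restricted to patients with a strictly positive net balance.

## Time windows

All event times are hours relative to ICU admission (t = 0); negative
times cover pre-ICU (emergency department) care.

| Quantity           | Window      | Convention | Rule                      |
|--------------------|-------------|------------|---------------------------|
| Initial hematocrit | [−12, 18]   | closed     | earliest measurement wins |
| Final hematocrit   | (18, 36]    | half-open  | mean of all measurements  |
| Net fluid balance  | [−6, 36]    | closed     | intake − urine output     |
| Outcome balance    | (36, 84]    | half-open  | intake − urine output     |

The half-open conventions are a deliberate design choice: endpoint events
are otherwise ambiguous, and with these rules a measurement at exactly
t = 18 h contributes only to the initial value, and a fluid event at
exactly t = 36 h is counted exactly once, in the resuscitation balance.
Ties at the earliest initial-hct timestamp are averaged. Urine output uses
the same window as intake; `other_output` volumes (drains etc.) never
enter a balance — they only drive the excess-output exclusion flag. All
window endpoints are configurable through `run_config()`.

Two BSA formulas are provided — Du Bois
(`0.007184 · kg^0.425 · cm^0.725`, the default) and Mosteller
(`sqrt(cm · kg / 3600)`) — because the literature on this index is
ambiguous about the intended body-size normalizer; the choice is exposed
in the run configuration rather than hidden.

## Cohort construction

Sepsis is the inclusion criterion. Exclusions apply in a fixed order with
first-match-wins attribution, so the attrition counts are additive:

1. bleeding diagnosis or blood products (either invalidates the
   hematocrit signal),
2. excess other fluid output,
3. renal replacement therapy,
4. erroneous demographics — operationalized as age < 16 years, height
   outside (100, 250) cm or weight outside (20, 350) kg, since no
   standard definition exists,
5. unreliable fluid charting (an input flag),
6. any missing VLI ingredient (initial or final hematocrit, height,
   weight, fluid data),
7. non-positive net fluid balance (zero counts as non-positive: "positive
   balance" is read strictly).

The fluid-balance cohort is a subset of the death cohort, additionally
removing patients who died strictly before 84 h (a death at exactly
84.0 h is retained — the boundary is not defined by convention elsewhere,
so the strict inequality is fixed here) and patients with no intake or
urine events in (36, 84] (missing outcome). Patients with a missing
severity score are not an attrition step; they are dropped, with a
warning, at model fitting.

## Distributional post-processing

Fluid charting errors dominate the extreme tails of the index, so values
strictly below the 5th or strictly above the 95th percentile are replaced
by the cohort median (values equal to a boundary are retained). Quartiles
are then cut at the 25th/50th/75th percentiles of the imputed vector,
right-closed. Both steps use the linear-interpolation empirical quantile
(R type 7) — imputation and quartile boundaries depend on the estimator,
so it is fixed and documented for reproducibility. Imputation is applied
within each analysis cohort separately, since the two outcome populations
are reported separately. Tail imputation by the median leaves the median
itself unchanged, which the test suite asserts as an invariant.

## Association models

Two model families per outcome:

* **Additive spline models** (`fit_death_gam()`, `fit_balance_gam()`):
  `outcome ~ s(VLI) + severity + comorbidity (if available) + age + sex`,
  logit link for in-hospital death, identity link for the 36–84 h
  balance. The smooth is a penalized cubic regression spline with basis
  dimension `k = 10` and REML smoothness selection (mgcv); `k = 10`
  leaves the effective degrees of freedom to the penalty while keeping
  the basis small enough for stable logistic fits. Significance of the
  smooth is mgcv's approximate ANOVA-type test of the fitted term.
* **Quartile contrasts** (`fit_quartile_model()`): the quartile as a
  4-level factor (Q1 reference) with the same covariates; Wald 95%
  confidence intervals on the link scale, exponentiated to odds ratios
  for death. Comorbidity is dropped as a term when entirely unavailable,
  mirroring datasets that do not record it. All-or-none event quartiles
  abort with advice to use exact methods rather than reporting unusable
  Wald intervals.

Partial-effect curves evaluate the fitted outcome over an even grid of
index values with covariates at reference (numeric means, modal sex) —
confidence bands are computed on the link scale and mapped through the
inverse link, so death-probability bands respect [0, 1]. Grids outside
the observed index range are clipped with a warning rather than
extrapolated.

## The synthetic generator

`generate_dataset()` draws patients whose ground-truth leak fraction
λ ∈ [0, 1] is known, so every pipeline stage can be verified without
clinical data access. The physiology is deliberately minimal — exactly
what the index can see:

* Baseline blood volume from the sex-specific Nadler formulas and
  red-cell volume `RCV = BV₀ · Hct₀/100`. The simulator uses Nadler
  blood volume while the index normalizes by Du Bois BSA, keeping the
  generator and the index mathematically independent.
* A fraction λ of every infusion leaks instantly; urine leaves the
  vasculature entirely: `ΔV = (1 − λ)·intake − output`. The hematocrit
  at any time is `100 · RCV / V(t)` — red-cell volume is conserved, so
  hemodilution is the only mechanism. A kinetic efflux model would be
  richer but is unidentifiable from two hematocrit readings.
* Output events that would push the hematocrit above 65% (blood volume
  approaching RCV) are rejected.

Default study conditions (all overridable in `sim_config()`): age
65 ± 16, 52% male, sex-specific height/weight, severity score 74 ± 26,
baseline hematocrit 36.5 ± 5%, λ ~ Beta(2.2, 2.6), ~15 infusions of
~450 ml over [−6, 36] h with 2% of volume pre-ICU, urine returning a
`0.15 + 0.25·(1 − λ)` fraction of intake (leakier patients are more
oliguric), hematocrit charted 6-hourly with 1.0 percent-point noise,
death on the logit scale with slope 1.6 per unit λ calibrated to ~14%
cohort mortality, and a 36–84 h balance of `200 + 1200·λ` ml plus
right-skewed noise. These values were fixed once, from the closed-form
dilution arithmetic, to land the derived cohort near an eICU-like sepsis
population — initial hematocrit ≈ 36%, final ≈ 29%, VLI median ≈ −3
with a left-skewed distribution and a small positive tail, mortality in
the 12–19% band — and to keep the index informative about the true leak
fraction (rank correlation ≥ 0.8) at the default noise level. The
calibration tests assert these only loosely (±20%).

Each patient draws from a private RNG substream seeded deterministically
from the top-level seed and the patient index, so a fixed seed
reproduces the dataset byte-for-byte and patient *i*'s course is
invariant to `n_patients`.

What the generator does **not** emulate: hemorrhage, transfusion, renal
replacement dynamics, charting gaps and transcription errors, informative
measurement timing, multiple ICU stays, or between-hospital practice
variation. Passing tests on these data therefore demonstrate that the
pipeline's arithmetic, windowing, cascade and inference are correct and
well calibrated — not that the index is clinically valid on any real
database.

## Numerical and degenerate-input choices

* Quantiles: R type 7 everywhere (imputation bounds, quartile cuts,
  summaries).
* Quartile ties: a value equal to a cut point goes to the lower
  quartile; with massive ties labels remain deterministic and monotone.
* Fewer than 20 index values: tail imputation is skipped with a warning
  (both 5% tails can be empty).
* No fluid events in the resuscitation window: balance 0, removed by the
  positive-balance rule; no events in the outcome window: outcome
  missing.
* Non-positive net balance reaching `compute_vli()` is an error — the
  cascade must have removed it.
* Implausible demographics are accepted at I/O and counted by the
  cascade; structurally invalid rows (hematocrit outside (0, 100),
  negative volumes, unknown directions, orphan events) are fatal at I/O.
* CSV round trips format doubles with 17 significant digits, so
  written/read values are bit-identical.

## Problem sizes used by the test suite

Simulation-based checks use n = 5000 patients for parameter recovery,
200 replicates at n = 1000 for the null calibration of the smooth-term
test, 100 replicates at n = 2000 for quartile-effect coverage, and one
n = 20 000 run (with a steeper, graded death slope of 2.0 per unit λ,
designed up front) for the dose–response ordering of the quartile odds
ratios. These sizes give the assertions comfortable Monte-Carlo margins
while keeping the default test run short.

## Known limitations

The index inherits the ambiguities of its inputs: it cannot distinguish
leak from unmeasured output, the first reliable hematocrit may already be
diluted by pre-ICU fluid, and patients with rising hematocrit land in the
highest quartile with uncertain biological interpretation. The attrition
order is fixed by convention; alternative orders redistribute counts
among filters (the retained set is unchanged). The generator's urine
model ties oliguria linearly to λ — convenient and directionally
realistic, but not a physiologic kidney model.
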