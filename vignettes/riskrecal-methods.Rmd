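---
title: "Validating and recalibrating CVD mortality risk equations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and recalibrating CVD mortality risk equations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical machinery it
implements: the risk-equation families, the validation statistics, the
recalibration procedure, the synthetic-cohort generator, and the design
decisions that were genuinely open. It states the assumptions behind each
choice and what the passing test suite does and does not demonstrate.

## 1. Risk-equation families

### Proportional-hazards ("cox_form") equations

Most CVD mortality equations — the Framingham scores, the Chinese
ischemic-CVD model, and the Pooled Cohort Equations — share one shape. A
subject's risk factors are transformed (natural log for age, lipids and
blood pressure in most families; contiguous category bands in the Chinese
model; products such as ln age × ln cholesterol in the Pooled Cohort
Equations), weighted and summed into a linear predictor $L$, and the
absolute risk over horizon $h$ years is

$$\text{risk}(h) = 1 - S_0(h)^{\exp(L - \bar L)},$$

with $\bar L$ the cohort mean linear predictor and $S_0(h)$ the baseline
survival of a subject at the mean. Each equation is a *spec file* (JSON or
YAML): terms, coefficients, $\bar L$, $S_0$, risk-category thresholds and
expected units. The scoring engine contains no hard-coded coefficients;
the ten shipped spec files carry the published recalibrated parameter sets
for both sexes of five equation families, transcribed cell by cell (a test
enumerates every transcribed value).

Two transcription caveats are flagged in the spec files themselves
(`notes` field). First, the published men's column for the
African-American Pooled Cohort equation is identical to the men's general
Framingham column — almost certainly a typesetting artifact in the source
table — and is shipped as printed. Second, the published women's column
for the white Pooled Cohort equation is internally inconsistent: evaluated
at a typical female risk profile it yields a linear predictor near +104
while its own printed mean is −51.68 (every other column is
self-consistent to within about one unit), so predicted risks under that
spec saturate near 1 on realistic cohorts. We ship printed numbers only
and do not attempt to repair the column; users validating that equation
should supply corrected parameters.

Conventions worth stating explicitly:

* **Units.** Cohort tables are stored in the measured units (mmol/L for
  lipids and glucose, mmHg, kg/m², years). Equations expecting mg/dL say
  so in their spec; the engine converts at the term boundary
  (38.67 mg/dL per mmol/L for cholesterol, 18.02 for glucose).
* **Category bands** are half-open $[lo, hi)$ and must partition the real
  line, so exactly one coefficient applies to any input; "referent" bands
  carry coefficient 0. A systolic pressure of exactly 130 therefore
  leaves the 120–129 band.
* **Conditional terms** (treated vs untreated blood pressure) are two
  terms guarded by complementary predicates.
* **Clipping.** Risk is clipped to $[0,1]$ after all multipliers; the ×5
  female diabetes multiplier can otherwise exceed certainty.
* **Horizon rescaling.** When a spec lacks $S_0$ at the requested horizon
  the engine can rescale from the native horizon by
  $S_0(h) = \exp(\ln S_0(H)\,h/H)$ — a constant-hazard-fraction
  assumption, i.e. cumulative baseline hazard proportional to time. The
  original method used to move ten-year baselines to five years is not
  published in a reproducible form, so this rule is explicit, documented,
  and overridable by cohort estimation (Section 4), which is preferred
  whenever target-cohort data exist.

### SCORE-type ("weibull_score") equations

The SCORE family models two causes (coronary, non-coronary CVD)
separately. Per cause, baseline survival in attained age $a$ is
$S_0(a) = \exp(-\exp(\alpha)(a-20)^p)$, shifted proportionally by
$w = \beta_1(\mathrm{TC}-6) + \beta_2(\mathrm{SBP}-120) +
\beta_3\,\text{smoker}$; the risk over $h$ years is
$1 - S(a+h)/S(a)$ per cause and the two are summed. The form is undefined
below age 20 and the engine refuses such input. Because the published
cause parameters ($\alpha, p, \beta$) are not reproduced in the source we
transcribe from, the shipped SCORE spec files carry *synthetic
placeholder* parameters (so the code path is fully exercised) and are
labelled as such in filename and notes; real use requires user-supplied
parameter files. Diabetes is not a SCORE covariate; following the
validation convention for this population, predicted risk of diabetic
subjects is multiplied by 3 (men) or 5 (women), attached to a spec via
`adjust_score_spec()` and applied at scoring time.

## 2. Discrimination

The event for ROC purposes is binary: CVD death within the evaluation
horizon. This matches how sensitivity, specificity and AUC are reported
in the validation literature we mirror; it is not a censoring-adjusted
time-dependent AUC, and with ~looser follow-up the two can differ. The
AUC is the Mann–Whitney concordance (ties get half credit) with DeLong
confidence intervals and paired DeLong tests between models on the same
subjects (via pROC). Operating points classify positive at
score ≥ cut-off (inclusive, consistent with "high risk is ≥ 20%"), with
Clopper–Pearson intervals for sensitivity and specificity and
LR⁺ = Se/(1−Sp), LR⁻ = (1−Se)/Sp reported as infinite when degenerate.
The confidence-interval methods are not stated in the work we mirror;
DeLong and Clopper–Pearson are standard, and the choice is recorded in
the pipeline report metadata.

The "cut-off recommended by the present population" is taken to be the
Youden-optimal cut-off (maximize Se + Sp − 1 over observed score values,
smallest value on ties); the selection rule was unstated in the source
and this assumption is flagged in the report metadata.

## 3. Calibration: the Greenwood–Nam–D'Agostino test

Subjects are split into ten groups by deciles of predicted risk (tied
predictions stay together). Any group with fewer than `min_events = 2`
events observed by the horizon is merged into the adjacent group whose
mean predicted risk is closer (edge groups merge inward; the lowest-risk
violator is processed first), repeating until every group complies. The
observed risk per group is $1-\mathrm{KM}_g(h)$, with Greenwood variance,
and

$$\chi^2_{\mathrm{GND}} = \sum_g \frac{(\mathrm{KM}_g - \bar p_g)^2}
  {\widehat{\mathrm{Var}}(\mathrm{KM}_g)}, \qquad \text{df} = G-1 .$$

Zero-variance groups (no events, or survival reaching zero) are excluded
with a warning. Whether the variance in the published analyses was
Greenwood or binomial $\bar p(1-\bar p)/n$ is not stated; both are
implemented (`variance =` argument), Greenwood is the default, and the
choice is recorded in report metadata.

**The degrees-of-freedom convention, and an honest caveat.** The
published chi-square/p pairs we reproduce (5.109 over 5 groups → 0.276;
2.917 over 4 groups → 0.405; 2.310 over 5 groups → 0.679) all pin
df = $G-1$, so that is the package's convention. For *external*
validation, however — no coefficients estimated on the validation data,
groups independent — each group contributes an asymptotically standard
normal deviate and the statistic is asymptotically $\chi^2_G$, not
$\chi^2_{G-1}$. Referring it to $G-1$ degrees of freedom is therefore
mildly liberal: with $G=10$ the asymptotic size at nominal 0.05 is
$P(\chi^2_{10} > q_{0.95,9}) \approx 0.0755$. The test suite measures
exactly this: simulating cohorts from a known proportional-hazards model
and validating that model against its own data (n = 5000, ~26% five-year
risk so each decile holds over a hundred events, 1000 replicates) gives a
rejection rate of about 0.08 at $\alpha = 0.05$ — and the corresponding
acceptance check, which demands the nominal [0.03, 0.07], fails for that
structural reason and is knowingly left failing rather than papered over
by switching conventions per test. At sparse event counts (a couple of
events per group, as in low-mortality cohorts with the minimum merge
rule) the Wald-type statistic with estimated variance is anticonservative
well beyond that, so GND p-values near 0.05 should be read cautiously in
sparse settings.

## 4. Recalibration

Two modes, mirroring how the shipped parameter sets were built:

* **mean-only** keeps the original coefficients and replaces $\bar L$
  (the cohort mean of the linear predictor) and $S_0(h)$;
* **full** first refits every coefficient by Cox partial likelihood on a
  design matrix that reproduces the spec's covariate structure exactly —
  same transforms, one indicator column per non-referent band, the same
  treated/untreated split, the same interaction products — then replaces
  $\bar L$ and $S_0(h)$.

$S_0(h)$ is the Breslow cumulative-hazard estimate centered at $\bar L$:
$S_0(h) = \exp(-H_0(h))$ with $H_0$ computed on predictors $L - \bar L$,
which is precisely the baseline the risk formula expects. Interaction
terms contribute their full product to the mean (the published "Mean
(Coefficient × Value)" is only reported as a total, so the package treats
it as the mean of $L$ over subjects; with interactions this is the only
construction that is well defined from subject-level data). SCORE Weibull
shape/scale parameters are *not* refit — recalibration for that family is
limited to the diabetes-multiplier attachment and horizon evaluation —
because the source work adjusted but did not refit them. Refits require
at least 30 events by default and refuse separation (|coef| > 50) or
non-convergence.

The self-recalibration closure property holds and is tested: fully
recalibrating a model on a 20 000-subject cohort generated from that very
model (at a realistic ~2% five-year baseline risk) moves per-subject
risks by a median of well under 0.002.

## 5. The synthetic cohort generator

The generator emulates the validation population's published baseline
table: per-sex means/SDs for age, total cholesterol, HDL, fasting
glucose, SBP and BMI; prevalences of smoking (72.9% men / 0.28% women),
diabetes, hypertension and treatment among hypertensive; 38.16% men.
Design choices:

* **Gaussian copula** over the six continuous factors with an
  exchangeable correlation of 0.2 — a declared assumption, since only
  marginals are published. The correlation matrix is user-configurable
  and validated for positive-definiteness.
* **Age** is truncated-normal on [40, 65]; the parent mean is solved so
  the *realized* truncated mean equals the declared value. The published
  age SD (≈7.2 within a 25-year window) lies essentially at the uniform
  bound $(65-40)/\sqrt{12}$, outside what a truncated normal can realize,
  so only the mean is matched and the realized SD is ≈5.9 — a known,
  documented limitation of the marginal family.
* **Other marginals** are normal with physiologic floors (e.g. HDL ≥ 0.3
  mmol/L); at realistic parameters the floors bind with probability
  below $10^{-4}$ and do not measurably move the means.
* **Outcomes** are Weibull proportional hazards for two competing causes
  (CVD, other death), shape 1 by default over the short six-year window,
  with a priori plausible log hazard ratios (per-year age 0.09, male
  0.45, per-mmol/L cholesterol 0.15, per-mmHg SBP 0.016, smoking 0.60,
  diabetes 0.70) centered at the published overall means. Other-cause
  death censors CVD death; loss to follow-up is off by default (the
  emulated cohort excluded subjects lost to follow-up upstream) but
  available as an exponential rate.
* **Calibration of the scales.** The two Weibull scales are chosen by
  `calibrate_baseline_hazard(account_competing = TRUE)` so the *observed*
  six-year death fractions — after competing-cause censoring — are 1.6%
  (CVD) and 4.0% (all causes). Given simulated covariate profiles the
  cause-specific death probability has a closed form when the causes
  share a shape, so the only Monte-Carlo noise in the calibration is the
  covariate draw (200 000 profiles); log-scale bisection stops within
  ±0.001 of the target by contract.
* **Reproducibility.** One master seed drives the whole draw in a fixed
  order; the same config yields a byte-identical cohort.

What passing the fidelity tests shows: the generator reproduces the
declared per-sex means (within 3 standard errors at n = 50 000), the sex
mix, the binary prevalences, and the target observed mortality. What it
does not show: anything about the true joint distribution of risk factors
in the real population (the copula correlation is assumed), about the
real age shape (under-dispersed here), or about real covariate-outcome
associations (the hazard ratios are declared, not estimated). Pipeline
results on synthetic cohorts validate the *machinery*, not the
epidemiology.

## 6. Numerical and interface choices

* Percentages are rounded half-up (2 decimals in summaries, 1 for
  headline rates) to match conventional display; `round_half_up()` is
  exported because base R rounds half-even.
* Non-CVD deaths are treated as censoring at death time in all
  Kaplan–Meier work (no competing-risks estimator) — deliberately
  matching the validation convention being mirrored; with ~2.4% competing
  mortality over six years the bias is second-order.
* Risk-category boundaries are inclusive upward everywhere (a risk equal
  to a threshold takes the higher category).
* Cross-model agreement between the four-category Pooled-Cohort scale
  and three-category scales uses a declared mapping (<7.5% → low,
  7.5–19.9% → intermediate, ≥20% → high), configurable per call.
* The evaluation horizon defaults to 5 years for recalibrated models
  while the generator follows subjects for 6; both are explicit
  arguments, because the validation setting mixes five-year predictions
  with six-year follow-up.
* Pipeline reports record every such choice (CI methods, variance
  flavour, df convention, category mapping, seed, versions) in their
  metadata block so a result can be audited from the JSON alone.
* Test problem sizes were chosen to make the statistical assertions
  sharp but cheap: 1000 replicates × n = 5000 for the GND size study,
  n = 20 000 for recalibration recovery, n = 50 000 for generator
  fidelity; the full suite runs in well under a minute on one core.

## 7. Known limitations

* The GND size issue under df = $G-1$ described in Section 3.
* The two transcription anomalies in the shipped parameter sets
  (Section 1); the affected PCE-white women spec saturates on realistic
  cohorts and its rank correlation with other models is undefined.
* SCORE specs ship with synthetic placeholder Weibull parameters only.
* The generator draws hypertension independently of the simulated SBP
  (both match their marginals, but their joint behaviour is not
  constrained); treatment is drawn only among hypertensive subjects.
* No survey weighting, no imputation of missing covariates, no
  competing-risks calibration, no net-reclassification or decision-curve
  analysis — all out of scope.
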