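---
title: "Height-corrected BMI: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Height-corrected BMI: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shrinkbmi)
```

## The problem

Body mass index, $\mathrm{BMI} = w / h^2$ (weight in kg, height in m), is the
standard anthropometric proxy for adiposity, but its denominator is not
constant over a lifetime: stature declines from roughly the fifth decade
onwards — vertebral compression, disc narrowing, kyphosis — at population
rates of a few centimetres over 40 years, faster in women than in men.
Because $h$ enters squared, a person whose weight never changes drifts
upward in BMI as they shrink. Around the conventional cutoffs (25 kg/m²
for overweight, 30 kg/m² for obesity) this purely geometric inflation
reclassifies people into higher risk categories without any change in
body composition.

`shrinkbmi` implements a longitudinal remedy: each subject is compared with
themselves. From repeated exams we estimate a subject's *young height* (mean
stature at ages 40 and under), define the *corrected BMI* as current weight
over squared young height, and quantify three consequences:

1. **Excess BMI** — current minus corrected BMI, the inflation attributable
   to height loss alone;
2. **Misclassification** — the age-resolved fraction of subjects whose
   current BMI places them in the overweight or obese category while their
   corrected BMI does not ("wrong overweight", "wrong obese");
3. **Risk distortion** — the relative risk of pre-diabetes, diabetes and
   hypertension in obese versus non-obese subjects, computed under both BMI
   definitions, within age bins.

Because cohorts with five decades of measured stature are access-restricted,
the package ships a synthetic cohort generator with a latent truth table, so
every estimator can be validated by parameter recovery under known
conditions.

## Per-subject smoothing and outlier rejection

Archival height records carry two artefacts: gross transcription blunders
(apparent growth or shrinkage of several inches) and quantisation (height
floored to the next lower quarter inch, weight to the nearest 5 lb), which
makes a subject near a rounding threshold oscillate between two values.
Both are handled per subject, before any population summary:

* **LOWESS** (`lowess_fit()`): locally weighted degree-1 regression with
  tricube weights, evaluated at the observation ages, for subjects with at
  least 4 exams. We use span `frac = 0.6` and *zero* robustness iterations:
  robustness is supplied instead by the explicit rejection rule below, so
  that exactly one, auditable mechanism decides which points are discarded.
  The span is a compromise — wide enough that a 25-exam series averages away
  quarter-inch oscillation, narrow enough to track the onset of decline; it
  is exposed as an argument throughout.
* **Two-threshold rejection** (`reject_outliers()`): a point is an outlier
  iff its absolute residual exceeds six times the subject's median absolute
  residual *and* is at least 1 cm (height) or 0.2 kg/m² (BMI). The median
  is taken over the subject's own residuals, making the rule scale-aware;
  the absolute floor prevents flagging benign rounding scatter in subjects
  whose median residual is tiny. The multiplicative comparison is strict
  (`>`, "more than six times"); the floor is inclusive (`≥`, "at least").
* **One rejection–refit cycle** (`smooth_with_rejection()`): fit, flag,
  refit once on the retained points. The refit is evaluated at *all*
  original ages (linear interpolation of the refit curve at flagged ages,
  linear extrapolation at the ends) so that per-age downstream metrics stay
  defined. If fewer than 4 points would survive, rejection is abandoned and
  the first fit kept — a deliberate fail-safe for short noisy series.
  Iterating to convergence was rejected: on series of 20–25 points a second
  pass mostly chases the absolute floor, and a single recalculation keeps
  the procedure auditable.
* **BMI consistency** (`bmi_consistency_filter()`): an exam whose recorded
  BMI differs by 5 kg/m² or more from the BMI recomputed out of recorded
  weight and (smoothed, when available) height is excluded from the BMI
  series entirely — such a row has an internally inconsistent record and no
  smoothing can tell which field is wrong.

Height is smoothed first; the consistency check and the BMI smoothing then
use the smoothed height. Series with fewer than 4 points pass through
unsmoothed and unflagged.

## From trajectories to the three BMI quantities

Eligibility requires at least one exam at age ≤ 40 and one after 40
(`eligible_subjects()`); the boundary age 40 counts as "young" in both the
eligibility rule and the young-height average, so the two filters cannot
disagree about the same exam. Young height is the mean of the (smoothed
when available) heights at ages ≤ 40, excluding rejected points
(`young_height()`). Per exam we then compute shrinkage (young − current
height), current BMI (the smoothed BMI series), corrected BMI (recorded
weight over squared young height) and excess BMI (current − corrected).
The sign convention makes excess BMI non-negative whenever stature has
declined; under measurement noise slightly negative shrinkage and excess
values occur and are reported as-is rather than clipped, so that population
means stay unbiased.

Corrected BMI deliberately uses the *raw recorded weight*, not a smoothed
weight: weight fluctuation is physiological signal, and the corrected BMI
is meant to respond to it; only the height in its denominator is an
estimate.

## Misclassification and relative risk

Categories split at 25 and 30 with left-closed intervals (`[25, 30)` is
overweight). Curves are computed in 5-year age bins centred on multiples of
5 (bin "80" is `[77.5, 82.5)`); a subject contributes one exam per bin —
the one closest to the bin centre, ties resolved toward the younger exam —
so that subjects with two exams in a bin are not double-counted. Both
denominators are reported: the whole population of that sex in the bin, and
the subjects currently in the category. Empty denominators yield `NA`,
distinct from a true zero fraction.

Disease definitions follow common operational thresholds on the recorded
measurements: pre-diabetes is non-fasting glucose strictly above 140 and at
most 200 mg/dL, diabetes strictly above 200 mg/dL (mutually exclusive by
construction); hypertension is an antihypertensive-medication code, or
SBP ≥ 140 mmHg, or DBP ≥ 90 mmHg. Relative risk is the plain prevalence
ratio — disease fraction among the obese over the fraction among the
non-obese — with "non-obese" meaning everyone below 30 under the chosen BMI
variant, overweight included. It is prevalence at exam, not incidence: the
records state presence of disease at visits, and no attempt is made to date
onset. Degenerate strata (no non-obese events, or an empty stratum) return
`NA` rather than an infinite or invented ratio; a log-RR Wald interval is
attached for plotting only. Pre-diabetes excludes diabetics; with the
categorical glycemic coding used here the alternative (cumulative) reading
can be recovered by OR-ing the two flags.

## Population trends

Height loss is summarised by pooled OLS of per-exam shrinkage on years past
age 35, linear and quadratic (`fit_trend()`), reported as the predicted
loss between ages 40 and 80 (`total_loss_40_80()`). The predictor "years
after 35" is treated as a non-negative quantity: exams before 35 lie
outside its domain and are dropped, while pre-onset exams at 35–40
contribute their (near-zero) shrinkage, the intercept absorbing the offset.
A pooled fit (no per-subject random effects) is used advisedly: the aim is
a descriptive population curve, not subject-level inference, and the
generator's truth table provides the unbiased check of the subject-level
rates. Excess BMI gets a degree-1 fit against age (or, optionally, against
shrinkage). Fits are reproducible from the stored inputs and expose
broom-style `tidy()`/`glance()` methods.

## The synthetic cohort generator

`simulate_cohort()` draws, per subject: sex; an enrollment age uniform on
30–38 with biennial exams to age 80 (so eligibility holds by construction,
with several exams on each side of 40); a young height
(women N(160.5, 6) cm, men N(174, 6) cm); a height-loss rate truncated at
zero (women N(0.12, 0.02) cm/yr, men N(0.09, 0.02) cm/yr — 4.8 cm and
3.6 cm over ages 40–80 at the means); and a young-adult BMI from a
truncated normal (women N(25.5, 3.5) on [17, 35], men N(26, 3.5) on
[19, 35]). True height is constant to the onset age 40 and declines
linearly after. Weight follows the BMI trajectory — young BMI, plus
0.05 kg/m²/yr drift after 40, plus N(0, 0.3) exam-to-exam noise — applied
to the *true young height*, so the latent obesity state (`true_obese`) is
the young-height BMI at each exam. The measurement layer adds N(0, 0.5) cm
height noise, gross errors with probability 0.01 per exam (±2.5–10 cm,
random sign), quarter-inch flooring and 5-lb rounding (half-up; flooring
uses a 1e-7 relative epsilon so that an already-floored value is a fixed
point); recorded BMI is recomputed from the recorded weight and height.

Disease states are drawn *state-first*: per exam, one categorical draw over
normal / pre-diabetic / diabetic with marginal probabilities
$\mathrm{base}(a) \cdot RR^{\mathrm{obese}}$ (clamped so the two sum below
1), and a Bernoulli for hypertension; glucose and blood pressure are then
drawn uniformly within the state's band (e.g. glucose in (140, 200] for
pre-diabetics), and half of hypertensive exams are coded as medicated, half
of those with sub-threshold pressures, so the medication clause of the
definition is genuinely exercised. Risk is tied to the *true* (young-height)
obesity state, with default ratios 2.8/2.4 (pre-diabetes, F/M), 3.5/2.8
(diabetes) and 1.5/1.8 (hypertension) over base prevalences that rise
linearly with age. This construction makes the configured prevalence ratio
hold exactly in expectation, which is what the parameter-recovery tests
need, and it encodes the substantive hypothesis that disease risk follows
body build (young-height BMI), not the geometrically inflated current BMI —
whence corrected-BMI relative risks exceed current-BMI ones at shrunken
ages, because the current-BMI obese stratum is diluted with "wrong obese"
subjects carrying non-obese risk.

Glucose and blood-pressure *marginal* distributions are calibration
choices, not estimates of any real cohort: only their exceedance structure
(which side of each diagnostic threshold) matters to the pipeline. What the
generator does **not** emulate: birth-cohort stature effects (it simulates
within-person decline only), mortality and dropout (every subject survives
to 80, so old-age bins are fuller than in any real cohort), weight-loss
illness near death, correlated measurement drift between exams, and
population structure beyond sex. Passing recovery tests on this generator
therefore shows the estimators are correct under the stated model — not
that the model captures everything in real archival data.

A single integer seed determines the entire cohort; identical config and
seed reproduce byte-identical tables.

## Numerical and degenerate-input choices

* LOWESS needs 4 points; below that, series pass through untouched.
* Rejection falling below 4 retained points abandons rejection (flags
  cleared) instead of refitting an unstable curve.
* Strictly increasing ages per subject are enforced at load time
  (duplicate `(subject, age)` rows are a hard error with the pair named).
* All-flagged early exams fall back to the unfiltered early mean for the
  young height rather than failing the subject.
* Truncated normals are drawn by inverse-CDF, keeping determinism under a
  single seed and exact truncation bounds.
* Fractions with empty denominators and relative risks with zero
  comparison events are `NA`, never 0, `Inf` or an exception.

## Problem sizes

The shipped tests exercise the estimators at the sizes where their
Monte-Carlo error is comfortably below the assertion tolerances: trajectory
and rule-level checks on series of 4–25 points against an independent
direct tricube weighted-least-squares oracle (agreement to 1e-8); cohort
recovery checks at 400–2000 subjects; the headline recovery runs use 1000
subjects per sex for the height-loss trend and five replicate cohorts of
2000 women for the misclassification and relative-risk summaries
(`scripts/acceptance.R` reproduces these from a single seed).

## Known limitations

The pooled shrinkage slope over years-past-35 slightly under-states the
post-onset loss rate, because pre-onset zeros at ages 35–40 flatten the
line and the smoother rounds the onset corner; the predicted 40–80 loss
lands a few percent below the generator's calibrated value. The default
young-BMI distribution concentrates more mass just below the obesity
cutoff at old ages than a mid-century cohort would, which raises the
wrong-obese fraction relative to the wrong-overweight one; both fractions
scale directly with that input distribution, which is fully configurable.
Corrected-BMI relative risks are mildly attenuated against the configured
truth by boundary flicker (exam-to-exam BMI noise moves subjects across
the 30 kg/m² line) and weight rounding. None of these affect the ordering
results (corrected ≥ current RR; monotone misclassification growth with
shrink rate), which are structural.
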