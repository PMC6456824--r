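---
title: "Methods: day-level causal analysis of coupled sleep and mood diaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: day-level causal analysis of coupled sleep and mood diaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Daily diary (EMA) studies record two coupled self-report series per person:
sleep quality each morning and mood through the day, both on 0–8 Likert
scales, alongside covariates that may drive both (stress, energy, focus,
physical activity, weather, work schedule). Two directional questions arise:
does a good night's sleep improve the next day's mood, and does a good day's
mood improve the following night's sleep? `sleepmood` implements a pipeline
for both questions at two levels:

* **Population level** — linear mixed-effects models of the lagged day pairs,
  on raw scores and on within-person z-normalized scores.
* **Person level** — a per-subject "personal causal effect": the treatment
  series is binarized at the subject's own mean, days are matched on a
  within-subject propensity score, and the effect is the standardized mean
  difference (SMD, a Cohen's-d-type statistic) in outcome between matched
  treated and control days. Cohort summaries are bootstrap means over
  subjects.

Because raw per-person diary panels of this kind are rarely shareable, the
package includes a synthetic cohort generator with known ground truth so that
every stage of the pipeline is testable against simulated truth.

## Day pairing and lag conventions

Sleep reported on the morning of day *t* describes the night ending that
morning. The two directional datasets are:

* `sleep_to_mood`: treatment = sleep quality reported morning of day *t*,
  outcome = mean mood of day *t* (same-day pairing);
* `mood_to_sleep`: treatment = mean mood of day *t*, outcome = sleep quality
  reported morning of day *t + 1*.

Mood, stress, energy, and focus are rated up to three times a day and enter
as the daily mean of the available ratings. The confounder vector of a row
holds stress, energy, focus, activity minutes, mean temperature, and
clear-sky minutes from the **day before the outcome day**, plus the day of
week and day type of that same day. This timing is genuinely ambiguous in
day-diary designs — "the previous day" cannot distinguish the two directions
— so `build_lagged_dataset(confounder_timing = "before_treatment")` switches
to the other convention; the default conditions on the information available
just before the outcome realizes.

History depth `T` (0–3) adds the mood and sleep values 1..`T` days before
the **treatment day** to the confounder vector. Anchoring history at the
treatment day keeps the two directions symmetric and avoids the degenerate
reading in which the first "lag" of mood in the mood-to-sleep direction would
be the treatment itself. All required days must be consecutive calendar days
present in the diary; any missing component drops the row — nothing is
imputed, matching the no-imputation convention of diary studies.

## Within-person normalization

People use response scales differently (both baseline and range). The
normalized arm replaces each subject's sleep and mood series by z-scores
using that subject's own mean and sample SD (n−1). Subjects with zero SD in
a variable cannot be normalized; they are flagged in the `zero_sd` attribute
and their values set to `NA` rather than silently dropped. Because
z-normalization removes any positive affine map exactly, the normalized
analysis is invariant to per-subject reporting styles *as applied to the
observed values*; note that the generator's ordinal rounding happens before
the analyst ever sees the data, so regenerating a cohort with different
styles gives approximately (not bit-) identical z-series.

## Mixed-effects models

The raw-score model is `outcome ~ treatment + (1 + treatment | subject)`,
REML, with a standard simplification ladder on non-convergence (correlated →
uncorrelated random effects → random intercept only; the rung used is
recorded). After within-person normalization every subject has mean 0 and SD
1 in both variables, so the normalized model drops the intercept entirely:
`outcome ~ 0 + treatment + (0 + treatment | subject)`. The reported p-value
is the large-sample normal approximation on `b1/se`; no degrees-of-freedom
correction is applied, appropriate at cohort sizes of tens of thousands of
rows. The two directions are compared by resampling subjects with
replacement (default 100 replicates), refitting both models per replicate,
and taking a two-sided percentile p-value for the difference in slopes.

## Per-subject propensity-score matching

For one subject and one direction:

1. **Exclusion** — subjects whose raw daily treatment variance is below 0.5
   (strict `<`, sample variance) do not admit a reliable above/below-mean
   discretization and are excluded, with the exclusion recorded. The n−1
   variance convention matches the z-score convention; the threshold and
   formula are configurable.
2. **Binarization** — days strictly above the subject's mean treatment are
   treated, the rest controls (ties at the mean are controls by default;
   configurable). The rule is invariant to positive affine rescaling.
3. **Propensity** — a logistic model of treatment on the standardized
   confounder vector (categoricals one-hot coded, first level dropped),
   fitted by Newton iteration with a small L2 penalty (default 1, intercept
   unpenalized). The penalty guarantees a finite fit under the perfect
   separation that is routine on a few dozen rows; with no varying
   confounders the scores collapse to the treated fraction.
4. **Matching** — greedy 1:1 nearest-neighbor on the logit propensity,
   without replacement, processing treated days in seed-shuffled order,
   within a caliper of 0.2 SD of the logit propensity by default.
5. **Effect** — SMD between matched groups: difference in mean outcome over
   the pooled (df-weighted) SD of the two matched groups. One matched pair
   cannot yield a pooled SD and is recorded as degenerate.

The unmatched comparator applies steps 2 and 5 to **all** paired days
(without requiring confounder completeness), mirroring the "no matching"
reference analysis.

Every gate (variance filter, single-class binarization, too few per class,
no match, degenerate outcome) produces an explicit exclusion record, because
silent sample attrition is the main audit risk of per-subject matching.

### The caliper trade-off

On per-subject series of ≤ ~42 days, the propensity model (14+ design
columns on 20–30 rows) is necessarily overfitted and its in-sample logits
spread widely whether or not true confounding exists. A caliper therefore
behaves very differently than in large-cohort epidemiology:

* **With the 0.2-SD caliper (default)**: under a strong shared daily
  confounder the caliper trims off-support days and the matched cohort mean
  returns to the simulated truth of zero while covariate |SMD| falls — the
  bias-correction property one matches for. The price is ~4 pairs per
  subject, per-subject effect SDs of 1 or more, and at history depth 3 a
  small, upward-biased surviving sample.
* **Without a caliper (`caliper = NULL`)**: near-balanced classes mean every
  treated day finds a partner, retention is ~9–12 pairs with per-subject SD
  ≈ 0.5, and the matched series is stable across history depths — but no
  trimming means essentially no confounding correction; the matched estimate
  tracks the unmatched one.

Both behaviors were measured on simulated cohorts (with-replacement matching
and stronger or cross-validated penalties were also measured and dominate
neither). There is no single configuration that both corrects strong
confounding and preserves the precision needed to detect moderate group
differences at this series length; the package defaults to the trimming
configuration because correction is the purpose of matching, and exposes the
rest. Users analysing cohorts they believe weakly confounded and who need
power for group contrasts should set `caliper = NULL` deliberately.

## Inference

Cohort means of per-subject effects are bootstrapped over subjects (default
100 replicates, matching common practice for such error bars); reported error
bars are the bootstrap SD and the interval is the 2.5/97.5 percentile range.
Direction comparisons pair each subject's two effects where possible (paired
bootstrap) and fall back to unpaired resampling with a flag when the subject
sets are disjoint. Group contrasts versus control use unpaired bootstrap
because groups contain different subjects. All p-values are two-sided
percentile-bootstrap p's with a +1 continuity correction, so the smallest
attainable p at 100 replicates is ≈ 0.02; no multiple-testing correction is
applied across contrasts. The history-depth sweep runs the unmatched arm and
matched arms at `T = 0..3`, reporting per-arm exclusion counts (analyzable
rows necessarily shrink as `T` grows).

## The synthetic cohort generator

The generator emulates a four-group design (control, depressed, anxious,
depressed-and-anxious), with screening scores drawn from truncated normals
honouring the PHQ-9 ≥ 10 / GAD-7 ≥ 10 cutoffs and group means/SDs typical of
such cohorts, 52 subjects per group and 42 planned days by default, and MCAR
day-level missingness (default 20%).

Latent dynamics per subject (day *t*, night indexed by its morning):

* `mood(t) = ar_m * mood(t-1) + b_sm * sleep(t) + s * c(t) + e(t)`
* `sleep(t+1) = ar_s * sleep(t) + b_ms * mood(t) + s * c(t) + e'(t)`

where `c(t)` is a shared standard-normal daily confounder that is also
emitted — with construct-level and rating-level noise — as the observable
stress, energy, and focus ratings. That makes stress/energy/focus *genuine
measured confounders*: correlated with treatment and outcome, and available
to the propensity model. Weather, activity, day of week, and day type are
exogenous noise covariates, so a balance table on simulated data shows the
realistic pattern of near-zero correlations for weather/activity/schedule and
moderate correlations for the affect constructs.

Observed ratings apply the subject's reporting style and ordinalize:
`round_half_up(clip(4 + scale * latent + shift, 0, 8))`, with three
within-day draws for mood/stress/energy/focus and one morning draw for
sleep.

Default parameter choices, fixed at design time:

* cross-lags `b_sm = 0.35`, `b_ms = 0.13` — the asymmetry magnitude typical
  of within-person day-level sleep/mood studies;
* persistence `ar_m = ar_s = 0.1` — kept modest so the marginal lag-1
  standardized association is dominated by the cross-lag coupling and the
  generative coefficient remains interpretable as ground truth (with strong
  persistence, a marginal lag-1 model would conflate carryover with
  coupling);
* `noise_sd = 1`, per-rating noise 0.25, style scale LogNormal(log 1.3,
  0.25), shift N(0, 0.7), confounding loading 0.3.

What the generator does **not** emulate: informative missingness (dropout,
compensation effects), weekly or seasonal mood cycles, floor/ceiling
response styles beyond affine shift/scale, and item-level (as opposed to
day-level) missingness. Passing tests on this generator therefore shows the
pipeline recovers truth under MCAR, affine response styles, and additive
shared confounding — not that it is robust to informative dropout or
non-affine scale use.

Ordinal measurement attenuates: the 0–8 rounding plus rating noise shrinks
the recoverable normalized slope by roughly 7–10% relative to the latent
coefficient, and modest persistence adds a small upward term; the recovery
tests budget for both (±0.07 at 100 subjects × 42 days).

## Numerical and degenerate-input conventions

* Round-half-up (not banker's rounding) in the Likert map, so the
  ordinalization is monotone at the .5 boundaries.
* Zero-variance subjects: flagged and excluded per variable, never silently
  dropped; zero-variance confounder columns are dropped from the propensity
  design; an all-constant design gives scores equal to the treated fraction.
* Propensity scores are clamped to (1e-8, 1 − 1e-8) before the logit.
* Matching ties (equidistant controls) resolve to the earliest candidate
  index; the treated processing order is shuffled by the configured seed, so
  a fixed seed gives bit-identical matches.
* Mixed-model fits with zero residual variance (exact linear relations)
  return the slope with `NA` standard error rather than failing.
* A master seed is fanned out to stage-specific sub-seeds through a fixed
  affine map modulo 2^31 − 29, so each stage is individually reproducible.

## Problem sizes used in the shipped checks

The package's own test suite validates parameter recovery and test
calibration on cohorts of 52–208 subjects × 42 days across 20 simulation
seeds per property, group-contrast behavior at 50 subjects per group, and
exact oracle equivalence of the matching chain on 8-day diaries; these sizes
were chosen to mirror the study scale the generator emulates while keeping
the full suite comfortably runnable on one CPU.

## Known limitations

* The personal effect is a Cohen's-d form statistic; on very small matched
  samples |d| is biased upward (no Hedges correction is applied, to keep the
  statistic exactly the documented closed form), which is visible in the
  `T = 3` arm of calipered sweeps on short diaries.
* Percentile-bootstrap p-values at 100 replicates are granular (min ≈ 0.02).
* Matching is strictly within subject; no pooled or hierarchical propensity
  model is offered.
* Treatment binarization at the subject mean discards within-class dose
  information by construction.
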