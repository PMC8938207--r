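---
title: "Methods: post-ETV ICP trend classification and diagnostic evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-ETV ICP trend classification and diagnostic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icptrend)
```

## The clinical question and the model

Endoscopic third ventriculostomy (ETV) treats obstructive hydrocephalus by
opening a bypass in the floor of the third ventricle. Whether the stoma
keeps working is hard to judge early: ventricles stay large on imaging even
when the patient does well. One direct window on stoma function is the
intracranial pressure (ICP) itself, recorded hourly through the external
ventricular drain left in place after surgery.

`icptrend` implements the three-stage analysis of such recordings:

1. **Summarization.** Hour indices count from the start of monitoring
   (which begins four hours after skin closure; that offset is metadata,
   not part of the indexing). Day $d$ covers hours $24(d-1)$ to $24d - 1$,
   a half-open window, and the daily average value is the arithmetic mean
   of that day's readings. Only days 1–3 enter the analysis; later readings
   are dropped with a warning.
2. **Trend classification.** At margin $\delta$ a patient is a
   *progressive increase* iff the DAVs rose continuously
   ($DAV_1 < DAV_2 < DAV_3$, strict) **and** $DAV_3 - DAV_1 > \delta$
   (strict). *Stable* is the complement. The margin is swept over a grid
   (default $\delta \in \{1,\dots,5\}$ mmHg), and the progressive sets are
   provably nested as $\delta$ grows — `sweep_margins()` asserts this on
   every run.
3. **Diagnostic evaluation.** The trend is treated as a binary test for the
   six-month outcome in two mirrored directions. With the stable trend as
   the test positive and success as the condition positive, sensitivity is
   $P(\text{stable}\mid\text{success})$, specificity
   $P(\text{progressive}\mid\text{failure})$, and PPV/NPV the corresponding
   posterior proportions; swapping the direction exchanges sensitivity with
   specificity and PPV with NPV. Each proportion carries an exact
   Clopper–Pearson interval, trend strata get success rates, and the 2×2
   table gets an uncorrected Pearson chi-square.

## Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_readings_per_day` | 24 | readings | A day's average is only meaningful from the full hourly record; any interrupted day marks the patient incomplete, which reproduces the usual "analyzable subset" logic of monitoring studies. Configurable down to 1 for exploratory reuse. |
| `margins` | 1–5 | mmHg | The conventional sweep grid for the day-1→day-3 rise. |
| `rule` | `"monotone"` | — | "Continuously increased" is read as strict monotonicity through day 2; ties go to stable because stable is defined as the complement. `"net_only"` drops the monotonicity clause — published nested counts cannot distinguish the two readings, so the choice is exposed as a switch rather than hard-coded. |
| `confidence` | 0.95 | — | Two-sided level for all intervals. |
| `ci_method` | `"clopper-pearson"` | — | See below. |
| `correct` | `FALSE` | — | Yates continuity correction off; see below. |

## Numerical choices

* **Strict inequalities, no rounding.** Both classification inequalities
  are strict (a rise of exactly $\delta$ is stable) and DAVs are compared
  at full floating precision; rounding conventions differ between
  statistical packages, and exact comparison is the only reproducible
  choice.
* **CI method identification.** The exact interval's closed-form lower
  bound at $x = n$ is $(\alpha/2)^{1/n}$: for 4/4 that is
  $0.025^{1/4} = 0.3976$, which matches the published bound 39.76 for that
  cell, and 4/19 matches the exact Beta quantiles 6.05–45.57. Score or
  Wald intervals do not reproduce these bounds, identifying the exact
  method; Clopper–Pearson is therefore the default, with Wilson available
  by flag (`wilson_interval()`). Exact intervals are conservative —
  empirical coverage is at or above the nominal level, which the test
  suite checks by simulation.
* **Chi-square without continuity correction.** On the 2×2 table at the
  >1 mmHg margin (stable 11/11, increasing 8/1) the uncorrected Pearson
  statistic gives $p = 0.0436$, matching the published $p = 0.044$; the
  Yates-corrected value ($p = 0.107$) does not. Uncorrected is the
  default, correction available by flag. The statistic is undefined when a
  row or column marginal is zero and is reported as such.
* **Undefined metrics.** Any proportion with an empty denominator (e.g.
  NPV when no patient shows the progressive trend) is reported as `NA`
  ("undefined" in rendered tables), never coerced to 0 or 1 — small
  cohorts routinely empty a stratum and a fabricated value would silently
  distort the report.
* **No multiplicity adjustment.** Per-margin p-values are reported without
  multiple-testing adjustment, as is conventional for a descriptive sweep;
  the report carries an explicit note.
* **Degenerate inputs.** Single-patient summaries report SD as missing;
  pressures outside 0–100 mmHg are a validation error (the usual cmH₂O
  vs mmHg unit mistake), not clipped.

## The synthetic-cohort generator

`simulate_cohort()` draws a cohort with the structure the analysis
assumes, with defaults fixed at the summary statistics of a 40-infant
congenital-hydrocephalus ETV cohort:

* **Opening pressure**: normal with mean 18.53 and SD 6.61 mmHg, truncated
  to 8–44 mmHg — the simplest law matching all three published summaries
  (mean, SD, range). Sampling is by inverse CDF on the truncated uniform
  range, so no rejection loop. Note the truncated-normal mean is 19.31
  mmHg, not the nominal 18.53; the generator tests check the sample mean
  against the quadrature value.
* **Trajectory archetypes**: each patient is progressive with probability
  4/31, else stable. The patient's day-1 level is normal (mean 6.36, SD
  2.46 mmHg, truncated at 0). Stable patients drift by independent
  uniform ±0.5 mmHg (`stable_jitter`) around the day-1 level; progressive
  patients rise monotonically by `progressive_drift` (default 4 mmHg)
  total, split 50/50 across the two day gaps so the "continuous rise"
  clause is satisfiable deterministically. For noiseless label-recovery
  arguments to hold, `stable_jitter` must stay below the smallest margin
  in use.
* **Hourly readings** are the day level plus independent Gaussian noise,
  floored at 0 mmHg. No published anchor exists for within-day
  variability; `hourly_noise_sd = 1.5` mmHg was chosen once as a
  realistic bedside-monitor spread (it perturbs a day mean by
  $1.5/\sqrt{24} \approx 0.31$ mmHg) and is not tuned thereafter.
* **Outcome**: six-month failure is Bernoulli conditional on the
  archetype (15/27 stable, 1 progressive — deaths count as failures,
  matching two-level outcome coding). One- and three-month outcomes
  back-date the eventual failures with fixed conditional probabilities
  derived from 62.5/40/35% success at 1/3/6 months; these cohort-level
  rates are emulated, not reproduced, since they depend on
  per-patient data that were never published.
* **Dropout**: with probability 9/40 a patient's drain is pulled and whole
  days are lost — day 2 onward or day 3 only, with equal probability,
  never single hours, because catheter pull-out is an all-or-nothing
  event. Expected analyzable subset: $40 \times 31/40 = 31$.
* **Determinism**: the seed is a mandatory config field; identical
  configurations give byte-identical CSV output.

What the generator does **not** emulate: sub-hourly waveform dynamics,
pressure–volume compliance physics, intra-operative pressures, or any
correlation between demographics/etiology and trajectory or outcome.
Passing recovery tests therefore show that the pipeline is a faithful
estimator under the stated generative model — not that the clinical
association itself generalizes.

## Problem sizes used in the test suite

Property tests run 1,000 random series against a brute-force summation
oracle, 1,000 random 2×2 tables for the direction-duality identity, 2,000
simulated binomial draws for interval coverage, and cohorts of 40–10,000
patients for distributional recovery (10,000 for moment checks, 40 × 60
seeds for the dropout expectation). These sizes keep every Monte-Carlo
check at three-sigma resolution while the full suite completes in a few
minutes.

## Known limitations

* The trend dichotomy discards the continuous day-1→day-3 difference; no
  ROC analysis over the continuous rise is attempted, matching the fixed
  published margins.
* Exact intervals are conservative; users wanting shorter intervals at
  moderate n can opt into Wilson, at the cost of no longer reproducing the
  published bounds.
* Partially recorded days are excluded wholesale under the strict default;
  there is no imputation of missing hours.
* The published lower bound 73.52 for the 12/12 cell differs from the
  exact value 73.54 by 0.02 percentage points (the original calculator is
  unknown); comparisons tolerate ±0.05 points on CI bounds.
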