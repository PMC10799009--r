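---
title: "Walking-bout assembly and two-tier agreement validation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Walking-bout assembly and two-tier agreement validation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbgait)
```

## Scope and data model

`wbgait` starts where the signal-processing ends. It assumes an upstream
pipeline has already produced, for each recording and each of two systems
(a wearable *device* and a *reference*): detected stride events (start and
end in seconds from recording start, with foot laterality), per-second
cadence and stride-length traces, and turn intervals. These live in a
`stride_stream`; a `gait_session` pairs the two systems' streams and
carries the sample rate (default 100 Hz) used for sample-wise detection
metrics. Raw IMU parsing, gait-sequence detection, initial-contact
detection, per-second DMO estimation, turn detection and laterality
classification are out of scope by design — they are consumed as inputs.

Two conventions matter throughout:

* **Time** is floating-point seconds from recording start. Per-second
  samples are indexed by their integer start second: sample `i` covers
  `[i, i+1)`.
* **Missingness** is explicit. A per-second row with `NA` values means
  "walking detected but measurement missing"; an absent row means "no
  walking". Interpolation must distinguish the two, so silent gaps are
  never used to encode missing measurements.

Strides of opposite feet may overlap in time — that is double support, not
an error — while same-foot overlaps are invariant violations. Validators
return all violations as data rather than failing on the first.

## The bout pipeline

**Stride speed.** `speed = (cadence / 120) · stride_length`: cadence in
steps/min divided by two steps per stride and 60 s/min gives strides per
second; one stride advances one stride length.

**Interpolation.** Each stride receives the time-weighted mean of the
per-second values over its span, each second weighted by its overlap with
the stride; `NA` seconds are dropped from the weights. A stride covered
only by missing seconds is flagged unvalued and removed at selection. With
traces that are constant within a bout the interpolation is exact, which
is what makes the end-to-end identity tests exact.

**Selection.** A stride is kept iff its duration lies in [0.2, 3.0] s
*inclusive* and its length is *strictly* greater than 0.15 m. The duration
bounds are read as inclusive ("between"), the length bound as strict
(">"); the boundary cases are pinned in tests.

**Assembly.** Strides are grouped over the time-sorted, interleaved
both-feet sequence. The break between consecutive strides is
`next start − previous end`, with negative values (double support) treated
as zero; a break greater than 3.0 s starts a new run. Runs are also split
wherever two consecutive strides share a foot, so every run alternates
L/R throughout; this is the conservative reading of the alternating-feet
definition when a laterality label is wrong. Because the interleaved
stride of one run can reach past the start of the next run after such a
split, trailing strides that cross the split point are dropped — bout
spans must never overlap, and the matcher enforces that as a contract. A
run qualifies as a walking bout iff it has at least two strides of each
foot.

**Aggregation.** Bout DMOs are unweighted arithmetic means over strides
("average value over all strides", no duration weighting). Whether the
bout speed should be the mean of per-stride speeds or the speed formula
applied to the bout's mean cadence and mean stride length is genuinely
ambiguous; both are implemented
(`pipeline_config(bout_speed_method = )`), the default is the mean of
per-stride speeds, and the two agree exactly only when cadence and length
are constant within the bout (asserted in tests).

**Complexity.** The turn fraction is the length of the intersection of the
(merged) turn intervals with the bout span divided by the bout duration:
`simple` below 0.20, `complex` at or above 0.60, `intermediate` between.
Turns outside bouts are ignored.

## Matching and detection metrics

**True-positive matching.** The published criterion — overlap "of more
than 80%" — names neither the denominator nor whether the comparison is
strict. Decisions here: the default denominator rule `both` requires the
intersection to exceed the threshold fraction of *both* bouts' durations
(the strictest symmetric reading); `reference` and `union` (Jaccard) are
selectable and every report records the rule used. The comparison is
strict (`>`), with one carve-out: a perfect overlap (fraction exactly 1)
matches at any admissible threshold, so an error-free device is never
penalized at threshold 1.0. Assignment is one-to-one greedy by descending
overlap seconds, ties broken by earlier reference start — chosen over
optimal assignment for transparency. Under the default rule with
threshold ≥ 0.5 a bout can be a candidate of at most one partner, so
greedy and exhaustive assignment coincide; the test suite checks greedy
against a brute-force exhaustive oracle on hundreds of random instances,
including low-threshold configurations where conflicts exist.

**Sample-wise detection.** Bout lists are rasterized to the recording's
sample grid: sample `k` is walking iff its midpoint `(k + 0.5)/rate` lies
inside a bout (closed span, so abutting fragments cover exactly the same
samples as their union — an invariance the tests assert). Accuracy,
sensitivity, specificity and PPV are computed per participant;
zero-denominator metrics are `NA` ("undefined"), never silently zero.
Cohort aggregation is the unweighted mean over participants with seeded
percentile-bootstrap intervals (the interval method for the published
cohort tables is unstated; percentile bootstrap, B = 1000, is this
package's documented choice).

## Agreement statistics

Errors are device − reference; relative errors are percentages of the
reference value (pairs with a zero reference value are excluded from
relative metrics and counted). Summary quantiles use R's default type-7
linear interpolation. Limits of agreement are mean ± 1.96 SD (sample SD;
the multiplier is configurable since 2·SD variants exist), with
percentile-bootstrap CIs per bound.

ICC(2,1) — two-way random effects, absolute agreement, single measure —
is computed from the two-way ANOVA mean squares of the n×2 table, with
the F-distribution confidence interval using Satterthwaite degrees of
freedom. The implementation is closed-form; the test oracle derives the
mean squares independently through `aov()`, and the two agree to 1e-10
across hundreds of random tables. Interpretation bands: < 0.5 poor,
0.5–0.75 moderate, 0.75–0.9 good, > 0.9 excellent; both band edges (0.75,
0.90) fall into the lower band's better-known label, i.e. `good` requires
≥ 0.75 and `excellent` a strict > 0.90. A table with zero variance in
both systems is defined as ICC 1 with a warning. Note the
absolute-agreement coefficient is not bounded below by −1: strongly
anticorrelated tables can push it below, and the package reports the true
value (any negative value is `poor`).

The **combined evaluation** reduces each system's *own* bouts — not only
true positives — to one median per unit (a laboratory task, or the whole
recording per participant in the real world) and compares unit medians
between systems. Units missing either system are excluded and counted.
For laboratory data, participant×task rows are the ICC subjects.

## Stratified reporting

Duration bins reproduce the published layout: the partition
[0,10), [10,30), [30,60), [60,120), [120,∞) s plus two deliberately
overlapping catch-alls (<10 s, >10 s), reported side by side with a
`partition_bin` flag; only the partition participates in the
count-conservation invariant. Binning uses the *reference* bout duration,
left-closed/right-open. Strata with fewer than 101 bouts are flagged
underpowered (the sample-size the study's power analysis required). The
speed-error relationship is an OLS fit of signed error on reference speed
with a seeded bootstrap CI on the slope; a zero-variance regressor is an
error, not a silent zero.

## The synthetic generator

The generator defines the study conditions; it is not a tuning dial.

*Reference streams.* Bout counts are Poisson at 20 bouts/h; durations are
log-normal with median 20 s and log-SD 1.0, chosen so roughly two thirds
of bouts are shorter than 30 s, matching the reported duration
distribution shape; durations are clamped to [4, 600] s and bouts are
placed uniformly with ≥ 5 s separation so they remain distinct under the
3 s break rule. Per-bout speeds are normal with the six cohorts'
real-world reference means (HA 0.72, CHF 0.95, COPD 0.65, MS 0.67,
PD 0.76, PFF 0.66 m/s), SD 0.25 m/s, truncated above 0.1 m/s. Within a
bout, cadence is drawn near 105 steps/min and clamped so that stride
duration stays within the selection bounds and stride length exceeds the
0.15 m cut — generated bouts are definition-compliant by construction,
which the end-to-end identity test verifies. Cadence, length and speed
are kept mutually consistent through the speed formula, and the
per-second traces are constant within bouts so interpolation is exact.
Turns arrive at 2/min of walking with 1–3 s durations.

*Device degradation.* Per reference bout: missed entirely with
probability 0.35 (bout-level sensitivity 0.65, the calibration anchor
from the reported aggregate detection performance), with an optional
extra miss probability below a speed cut for preferential-slow-miss
experiments (0 by default); fragmented with probability 0.15 by a silent
gap of 4 s (> 3 s, so fragments stay separate bouts downstream);
per-stride timing jitter (SD 0.02 s); laterality flips at 0.005 per
stride (same-foot overlaps created by a flip are resolved by truncating
the earlier stride); and a per-bout speed error `e = a + b·v + N(0, σ)`
with a = 0.25 m/s, b = −0.25 and σ = 0.15 m/s — overestimation below
1 m/s, underestimation above, with limits of agreement comparable to the
real-world report — applied through the per-second *stride length*
(spatial estimation carries most of the error) plus 0.02 m per-second
noise. Spurious walking appears at 4 false bouts/h of 5–10 s in
non-walking time, which leaves specificity near 0.99. Default study
scale: one 2.5 h recording per participant, 17/9/17/13/15/11 participants
for HA/CHF/COPD/MS/PD/PFF.

Every injected truth (per-bout speed, miss/fragment flags, injected speed
error) is recorded in a manifest so the downstream analysis can be tested
as a parameter-recovery problem: the recovery suite checks an injected
additive bias of 0.06 m/s to ±0.01 over ≥ 500 true-positive bouts, slope
−0.25 via bootstrap-CI coverage over 200 replicates, error SD 0.10
through the LoA width at n = 1000, and a 0.35 miss rate as aggregated
sample-wise sensitivity 0.65 ± 0.05 over 50 participants.

*What the generator does not emulate.* Strictly stationary gait within
bouts (no within-bout speed drift), no missing per-second values inside
detected gait (real pipelines have them; the data model and interpolation
support them, the generator does not produce them), no walking-aid
effects, no cohort-specific detection performance, no laboratory task
structure, and no correlation between bout duration and speed. Passing
tests therefore demonstrate the correctness and calibration of the
*analysis machinery*, not the field performance of any device.

## Determinism and problem sizes

All randomness flows from explicit integer seeds; bootstraps are locally
seeded (the caller's RNG state is saved and restored), and identical
configuration plus seed yields byte-identical study files and report
files — asserted at file level in the tests. The test suite exercises the
generator at recording lengths of a few hundred to a few thousand
seconds with small cohorts, and the acceptance script runs the full
default study (82 participants × 2.5 h) in about a minute; these sizes
are the package's chosen trade-off between Monte-Carlo resolution and
quick iteration.

## Known limitations

* Greedy matching is not globally optimal for low thresholds or
  non-symmetric denominator rules; the tests quantify (and bound) the
  gap, and the default configuration provably coincides with optimal.
* Fragment matches are not merged before matching: a device that splits
  one reference bout into two fragments usually loses the true-positive
  match entirely, which is faithful to the two-tier design but means
  fragmentation depresses the true-positive count, not the error
  statistics.
* Regression-adjusted (proportional-bias) limits of agreement are not
  offered; the Bland–Altman interval assumes an additive error scale.
* The ICC confidence interval relies on the F approximation, which
  degrades for extreme negative coefficients; the point estimate is
  always reported.
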