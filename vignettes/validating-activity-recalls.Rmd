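---
title: "Validating 24-hour activity recalls against accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating 24-hour activity recalls against accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(par24)
library(dplyr)
```

## The measurement problem

A 24-hour physical activity recall asks a respondent to reconstruct the
previous midnight-to-midnight day as a sequence of timed activities. Each
reported activity is assigned a MET value (metabolic equivalent of task:
the energy cost of the activity as a multiple of resting metabolic rate),
and the day is summarised as minutes spent sedentary, in light activity,
and in moderate-to-vigorous activity (MVPA). An accelerometer worn over
the same day provides an objective criterion: activity counts per minute
(cpm), classified with conventional cut-points. Concurrent validity is the
agreement between the two methods over the same day; test-retest
reliability is the agreement between two administrations of the recall for
the same day.

`par24` implements the diary data model and scoring, the accelerometer
reduction, and the full nonparametric concordance analysis, plus a
synthetic cohort generator that makes the whole pipeline testable against
known ground truth.

## The diary model and its conventions

A diary day lives on a 5-minute grid: entries are half-open intervals
`[start_min, end_min)` in 0-based minutes since midnight, each at least
5 minutes long, together covering all 1440 minutes with at most two
concurrent activities. Half-open intervals make adjacent bouts
non-overlapping and coverage arithmetic exact. Days that fail validation
are never silently scored; `validate_diary()` returns each violation as a
data row (gap, overlap, granularity fault, unknown code) and the pipelines
log and drop the day.

MET assignment distinguishes three activity kinds in the catalog:

* simple activities carry one MET value;
* effort-ranked activities (e.g. cycling) carry light/medium/hard values,
  required to be monotone nondecreasing — three catalog columns rather
  than effort multipliers, since energy-cost compendia list distinct
  entries per intensity;
* posture-adjustable activities (e.g. desk work) carry sitting and
  standing values, combined as
  `f * met_standing + (1 - f) * met_sitting` for reported standing
  fraction `f`. The linear rule is the time-weighted average of the two
  postural states.

When two activities are reported concurrently, the per-minute MET is the
maximum of the two by default: the dominant activity determines the
minute's intensity. The alternative (`overlap_rule = "mean"`) averages
them. How a live instrument should arbitrate concurrent entries is a
genuinely open design point; the maximum is the conservative choice for
intensity classification and is exposed as an option rather than baked in.

Minutes are classified as sedentary when MET ≤ 1.5, light when
1.5 < MET < 3.0, and MVPA when MET ≥ 3.0. The sedentary boundary is
*inclusive* of 1.5: published boundary statements vary between "< 1.5" and
"≤ 1.5", and the inclusive form is the one that governs tabulated results
in the validation literature this package mirrors, so it is applied
consistently here and asserted in the tests. The 24-h average MET is the
arithmetic mean over all 1440 minutes (not waking minutes only — a
convention choice, stated here because published reports are often
ambiguous about it).

The shipped `demo_catalog()` is fixture data: 34 activities across the 13
standard broad categories, with MET values from the public Ainsworth
compendium. Any catalog in the documented CSV dialect can be supplied.

## The accelerometer criterion

Counts are ingested at a constant epoch length (1–60 s), summed to counts
per minute over an explicitly specified recall date (never inferred from
the data — criterion windowing must be exact), and classified with the
Freedson/Matthews cut-points: sedentary < 100 cpm, light 100–1951 cpm,
MVPA ≥ 1952 cpm. Those cut-points are vertical-axis conventions, so the
single counts column is interpreted as vertical-axis counts. A minute
containing any non-wear epoch is wholly non-wear, which avoids inflating a
minute's count from a partial wear window. Days with fewer than 720 wear
minutes (half the day) are excluded; intensity totals are computed over
wear minutes only, and `included_min` records how many there were.
Reported wear flags are an input column because the target study design
collects wear interruptions from participants; a conventional detector
(≥ 60 consecutive zero minutes) is available but off by default. Counts
are never converted to MET: no count-to-MET conversion rule is reliable
across activity types, so the accelerometer summary's `avg_met` is `NA`
and validity is assessed on class minutes only.

## The concordance statistics

All comparisons are nonparametric and two-sided, evaluated at the 5%
level, on per-participant paired totals (`value_a` the instrument,
`value_b` the criterion; differences are always `value_a - value_b`):

* **Spearman correlation** — the Pearson correlation of midranks — is the
  primary agreement measure.
* **Wilcoxon signed-rank** tests a systematic shift between methods. Zero
  differences are dropped before ranking (the classic convention;
  `zeros = "pratt"` is available). The exact distribution is used when,
  after zero handling, there are no ties and n ≤ 25; beyond that the
  normal approximation with continuity and tie correction. The all-zero
  case returns p = 1 with a degenerate flag rather than an error.
* **Wilcoxon rank-sum** compares the per-participant differences between
  two strata; exact for tie-free combined samples of at most 12.
  The exact/approximate thresholds (25 and 12) are implementation
  constants balancing fidelity and runtime; both regimes are verified in
  the tests against full-enumeration oracles (all 2^n sign assignments,
  all C(n, k) rank splits).
* **Median of differences** with a median percent difference. The median
  of per-participant differences is deliberately *not* the difference of
  medians, and the two can disagree in sign; the report carries the
  former. Percent differences use each pair's own criterion value as the
  denominator (pairs with a zero criterion are excluded from the percent
  median); printed percentages in the literature cannot always be
  reconciled with a single denominator convention, so the pooled
  alternative (`denominator = "pooled_median"`) is provided as a switch.
* **Bland–Altman** bias and 95% limits of agreement,
  `bias ± 1.96 × SD` of the differences with the sample (n − 1) SD; the
  per-pair (mean, difference) points are kept for plotting.

Stratified comparisons cut age at 60 years and BMI at 25 kg/m², with the
upper stratum inclusive (≥). Spearman is also the reliability statistic
(it is what validation tables in this literature report, despite
occasional "intraclass correlation" wording); a two-way random
single-measure ICC, `icc_two_way()`, is provided for comparison but is not
used by the pipelines.

A stratum with fewer than three participants, or one in which a method is
constant, has no defined Spearman correlation; `method_agreement()` raises
that as an error, and the study pipelines degrade gracefully by dropping
the affected stratified block and recording the reason in the report's
`notes` table. The overall block always runs.

## The synthetic cohort generator

No participant-level data accompany the validation studies this package
mirrors, so testing rests on a generator with known ground truth
(`sim_config()` / `simulate_cohort()`). Per participant:

1. **True schedule.** Class minute totals are drawn Dirichlet-style around
   means of 1000 sedentary / 400 light / 40 MVPA minutes (near the
   accelerometer medians reported for adult validation cohorts), with
   concentration 40, then laid out as alternating bouts with geometric
   lengths (mean bouts 60/30/20 min) on the 5-minute grid.
2. **Counts.** Each minute's cpm is drawn from a truncated normal
   conditioned on the true class, with support truncated to the class's
   cpm interval. Truncation makes the truth identifiable by construction:
   the accelerometer summary recovers the true schedule exactly, which
   separates testing of the statistical machinery from cut-point
   estimation (not this package's concern). `sd = 0` gives degenerate
   class-typical emission. Counts default to 60-s epochs; sub-minute
   emission splits each minute's count conservatively and exists to
   exercise the epoch reduction.
3. **Misreporting.** Each true-light 5-minute block is independently
   re-reported as MVPA with probability 0.225 (over-reporting) or as
   sedentary with probability 0.075 (under-reporting). At 400 expected
   true light minutes those defaults transfer about +90 min into reported
   MVPA and −120 min out of light time — the magnitudes around which the
   parameter-recovery tests are built — while sedentary time gains only
   the small under-reported remainder.
4. **Replicates.** Both recalls share the one misreported schedule (the
   participant's stable perception of the day) and then each flips block
   classes to an adjacent class independently with
   `boundary_confusion_prob` (default 0.02). Reliability correlations
   therefore rise toward 1 as the confusion probability falls to 0, which
   the tests assert in expectation over seeds.
5. **Covariates and wear.** Age is normal (mean 52, SD 13) clamped to
   22–70 years, gender balanced, BMI normal (26.1, SD 4.4) clamped to
   18.1–41.2 kg/m² — the covariate structure of a general-population adult
   sample. A day contains one non-wear bout of 30–120 min with
   probability 0.1, well short of the 12-h exclusion threshold.

Reproducibility: one master seed; participant `i` uses substream seed
`(seed + 1000003 * i) mod (2^31 - 1)`, so enlarging a cohort never changes
existing participants, and identical configurations are byte-identical.

What the generator does **not** emulate: correlation between covariates
and activity (strata differ only by sampling noise, so between-strata
tests are null by construction); magnitude-dependent sedentary bias;
activity-specific count signatures or raw-acceleration artifacts;
misreporting of bout timing (only class identity is distorted). Passing
tests therefore demonstrate that the machinery is correct and that
injected biases are recovered — not that any particular real instrument
is valid.

## Problem sizes and numerical choices in the test suite

The conservation property is checked on 1000 simulated participant-days;
oracle equivalence on 500 random Spearman instances (n ≤ 30, ties
allowed, tolerance 1e-12) and 200 instances each for the exact signed-rank
(n ≤ 12) and rank-sum (combined n ≤ 10) tests; parameter recovery on 20
seeds of 50-participant cohorts with boundary confusion disabled so the
misreport channel is isolated, requiring each seed's median differences to
match the injected expectations within 25 min. The no-distortion
configuration (zero misreport factors, degenerate count emission, full
wear) is the identity case: diary, accelerometer, and truth agree exactly,
so the validity pipeline must report zero median differences and unit
correlations.

`scripts/acceptance.R` re-runs both studies at the scale of the motivating
design — 49 participants for validity, 67 for reliability — from a single
command-line seed.

## Known limitations

* Exact replication of any published cohort's p-values is out of scope:
  the software and tie conventions behind published tables are generally
  unknown, and the underlying data are not deposited.
* The signed-rank exact path requires tie-free differences; minute totals
  on a 5-minute grid tie often, so real-scale analyses will usually take
  the approximate path.
* Device binary formats (AGD/GT3X) are not parsed; counts arrive as CSV.
* The generator's count emission is class-faithful by design, so
  simulated method correlations are higher than those observed with real
  accelerometry; treat simulated Spearman magnitudes as upper bounds, not
  calibrated predictions.
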