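---
title: "Trial-aligned working-memory analysis: models, parameters and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-aligned working-memory analysis: models, parameters and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the trial-alignment model, each analysis and its
assumptions, what the synthetic-session generator does and does not
emulate, and the numerical and design choices that were genuinely open.

## The trial model

A trial of the delayed non-match-to-place task is anchored at 11
behavioral events (start of sample run, T-junction turn, first reward,
end of licking, turn towards the start box, arrival at the start box,
start of the choice run, T-junction turn, second reward, end of licking,
end of choice run). Consecutive events bound 10 phases; phases 1–4 form
the encoding period, 5–6 the maintenance (delay) period, 7–10 the
retrieval period. Mistake trials earn no second reward, so events 9 and
10 do not exist for them and only 9 events remain.

Freely moving animals take variable time through each phase, so signals
from different trials are not comparable bin-by-bin. The package
registers them by *segment-wise temporal resampling*: every phase of
every trial is linearly interpolated onto `round(median duration ×
rate)` bins (minimum 2), where the median is taken across all trials
possessing the phase. After resampling, phase boundaries fall on the
same bin index in every trial and trial averaging is meaningful.

Numerical choices here:

* Interpolation is piecewise-linear on an endpoints-inclusive grid. This
  is the minimal assumption consistent with "resampling": it preserves
  constants exactly, keeps the warp monotone, and makes the identity
  warp exact when a trial already has the target duration. Nonlinear
  warps (e.g. dynamic time warping) are deliberately out of scope: the
  events are the alignment anchors.
* Phase durations pool *all trials of the session* when computing
  medians; per-group pooling is available by passing explicit `targets`.
  Both readings of "median across all trials" are defensible; pooled is
  the default because the common timebase should not depend on a
  grouping chosen later.
* Mistake trials lack events 9 and 10, so the retrieval tail from event
  8 to event 11 is resampled as one merged segment onto the combined bin
  count of phases 8–10. Analyses that need those sub-phases use correct
  trials only; maintenance-period analyses keep mistake trials, which is
  where they are scientifically needed.
* Time bins are half-open `[t, t + 1/rate)`; a phase shorter than two
  samples is an error rather than a silent degenerate warp.

ΔF/F is `(F − F0)/F0 × 100%` and the per-trial z-score is
`(F − F0)/σ`, with `F0` the mean and `σ` the *sample* standard
deviation (n − 1 denominator; the convention had to be fixed and is
configurable in code) of the fluorescence in the 1-s window before event
5 — i.e. immediately before the maintenance period, so delay activity is
measured against the pre-delay baseline. A zero `σ` or `F0` raises an
error instead of emitting infinities.

## Synthetic sessions

The generator exists so that every downstream stage can be tested
end-to-end with known ground truth. It emulates, per session:

* the trial grammar above, with per-phase durations drawn as
  `median × lognormal(cv)` — multiplicative jitter keeps durations
  positive and leaves the configured medians invariant;
* pseudo-randomized sample sides with at most three consecutive runs to
  the same arm, and mistake trials at probability `p_mistake`;
* unit classes: fractions of encoding-, maintenance- and
  retrieval-preferring units (defaults 0.22/0.56/0.22) plus an untuned
  remainder. Encoding/retrieval units fire extra spikes uniformly within
  one planted phase, with gain `1 ± side_modulation` by sample side;
  maintenance units form a sequence whose per-trial Gaussian fields
  (s.d. `field_sd` = 0.4 s) tile the first `sequence_span` seconds of
  the delay in planted rank order;
* mistake-trial degradation: maintenance spikes receive timing jitter
  with s.d. `mistake_jitter × sequence_span` and reduced amplitude
  (`mistake_gain`), emulating a sequence that falls apart without a
  generative model of *why* it does;
* fluorescence: spikes carry gamma-distributed amplitudes (inferred
  spike events are continuous-valued, not unit counts), are convolved
  with an exponential kernel (`kinetics_tau` = 0.6 s, GCaMP6-like) on a
  resting baseline of 1, plus Gaussian noise of s.d. `1/snr`. The
  noiseless binned spike-amplitude train is returned as the
  "deconvolved" channel — a ground-truth stand-in for spike inference,
  which is itself out of scope.

Defaults describe an expert miniscope session: 150 trials × 60 units at
20 Hz, median phase durations (2, 1.5, 2, 1, 2, 5, 2, 1.5, 2, 1) s — a
5-s enforced delay inside a ~20-s trial — duration CV 0.3, 10-s
inter-trial interval, background rate 1 Hz, active rate 2 Hz,
`p_mistake` 0.25 (a 70–80% correct rate).

What the generator does **not** emulate, and what passing tests
therefore cannot show about real data: correlated noise across units
(motion, neuropil), spike-inference errors and their temporal bias,
slow drift and bleaching, behavioral covariates of phase durations
(running speed), non-Poisson firing statistics, and session-to-session
unit identity. Recovery results on synthetic sessions demonstrate that
the *statistics* behave as intended, not that any particular biological
claim holds.

A note on the generator's one deliberate failure mode: with the default
1-s window the baseline falls at the end of the encoding period, so
bulk z-scored profiles are negative during early encoding. That is a
property of baseline placement, not a bug; the same happens with real
recordings z-scored against a pre-delay window.

## Phase preference

Per unit and window (10 phases or 3 periods), the per-trial mean of the
deconvolved signal over the window's *original* (non-resampled) time
span is compared against the pooled per-trial means of all other windows
with a one-sided Wilcoxon rank-sum test (alternative "greater":
"preferentially active" is directional). Significance is −log10(p),
binarized inclusively at p ≤ 0.01. The preferred window is the argmax of
−log10(p), ties to the earlier window. Co-activity matrices count the
fraction of units significant in both windows of a pair; the diagonal is
the single-window fraction, so the matrix is symmetric and
diagonal-dominant by construction.

Enrichment between periods uses an exact binomial test. Under the null
that each unit is equally likely (1/3) to prefer any period, a unit
preferring one of a given pair is equally likely to prefer either, so
the pairwise test is binomial with p = 1/2 on the counts restricted to
the pair — this is the per-pair formulation of the 1/3-uniform null.
Per-session p-values combine across sessions with Fisher's method
(−2Σln p against χ² with 2k d.f.).

A calibration caveat the test suite quantifies for periods and
documents here for phases: pooling "all other windows" mixes windows of
unequal duration. Shorter windows yield higher-variance, right-skewed
per-trial means, which makes the one-sided rank-sum slightly
anticonservative at the phase level (a measured excess of roughly a
quarter of the nominal 1% rate on untuned sessions). The three periods
have near-equal spans (~6.5–7 s), satisfy exchangeability under the
null, and calibrate within the binomial band; the suite's calibration
run therefore asserts the band on period windows.

## Time-resolved ROC

For a two-class trial contrast, each of 20 repetitions draws 100 trials
per class (with replacement when a class is scarcer than that, as
mistake trials are), smooths each trial's bulk signal with a centered
3-bin boxcar (truncated at the edges), and computes the per-bin AUC
(Mann–Whitney identity, ties counted 1/2). The same procedure on
label-shuffled trials — a fresh permutation per repetition, class sizes
preserved — yields the null draws. Per bin, a two-sided rank-sum test
compares the 20 real against the 20 shuffled AUC values; p-values are
Benjamini–Yekutieli-adjusted across the analyzed span (BY is valid under
the arbitrary dependence smoothing induces) and masked at adjusted
p ≤ 0.01.

**Known limitation.** This draw-based comparison is intrinsically
anticonservative under the global null. All real repetitions share the
one observed label partition, whose per-bin AUC deviates from 0.5 by
sampling noise of order `sqrt((Na+Nb+1)/(12·Na·Nb))`; the shuffle
repetitions each carry a fresh partition. The rank-sum then detects the
shared partition offset rather than a class effect, and because that
offset is common to all bins, the BY step cannot repair it. The
calibration run in the acceptance suite measures the session-level
consequence (a majority of null sessions show at least one
BY-significant bin, far above the nominal 1%) and is left failing by
design: the procedure is implemented as defined, and this vignette is
where its calibration property is recorded. Interpret the significance
masks as descriptive highlighting of large AUC excursions, not as
calibrated tests; the permutation-based L2 decoding below is the
calibrated alternative for population contrasts.

## Binary Directed Orderability

For each unit and trial over an analysis span (default: the maintenance
period), the nonnegative baseline-subtracted deconvolved signal is
normalized to an activity probability `p(t) = x(t)/Σx(t)` and summarized
by its center of mass `μ = Σ t·p(t)` (1-based bin units) — more robust
per noisy trial than the peak bin. For a unit pair (i, j), `f_ij` is the
fraction of trials with `μ_j > μ_i`, counted over trials where both
units are valid; `BDO_ij = 2 f_ij − 1` is antisymmetric in [−1, 1], and
ABDO is the mean |BDO| over off-diagonal pairs. The population-level
null shuffles unit labels independently within every trial and
recomputes ABDO; the p-value uses the add-one estimator
`(1 + #{null ≥ obs})/(1 + n_perm)` so it is never zero. Defaults:
1000 permutations.

Choices that had to be made:

* Exact ties `μ_i = μ_j` (possible on discrete toy inputs, negligible
  for floating-point data) are excluded from the pair's trial count,
  preserving `f_ij + f_ji = 1`; counting them as "not later" on both
  sides would break that identity.
* Baseline subtraction before normalization is the per-unit per-trial
  minimum (guaranteeing nonnegativity; a percentile baseline is
  available). For nonnegative deconvolved signals the minimum is
  typically zero, so this is the gentlest choice.
* A unit silent in a trial is invalid for that trial only; pairs with no
  untied co-valid trial are unorderable (`NA`) and excluded from ABDO.
  No NaN ever propagates.
* BDO depends only on the within-trial *order* of centers, so it is
  invariant to any monotone per-trial rescaling of time — the property
  that makes it robust to the duration variability the task creates.

## Sequence train/test validation

Correct trials split into random disjoint halves (training takes the
extra trial on odd counts). Per unit, the trial-averaged
maintenance-span signal of each half is max-normalized and its argmax
(earliest bin on ties) is the peak time; units whose mean signal is
identically zero are excluded. Units are ordered by training peaks;
held-out correct trials and mistake trials are evaluated by the per-unit
absolute peak shift in seconds. Medians and 75th percentiles use linear
interpolation between order statistics (the quantile rule had to be
fixed); the test-vs-mistake comparison is a paired two-sided Wilcoxon
signed-rank test with zero differences dropped (the standard
convention), returning p = 1 when all differences are zero.

## Transient population decoding

Per bin, the L2 norm over units of the difference between the two
conditions' mean population vectors, against a null of `n_perm` label
permutations preserving class sizes, with the add-one p estimator. No
multiple-testing correction is applied: the −log10(p) trace is itself
the reported object, and the per-bin test is exactly calibrated by
construction (verified in the suite at the 5% level). Per-unit
predictive fractions use a two-sided rank-sum per unit and window at
α = 0.01, and the window-level count is referred to an exact binomial
tail `P(X ≥ count | n_units, 0.01)` under independent-unit nulls.

## Orchestration and reproducibility

`run_pipeline()` executes simulate → align → phase preference → ROC →
orderability → sequence → decoding from one strict-schema configuration
(YAML-able; unknown keys rejected), writes per-stage CSVs plus a
`summary.json` carrying a provenance block (package version, seed,
config hash), and logs per-stage wall-clock to stderr. Every stochastic
stage takes an explicit seed derived from the master seed, so a given
configuration byte-reproduces all CSV outputs; only the provenance
timestamp differs between runs.

Problem sizes used by the test suite, chosen to exercise the statistics
at meaningful power: calibration runs use 200 untuned sessions of 40
trials × 8 units (ROC null draws 50 × 10; ABDO nulls with 199
permutations); recovery runs use the study-scale 150 trials × 60 units
with planted fractions 0.2/0.6/0.2, and the mistake-degradation
replication uses 100 such seeds. The acceptance script itself is
analytic and runs in well under a second.

## Known limitations

* The ROC shuffle comparison's anticonservativity, described above.
* Phase-level (not period-level) preference tests are slightly liberal
  under heteroscedastic window durations.
* The generator's Poisson/Gamma activity model has no correlated noise
  across units, so population analyses see a friendlier world than real
  recordings; recovery thresholds in the suite should be read
  accordingly.
* Orderability assumes the deconvolved signal is nonnegative after
  baseline subtraction; fluorescence (not deconvolved) input should use
  the percentile baseline option with care.
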