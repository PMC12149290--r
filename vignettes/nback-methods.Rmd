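---
title: "Models and methods behind nbackPFC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nbackPFC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbackPFC)
```

This vignette documents the scientific model the package implements, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical and design decisions taken where more than one
reasonable choice existed.

## Task model

The oculomotor n-back task presents 2–4 brief cues (150 ms) at one of four
locations (12° eccentric), separated by 800-ms delays, while the subject
fixates. FP offset is the go cue; the goal is the most recent cue location
under the 1-back rule and the one-previous location under the 2-back rule.
Three derived quantities drive everything downstream:

* the **required memory set** after cue *k*: the last cue location
  (1-back), or the last two (2-back; duplicates collapse);
* the **extinction location** at cue *k*: the location present in the
  memory set after cue *k−1* but absent after cue *k*. A same-location
  repeat produces no extinction event — extinction is defined on memory
  content, not on cue identity;
* the **choice taxonomy**: a completed saccade is `correct`, a
  `rule_error` (the other of the last two cue locations), a
  `mem_error_23back` (an earlier cue location of the trial) or a
  `mem_error_random` (a never-cued location). When the last two cues
  coincide no distinct rule-error location exists; such trials simply
  cannot produce a rule error and are excluded from rule-error accounting.

Location indices are 0-based; angles are degrees counterclockwise from the
rightward horizontal; the default angle set is oblique (45/135/225/315), so
index 0 is upper-right and index 2 lower-left. Hemifield labels
(ipsi/contra) derive from the session's recorded hemisphere.

## The encoding model

Spike counts in the early and late 400-ms epochs of every delay period are
modeled with a log-link Poisson regression. The early model carries
per-location Visual and Extinction indicator blocks plus Order, Rule and a
bias; the late model carries the per-location Memory block (both remembered
locations set in 2-back) plus Order, Rule and a bias. Order is `(k-1)/3`
for cue position *k*, spanning 0–1 over positions 1–4; Rule is `1` for
2-back. Estimating Order, Rule and the bias separately per epoch model
gives 12 location betas + 2×3 scalars = 18 coefficients.

Two numerical points deserve emphasis:

* **Rank deficiency is structural.** Every early row has exactly one
  visual indicator set (each delay follows a cue), so the visual block sums
  to the early bias. The fit resolves this deterministically: biases and
  scalar covariates are protected and the last aliased indicator
  (`visual_3`) is dropped and reported as *absent* (NA), never as zero.
  Because the four location unit vectors of a symmetric angle set sum to
  zero, this reference coding leaves each component's direction vector sum
  — and hence the preferred angle and the DI numerator — unchanged.
* **Response scaling vs. test calibration.** By default the response is
  each neuron's epoch count scaled to 0–100% of its maximum, which makes
  coefficient magnitudes comparable across neurons but inflates the nominal
  Poisson information: Wald tests at unit dispersion are then
  anticonservative, and component-significance flags should be read as
  liberal. Two remedies are built in: `responseScale = "raw"` fits the
  integer counts (calibrated tests; used wherever the package itself needs
  accurate type-I control), and `dispersion = "pearson"` rescales the
  standard errors by the quasi-Poisson dispersion estimate.

The IRLS solver uses step halving, which makes the deviance non-increasing
across iterations; fits that fail to converge in 100 iterations or drift to
|β| > 30 (quasi-separation) are flagged and the neuron is left
unclassified.

A neuron *carries* a component when any of its betas has p < 0.05; it is
*directional* when additionally DI > 0.1, with DI = ‖Σβᵢuᵢ‖/Σ|βᵢ| over all
four betas (significant or not). The Σ|β| denominator and the use of all
four betas are package choices where alternatives exist; the max-norm
denominator could be substituted in `directionalIndex()` without touching
the rest of the pipeline.

## Behavioral analysis

Saccades are detected when the smoothed angular eye velocity exceeds 70°/s
and the excursion displacement exceeds 6°. Velocity is computed by central
differences of the 1-kHz trace, smoothed with a 5-ms boxcar *per
component* (the magnitude of unsmoothed jitter noise does not average to
zero); onset/offset are then refined outward to a secondary threshold of
40% of the main one so the slow initial ramp and landing phase are
captured. With these constants the round trip through the synthetic eye
generator recovers reaction times within ±5 ms and endpoints within ±0.2°.

The chosen location is the task location *nearest* the saccade endpoint
even outside the 4° reward window — the window governs reward only, while
the error taxonomy needs a chosen location for every completed saccade.
Fixation breaks are excluded (and their proportion reported) before all
other statistics.

The trajectory angle θ is the signed angle between the fixation→endpoint
and fixation→goal vectors, positive toward the non-target cue; it is
radially invariant by construction. Sessions statistics use only correct
trials whose last two cue directions are 90° apart. Stimulation-effect
screening uses Fisher's exact test per session (the per-session test family
is configurable to χ²; the choice is deliberately explicit because either
is defensible), followed by paired t tests across sessions on error
proportions, reaction times and endpoint accuracy.

## The synthetic session generator

The generator is first-class, tested code: it defines the conditions under
which every recovery claim in the test suite holds.

**Behavior.** Per-rule category probabilities default to session-level
values typical of well-trained subjects: rule errors 1.7%/3.3%, 2/3-back
memory errors 2.8%/4.1%, random errors 0.2%/0.4%, fixation breaks
5.6%/7.5%, reaction times 208 ± 51 / 194 ± 29 ms (1-back/2-back), and a
trajectory-angle bias of +1° (1-back) vs −2° (2-back) with 6° per-trial
spread, i.e. a −3° 2-back-minus-1-back difference. Some categories are
unachievable on some trials (no 2/3-back location exists on a 2-cue trial;
no never-cued location when all four were cued), so the sampler
renormalizes each category's probability by the fraction of trials on
which it is achievable and always re-derives the recorded category from
the chosen location via `classifyChoice()`. Marginal category frequencies
therefore converge to the specified probabilities (verified by a χ²
goodness-of-fit test at n = 5000) while every record stays internally
consistent.

**Spikes.** Each neuron archetype is a piecewise-constant rate: memory
(baseline + gain while the preferred location is required), extinction and
visual (400-ms transients aligned to cue onset, so they dominate the early
epoch), order (gain scaled by `(k-1)/3`), rule (tonic in 2-back), mixtures,
and null. Spike trains are drawn by thinning against the profile maximum,
so window counts are exactly Poisson with the integrated rate;
`simulateEpochCounts()` is a distribution-identical fast path that draws
the epoch counts directly from the integrated means.

**Stimulation.** The erasure manipulation is modeled causally on both
sides: with probability `stim_p_erase` an eligible stimulation trial
(early stimulation, 2-back, contralateral last−1 cue; or late stimulation,
1-back, contralateral last cue) sets an erased-memory flag that (a)
redirects the choice to the location the spared memory implies — a rule
error — and (b) truncates the memory-neuron rate for the erased location
at stimulation onset, so neural and behavioral effects cohere while
remaining independently testable. Latency shortening (15 ms) and endpoint
scatter inflation (0.5°) are free parameters applied to all stimulation
trials; the generator makes no mechanistic claim about them.

**What the generator does not emulate:** trial-to-trial rate correlations,
adaptation, oscillations or spike-history effects; waveforms and LFPs;
microsaccades, blinks and drift in the eye signal; learning or motivational
drift across a session. Recovery results on this generator therefore show
that the pipeline is correct and well-calibrated under its stated
assumptions — not that real prefrontal data satisfy those assumptions.

## Decoding protocol

Features are the spike counts of the four decoding epochs (early/late of
the last two delays, D1 and D2) on correct P-N trials: second-to-last cue
at the neuron's preferred location, last cue elsewhere. The published
protocol label ("P-N-FP-off") and its verbal description conflict on which
cue is the preferred one; the package defaults to second-to-last-preferred
(matching the population-alignment figures) and exposes
`pnOrder = "last-preferred"` as the alternative reading. The preferred
location used for trial selection is the 4-location snap of the
memory-component preferred angle, falling back to the visual component for
memory-non-directional neurons.

Per classifier instance, 8 trials per rule per neuron form the training set
(4 epochs × 8 trials × 2 rules = 64 training points per neuron), features
are standardized with training-set statistics, and a soft-margin linear
SVM (cost 1) is trained; 100 held-out pseudo-trials are decoded per
instance and 100 training re-draws give the accuracy distribution.
Decision-boundary ties classify as 1-back — a deterministic,
seed-independent tie-break. Error-trial choice probability reuses the
limited error pools across validation draws, with variability coming from
the training re-draws, and scores an error trial by the rule consistent
with the executed choice (the opposite of the instructed rule, since a
rule error is a saccade to the other rule's target) — one explicit
definition among several the literature leaves open.

## Problem sizes and tolerances

The test suite and `scripts/acceptance.R` choose simulation sizes that make
each claim statistically meaningful while keeping a full run on a single
CPU in minutes: 400-trial sessions for coefficient recovery (median
absolute error < 0.1), 500–1000 null replicates for Wald calibration
(pooled type-I within [0.035, 0.065]), 20 neurons per directional archetype
at gain 8 spikes/s over baseline 5 for type recovery (≥ 90% labels, ≥ 95%
exact preferred locations), 60–100 neuron pools for the decoding sweeps,
100 sessions of 200 trials for θ recovery, and 100 seeded experiments of
17 sessions for the stimulation-effect specificity check. Statistical
assertions use confidence bands matched to those sizes (binomial CIs for
accuracies, 1.96·SEM for the θ difference) rather than point equality.

## Known limitations

* The encoding model is static per epoch; time-resolved or
  history-dependent GLMs are out of scope.
* Wald inference on scaled responses is anticonservative by design (it
  mirrors the conventional analysis); use raw counts or Pearson dispersion
  when calibrated significance is required.
* The stimulation generator implements a single-site, all-or-none erasure;
  graded or spatially spreading effects are not modeled.
* Session files are plain CSV/JSON; binary acquisition formats need
  external conversion.
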