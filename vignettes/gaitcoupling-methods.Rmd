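---
title: "Methods: spike–gait-phase coupling analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike–gait-phase coupling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitcoupling)
```

This vignette is the package's own account of its models and the choices
behind them: what each stage computes, which parameters matter and why
their defaults are what they are, what the synthetic generator does and
does not emulate, and where the design was genuinely open.

## The analysis problem

A mouse walking freely in an arena is filmed bottom-up at 80 frames/s
while extracellular electrodes record striatal single units. Pose
estimation yields per-frame 2-D coordinates of six body parts (four paws,
nose, tail base; 0.3 mm/pixel). The scientific questions are: do single
units fire preferentially at particular phases of an individual limb's
stride cycle; do they also encode whole-body variables (movement
initiation/cessation, speed); and do identified cell classes (D1 vs D2
medium spiny neurons, tagged optogenetically) differ in these codes?

All public interfaces use mm, seconds and degrees.

## Gait segmentation

**Model.** A stride is one stance + swing cycle of one limb. Projected
onto the unit vector from tail base to nose (larger = closer to the
nose), a limb's position oscillates once per stride; after a zero-phase
band-pass restricted to the 0.5–8 Hz gait band, stance onsets are the
troughs of this projection and swing onsets the peaks. Limb phase is 0°
at stance onset and increases linearly in frame index to 360° at the next
stance onset; frames outside detected strides carry no phase.

**Parameters and defaults** (all in `gait_config()`):

* `sg_window = 7` frames (~87 ms). The smoothing filter order (3) is part
  of the method; the window length is a free choice. Seven frames is the
  shortest odd window that meaningfully suppresses pixel noise while
  leaving content at the 8 Hz band edge essentially untouched; it is
  configurable because camera noise varies between rigs.
* `band = c(0.5, 8)` Hz; implemented as a 3rd-order Butterworth applied
  forward–backward (`signal::filtfilt`). Zero-phase filtering is
  essential: stance/swing timing feeds directly into phase, so the filter
  must not shift extrema.
* Extrema: minimum separation 1/16 s (the half-period of the 8 Hz edge),
  and a sign-aware prominence rule — peaks must rise above +10% of the
  bout SD, troughs below −10%. When two same-type extrema appear in
  sequence (the intervening reversal being sub-threshold), the more
  extreme one is kept. Strides whose duration falls outside the band's
  period range (0.125–2 s) are discarded as segmentation artifacts.
* Walking bouts: body speed > 50 mm/s sustained ≥ 0.5 s (gaps < 0.25 s
  merged) proposes candidates; a candidate is auto-accepted when the
  rhythmicity score — the fraction of detrended projected-limb variance
  inside the gait band, averaged over the four limbs — reaches 0.5.
  Broadband (non-rhythmic) limb motion scores ≈ (8 − 0.5)/(40 − 0.5) ≈
  0.19 on raw tracks, rhythmic gait ≈ 1, so 0.5 separates the two
  regimes with margin. The interactive review step this replaces is
  still available as an `overrides` argument keyed by bout id, which
  forces acceptance or rejection and is honored downstream.
* Missing keypoints: linear interpolation across gaps ≤ 5 frames
  (62.5 ms); longer gaps stay missing and the affected frames cannot
  enter bouts.

**Degenerate inputs.** Coincident nose/tail frames make the projection
undefined; isolated ones are interpolated. Bouts with less than one full
cycle yield zero strides without error. Stride length uses the smoothed,
unfiltered coordinates at the two stance onsets, so band-pass edge
effects never contaminate lengths.

## Whole-body motion bouts

Body speed is the centered finite difference of the six-keypoint
centroid. Motion bouts are runs above 50 mm/s lasting at least 0.3 s,
extended to the surrounding 20 mm/s crossings; values exactly at
threshold count as above, making boundaries deterministic. Bouts
truncated by the session edges are flagged, and event-aligned analyses
drop events whose baseline window would leave the session. Merging of
bouts separated by brief dips occurs only through the 20 mm/s extension
itself.

## Phase coding

The firing-rate-versus-phase curve divides the spike count in each 15°
bin by the frame count in that bin and multiplies by the frame rate, so
unequal phase occupancy cannot masquerade as tuning. Each video frame
covers [t, t + 1/80) s and a spike takes the phase of the frame
containing it, matching the frame-count normalization. The mean
resultant vector of this curve (unit vectors at bin centers weighted by
rate) gives the coupling strength (length, 0–1) and preferred phase
(angle). Bin centers (7.5°, 22.5°, …) represent the bins so that flat
tuning yields zero resultant without bias.

Significance uses a spike-time jitter null: every spike is shifted by an
independent uniform draw on ±0.5 s, the vector length recomputed, 100
iterations; the unit is significant for a limb when the real length
exceeds more than 95% of jittered lengths. Jittered spikes are re-binned
against the same phase series, so spikes that land outside walking
frames are dropped exactly as in the real computation — the jitter
operates on spikes in time while the phase comes from video. The
per-limb tests are deliberately not corrected for the four limbs: a unit
is "phase coding" if significant for at least one limb, and that
union rule is part of the definition. Units with any vector length above
0.9 are treated as outliers and excluded from all downstream group
analyses.

A ±0.5 s jitter spans one to several stride periods in the 0.5–8 Hz
band, which is what makes it a phase-destroying null while preserving
slow rate fluctuations; with 100 iterations the achievable per-limb
false-positive rate is 5/101 ≈ 0.05, and the calibration test in the
suite confirms the empirical rate sits inside the binomial 95% band.

## Start/stop and speed coding

Event tests compare, across motion bouts, mean rates in the baseline
window (−5 to −1 s) and event window (±0.5 s) with a paired t-test
(p < 0.05). The modulation index normalizes rates by the baseline mean
(so baseline ≈ 1), bins the event window at 20 ms, takes the maximum
normalized bin as FR_event, and reports |FR_event − FR_baseline| /
FR_baseline — a fractional change capturing elevation or suppression,
invariant to uniform rescaling of the unit's rate. A zero baseline
leaves the index undefined rather than infinite.

Speed coding bins the whole-session speed series at 10 mm/s, computes
the occupancy-normalized rate per bin, and scores the absolute Pearson
correlation of bin rate against bin center. Bins occupied for less than
1 s are dropped — a rate estimated from a handful of frames is noise —
and fewer than three surviving bins leaves the score undefined. The
shuffle null permutes the rate values across speed bins (100
iterations), implementing label exchange at the bin level; the
alternative of shuffling underlying frames would destroy the occupancy
structure the statistic conditions on.

## Optogenetic tagging

Three conjunctive criteria: (1) a significant excitatory response within
6 ms of laser onset, after removing spikes within 0.6 ms of onset where
photoelectric artifacts can imitate spikes; (2) Pearson r > 0.95 between
mean evoked and mean baseline waveforms; (3) a voltage-minimum ratio
< 2, which defeats the scale invariance of the correlation. Criterion 1
is operationalized as a one-sided paired test of per-pulse spike counts
in (0.6 ms, 6 ms] against duration-matched windows immediately before
each pulse; the t form is the default and a rank (Wilcoxon) form is
selectable, since the underlying test is not pinned down by the
criterion itself. The ratio is symmetrized as max(r, 1/r) ≥ 1 so "< 2"
is direction-independent. Fewer than 10 evoked spikes leaves the
waveform criteria undefined and the unit untagged. Tagged units inherit
their label from the session genotype (D1-Cre → D1, A2a-Cre → D2).

## Circular group statistics

The angular permutation test compares two groups of angles by the
Euclidean distance between their mean resultant vectors (each sample a
unit vector), against a null built by reassigning samples to groups with
sizes fixed, 1000 iterations. Significance follows the percentile rule
(real distance beyond the 1 − α/m fraction of resamples, Bonferroni
divisor m), while the reported p-value uses the standard small-sample
correction (1 + exceedances)/(1 + iterations) so it is never exactly
zero — a cosmetic difference from the raw percentile rule, documented
here because the two disagree only in the extreme tail. The angular
deviation √(2(1 − R)), in degrees, summarizes angular spread (81.03° in
the uniform limit).

For vector-length contrasts `compare_groups()` fits the two-way
group × limb ANOVA in the layout used for cell-type comparisons, and
additionally reports a between-unit stratum p-value (`group_p_units`).
The pooled table treats the four limbs of a unit as independent
observations; simulation during development showed that this inflates
the group factor's false-positive rate on equal-coupling cohorts,
whereas the between-unit stratum (equivalent to testing unit means) is
calibrated. Both are reported; the repeated-measures handling across
limbs is genuinely ambiguous in the source layout, and readers can pick
the stratum matching their inferential target.

## The synthetic generator

The generator exists so that every stage can be validated against known
ground truth without recorded data. It emulates:

* **Lateral-sequence gait.** A common oscillator advances at
  `stride_frequency` (default 2.5 strides/s) during scheduled walking
  bouts; each limb oscillates sinusoidally along the nose–tail axis with
  a fixed offset. The defaults (LR 0°, LF 175°, RR 185°, RF 350°) encode
  left–right alternation within each girdle, near-synchronous diagonals
  and the footfall order LR→LF→RR→RF. Exact diagonal synchrony and an
  exact quarter-cycle footfall sequence are mutually inconsistent, so
  the defaults carry deliberate 10° asymmetries; same-side front–rear
  offsets land at 165–175°, i.e. "approximately anti-phase".
* **Sessions.** Default 300 s with five 30-s bouts at 60–120 mm/s —
  desk-scale stand-ins for 30-minute recordings, giving ~370 strides per
  limb (hundreds, as in real sessions) while keeping the test suite
  fast; the acceptance checks that need ≥ 500 strides use a six-bout
  schedule. Stride-timing jitter is an AR(1) phase noise with ~0.5 s
  correlation time and stationary SD 2π·f·`timing_jitter_sd` (default
  3 ms), and keypoints get 0.15 mm i.i.d. localization noise — values
  chosen as realistic for high-resolution tracking, small enough not to
  dominate the 15° phase bins.
* **Spike trains.** Inhomogeneous Poisson with rate
  base × vonMises(phase) × (1 + start transient), plus an additive
  linear speed term, rectified at zero. The von Mises kernel is
  normalized by I₀(κ) so the mean rate over a uniform phase cycle equals
  the base rate and — crucially — the expected recovered vector length
  has the closed form I₁(κ)/I₀(κ), verified by numerical integration
  before the build and used as the recovery oracle (0, 0.2425, 0.4464,
  0.6978 for κ = 0, 0.5, 1, 2). Spikes are drawn per frame
  (piecewise-constant rate) and placed uniformly within the frame.
* **Tagging blocks.** 200 pulses, 10 ms duration, one per 3 s, starting
  10 s after the behavioral session; evoked spikes at a configurable
  latency (default 2 ms, the shortest physiological tagging latency)
  with per-pulse probability; per-spike waveform snippets from a
  biphasic template, evoked ones rescaled (or reshaped) to build
  criterion violators.

**What it does not emulate** — and hence what passing tests do not show
about real data: pose-estimation failure modes (identity swaps, missing
detections beyond simple gaps), grooming and rearing (non-gait rhythmic
motion that the rhythmicity score must reject in practice), speed-dependent
stride frequency, spike-sorting contamination, bursting or refractory
structure, and electrode drift. Turning is available only as a constant-
curvature option without any claim of fidelity to lesioned-animal
kinematics, which the source material does not describe at the limb
level.

## Numerical choices

* Reproducibility is seed-exact: generators and all randomized tests
  (jitter, shuffles, permutations) consume explicit seeds, and identical
  configs reproduce identical reports.
* Phase at a frame is taken from the stride interval containing it
  ([stance, next stance)); the 360° endpoint belongs to the next stride.
* Paired tests with exactly constant nonzero differences (possible in
  deterministic fixtures) are assigned p = 0 rather than erroring;
  all-zero differences give p = 1.
* Permutation/shuffle significance thresholds are strict inequalities on
  the exceedance fraction, making decisions reproducible at the
  iteration counts used.
* Problem sizes in the validation suite (300-s sessions, 200-unit null
  panels, 500-repetition calibrations) were chosen as the smallest that
  give the binomial confidence bands quoted in the tests.

## Known limitations

The stride model is sinusoidal, not a stance-drift/swing-return
sawtooth; detection relies only on band-passed extrema, which are
insensitive to that waveform difference, but stance:swing asymmetry in
real data will shift peak positions relative to the synthetic case. The
rhythmicity score is a variance-fraction heuristic, not a classifier
trained on grooming. HDF5 pose layouts are not read; CSV is the
interchange format. The angular permutation test assumes exchangeability
under the null within the pooled sample and fixed group sizes.
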