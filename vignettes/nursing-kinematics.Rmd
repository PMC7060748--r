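---
title: "Quantifying nursing kinematics from whale-borne motion tags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nursing kinematics from whale-borne motion tags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nursekin)
```

## The problem

Humpback whale calves nurse below the surface, briefly, and in postures
that surface observers routinely misread. Combined video/motion tags
(suction-cup archival loggers carrying a camera, tri-axial
accelerometer, and pressure sensor) let an analyst verify nursing
visually — the calf's rostrum on the mother's mammary gland, milk
visible at release — and then ask whether the accelerometer record
carries a kinematic signature of the behavior. The comparison of
interest is *within* individual and *within* dive phase: did this calf,
during this kind of diving, move differently while nursing than during
matched baseline segments?

`nursekin` implements that analysis: sensor processing, dive-phase
segmentation, randomized phase-matched baseline sampling, per-segment
kinematics, a mixed-effects comparison, and the video time budgets. A
seeded synthetic deployment generator with full ground truth stands in
for raw tag records, which are rarely public for this kind of study.

## Sensor processing

Tag streams arrive at heterogeneous rates (accelerometers at hundreds
of Hz, pressure at ~10 Hz). All channels are decimated to a common
10 Hz analysis rate: a zero-phase 4th-order Butterworth low-pass at 80%
of the target Nyquist, applied forward-backward around reflective
padding, followed by subsampling. Demeaning before filtering makes
constant channels pass through exactly.

Because a suction-cup tag lands at an arbitrary orientation, records
are rotated into the whale frame (x surge forward, y sway left, z heave
up; specific force (0, 0, −9.81) m/s² at rest) using a calibration
window in which the animal is assumed level and unaccelerated —
typically a quiet surface interval. The fixed rotation maps the
window-mean specific force onto (0, 0, −g); windows whose mean force
magnitude differs from gravity by more than 20% are rejected as
non-quiescent. The rotation is rigid, so per-sample norms are
preserved.

Specific force is split into a *static* (gravitational/postural)
component — a centered running mean over `window_s` per axis — and a
*dynamic* remainder, so `static + dynamic == acc` holds exactly,
including at the edges (shrinking windows). The default window is 5 s,
a little over twice a typical ~4 s humpback fluke-stroke period. Two
numerical caveats worth knowing: a boxcar mean leaks a fraction
`sinc(f·w)` of a sinusoid at frequency `f` into the static estimate
(≈18% amplitude inflation of the dynamic at 0.25 Hz with a 5 s window;
zero at an 8 s window), and posture changes faster than the window
bleed into the dynamic component near dive corners. Neither affects
relative nursing-vs-baseline contrasts computed with a common window,
but absolute ODBA levels depend on `window_s` and it should be reported
with results.

ODBA is the L1 norm of the dynamic vector, `|d_x| + |d_y| + |d_z|`.
Pitch is `asin(x/‖static‖)` (nose-up positive) and roll
`atan2(y, −z)`; samples whose static magnitude is implausibly far from
gravity are flagged rather than silently propagated.

Fluke strokes are detected on the dorsoventral dynamic axis (or
optionally on pitch — the choice is a configuration item, since either
oscillates with fluking) after band-passing to 0.1–0.6 Hz. One stroke
is one full oscillation: the detector arms when the signal falls below
−`amp_threshold` (default 0.05 m/s²), records the next positive-going
zero crossing (linearly interpolated), and confirms the stroke only
when the signal then exceeds +`amp_threshold`. The confirmation step
matters: with plain arm-and-cross counting, the sub-threshold wobble
left in a glide by filter ringing and running-mean leakage fires one
spurious stroke per glide. Detection is invariant to constant offsets
by construction.

## Dive phases

Dives are maximal excursions beyond a surface threshold (default 1 m)
reaching at least a minimum depth (default 5 m) — values the breath-to-
breath segmentation needs but that visual analyses leave implicit, so
both are configurable. Each dive is partitioned into:

* **descending** — dive start through the *first* attainment of maximum
  depth (ties broken early, making descending shortest);
* **ascending** — the earliest-starting suffix in which the whale has
  committed to surfacing: depth strictly decreasing into the start
  sample, the decrease sustained at least `ascent_commit_tol_m`
  (default 0.2 m) before depth ever rises back above it, and the whole
  suffix never rising more than `ascent_excursion_limit_m` (default
  10 m, less than an adult body length) above its running minimum;
* **horizontal** — whatever lies between, possibly empty (V-shaped
  dives).

The commitment clause is the operational reading of "had started to
decrease its depth towards the surface": the excursion rule alone
cannot distinguish a flat bottom from an ascent (depth never rises on a
flat bottom, so every bottom sample trivially satisfies it), and a
strict-decrease rule alone is defeated by sub-meter pressure ripple.
With the 0.2 m tolerance, ripple cannot anchor an ascent, re-descents
up to the 10 m limit stay inside the ascent, and larger ones push the
ascent start past the excursion. The classifier is verified
sample-for-sample against an independent brute-force implementation of
the same rule on randomized dive shapes. Pitch is deliberately not used
for phase boundaries: a nursing calf's pitch is confounded by the
behavior under study.

## Baseline sampling

Non-nursing baseline segments are 30 s — the mean nursing event
duration (23 s) plus one standard deviation (7 s) — drawn by the
randomized procedure the comparison design calls for: draw a uniform
start time over the deployment, scan forward to the first admissible
window, repeat until `n` windows are placed. *Admissible* means the
whole window lies inside one contiguous interval of the requested phase
(the strictest reading of phase matching; windows never straddle phase
boundaries or surface time) and overlaps no nursing, probable-nursing,
or poor-video interval, nor any previously selected window.

Feasibility is decided exactly before sampling: the admissible start
set is computed by interval arithmetic and greedy earliest-fit packing
gives the maximum number of disjoint windows; requests beyond it fail
with that maximum named. Because randomized placement does not pack
optimally, requests near the bound can still exhaust the draw cap
(10^5) — the procedure is the specified design, not an optimizer. With
a single free interval the selected start times are exactly uniform
over the feasible range, which the suite checks with a
Kolmogorov–Smirnov test over 200 seeds.

The default design takes 15 baselines per nursed phase per calf
deployment and 9 per mother, only for phases in which that individual
nursed. Mother nursing segments copy the calf's event timestamps
(nursing is scored from the calf's camera); where the mother's tag
covered only a subset of events, her own event rows take precedence
over the wholesale copy.

## Segment metrics and the comparison model

For each segment: minimum, maximum and mean depth; mean speed if the
channel exists (never imputed); mean ODBA; FSR = strokes whose detected
time falls in `[start, end)` divided by duration (edge strokes belong
to the segment containing their zero-crossing time); circular means of
pitch and roll via `atan2(mean sin, mean cos)`, erroring on resultant
lengths below 1e−12 rather than returning an arbitrary angle.

The comparison is a linear mixed model per response (mean ODBA, FSR):

```
response ~ nursing * phase,  random = ~ 1 | individual   (REML)
```

with the nursing effect tested by a marginal (Type III) Wald F. Dive
phase enters with sum-to-zero contrasts so the nursing term is the
phase-averaged nursing effect; under treatment contrasts it would be
the effect at an arbitrary reference phase, which is nearly untestable
when only one deployment nursed in that phase. Denominator degrees of
freedom follow the within-group convention of nested mixed models,
`N − n_individuals − p_within`; for the classic design of 116 calf
segments over 4 deployments this gives F(1, 107). No
Satterthwaite-style correction is applied — the convention is an
approximation, chosen for transparency and portability, and the suite
verifies its calibration directly: over 1000 null simulations of the
116-segment design the 5% test rejects at a rate inside [0.03, 0.07].
Whether the original analyses used marginal or sequential tests is not
documented; marginal is implemented and stated. Mother segments are
summarized descriptively — three nursing segments cannot support a
mixed model.

Budgets use exact closed-open interval arithmetic: nursing seconds as a
percentage of good-quality video per deployment (report rounding:
durations to whole seconds, half-to-even; percentages to two decimals;
speeds to one decimal); non-nursing proximity as
`|proximity ∖ nursing|`; and per-nursing-event shortest gaps to any
foraging event (lunge, dragging, bottom feeding), zero on overlap,
undetermined when a deployment's log records no foraging.

## The synthetic generator

`sim_config()` defines one deployment: a dive plan (surface interval,
descent rate, maximum depth, bottom time, ascent rate per dive, with
optional V-shaped re-descent excursions), a gait, nursing events, and
noise. Defaults are chosen to be realistic for feeding-ground humpback
mother-calf pairs and are fixed once:

* dives to 35–55 m at 1 m/s with 90–150 s bottom times, 60 s surface
  intervals; travel speed 1.5 m/s with a 10% stroke-locked ripple;
* dorsoventral sinusoidal stroking at 0.25 Hz, amplitude 0.3 m/s²,
  which puts baseline segment mean ODBA near 0.2 m/s² — the magnitude
  range published for free-swimming pairs;
* glides occupying 10% of time in exponential bouts of mean 20 s
  (active bouts derived from the glide fraction), with every stroking
  bout running to a completed oscillation and a ~4 s amplitude taper,
  so gating leaves no broadband transient a detector would have to
  disambiguate;
* posture (pitch from smoothed vertical rate over travel speed)
  re-orients over ~14 s, as a large whale does, rather than
  sample-to-sample;
* nursing effect multipliers from the published per-event contrasts:
  calf FSR ×1.7 and ODBA ×1.5, mother ×0.3 for both; during events the
  animal strokes continuously (station-keeping), except that unit
  multipliers leave the record bit-identical (an identity the suite
  asserts);
* Gaussian sensor noise of 0.02 m/s² per axis; depth generated at the
  acceleration rate, subsampled to 10 Hz and held, mimicking the
  pressure-sensor mix; gravity 9.81 m/s².

Everything is driven by one seed; equal configurations produce
bit-identical output, and the ground truth (event log, per-sample phase
labels, stroke times at exact phase-completion instants, noise-free
per-event mean ODBA) is returned alongside the record.
`simulate_study()` arranges deployments in the published structure:
four calves whose 11 events carry the published durations and phases,
plus the two paired mothers holding three of those events.

What the generator does **not** emulate — and hence what passing tests
do and do not show about real data: no heading dynamics or
magnetometer, no tag slippage, no hydrodynamic coupling between
stroking and speed beyond the ripple, no behavioral variety beyond
stroke/glide/nurse, no day-night structure, and depth that follows the
plan exactly rather than a foraging whale's improvisation. Recovery
results on simulated deployments validate the *machinery* (filters,
detectors, interval logic, model plumbing) under known truth; they do
not certify performance on noisier field records, where calibration
windows, stroke bands and thresholds need case-by-case judgment.

## Numerical choices and problem sizes

Tolerances that matter: timestamp uniformity to 1e−6 of a sample
period; frame-correction window mean within 20% of g; stroke hysteresis
0.05 m/s²; ascent commitment 0.2 m; circular-mean resultant floor
1e−12; zero-variance responses detected at var < 1e−16 and returned as
exact zero effects from the fixed-effects fit. Degenerate inputs error
eagerly: empty channels, non-uniform time, overlapping same-type
events, windows shorter than 3 samples, dives too short to classify.

The test suite and the acceptance script simulate at a reduced
acceleration rate (50 Hz, or 20 Hz for the replicated direction
checks) and deployments of 17 dives (~75 min): the synthesized dynamics
live below 1 Hz, far under either Nyquist, and these sizes keep the
full suite under a minute of simulation per scenario while still
hosting the full 15-baselines-per-phase design. The stroke-recovery
checks compare detected against ground-truth stroke counts per 30 s
within-phase window on a continuous-gait deployment (posture corners
and glide-bout edges produce ±1 jitter near window boundaries on diving
records, where whole-record counts are held to 5%).

## Known limitations

* The running-mean static estimate biases absolute ODBA as a function
  of window length and stroke frequency (see above); comparisons should
  fix one window.
* Denominator df and the Wald F are approximations; with four
  individuals, random-intercept variance is weakly identified (REML
  fits are accepted even when the variance estimate hits zero).
* The sampler emulates the published randomized procedure faithfully,
  including its inability to reach exact packing bounds; requesting
  close to the theoretical maximum may be slow or fail.
* Heading is not computed (magnetometer calibration is undescribed for
  the source deployments); circular statistics are exercised on pitch
  and roll.
* Annotations are assumed to be expressed on the sensor time base; the
  mapping from video timestamps to sample indices is outside the
  package's scope.
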