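---
title: "Methods: bottleneck-crossing kinematics and the synthetic gait generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bottleneck-crossing kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures the package implements,
the choices made where a definition was genuinely open, and what the
synthetic generator does and does not emulate. It states no empirical
result beyond what the test suite and `scripts/acceptance.R` compute.

## Coordinate conventions

The world frame puts the origin at the bottleneck centre, the crossing
line at *y* = 0, the approach side at *y* > 0, and *x* > 0 on the side of
positive approach angles. Angles are degrees, distances metres, times
seconds; all series are resampled to a uniform 60 Hz grid on load. With
this convention the crossing-offset law for positive angles reads
*C*(*w*) = +0.176 *w* − 0.078 with a single sign rule (mirror-negated for
negative angles).

## Per-run pipeline

**Crossing and distance.** The crossing is the COM sample with minimal
|*y*| (earliest on ties; an error if the path never comes within 0.5 m of
the line). The distance to crossing *d* is the cumulative chord length
along the COM trajectory, signed positive before the crossing. Chord sums,
not Euclidean offsets, so curved approaches are measured along the walked
path.

**Speed.** The running-mean speed is the two-point window-edge difference
of *d* over a centred 0.5 s window (about one step), which equals the
window mean of the instantaneous path speed and is exact on affine *d*.
Near the trajectory ends the window shrinks symmetrically so the first and
last samples always participate; at the extreme edge samples a one-sided
single-step difference is used. The same shrink rule drives the
running-mean smoother used elsewhere. *v*max is searched over
*d* ∈ [0, 3.5] m and *v*min from the time of *v*max to the end of the
recording ("end of the walking path" is read as the last recorded sample).
The mean speed runs from the first sample within a 3 m radius of the
origin (excluding the acceleration phase) to the crossing. Phase
boundaries elsewhere are measured on *d*; only the mean speed uses the
radius, and both conventions are configurable.

**Deceleration.** The classification acceleration is the central
difference of the *raw* chord speed followed by the 0.5 s running mean.
Smoothing the already-smoothed speed again would smear any braking episode
by a full second of negative support, so no brake could ever classify as
"shorter than 1 s"; with a single smoothing pass an episode of duration
*D* appears as roughly *D* + 0.5 s of negative acceleration and the
duration threshold separates categories as intended. Strictly negative is
implemented as *a* < −10⁻⁹ m/s²: a pure float-noise wiggle of a
constant-speed run must not form a group, and the floor is five orders of
magnitude below the amplitude threshold. Within the 3.5–0 m window,
maximal negative groups are formed; the first group longer than 1 s is
evaluated if one exists, otherwise the first group. "Longer than 1 s" is
strict (a boundary-equal duration falls to the short branch); "larger than
the amplitude threshold" is read as larger in magnitude
(*a* ≤ −0.0075 m/s²), with a config flag for the literal reading. A single
negative sample is given one sample period of duration. The −0.0075
default reproduces the 3σ rule applied to straight-walking acceleration
noise of sd 0.0025 m/s².

**Shoulder rotation.** γ is the signed angle from the movement direction
(COM chord across a 0.5 s interval, shrunk one-sidedly at the edges) to
the facing direction (right→left shoulder vector rotated −90°); positive
is a left turn. Samples with less than 1 mm of COM displacement in the
window are flagged undefined. The straight-phase mean is subtracted before
the 3σ onset test — this removes per-run posture bias; disable with
`center = FALSE`. The onset search is restricted to *d* < 1.5 m so the σ
estimation window cannot contain its own trigger. The maximum is the
largest |γ − straight mean| at or after the onset, reported signed
(figures in this literature report absolute maxima; the sign carries the
turn direction), earliest sample on ties.

**Steps.** Heel speed is |vx| + |vy| (the sum of the coordinate
derivatives, as in the original detector; Euclidean available via config).
Stance phases are maximal sub-threshold intervals of at least 0.1 s and
the strike is the stance onset — the physically labelled equivalent of
triggering on the threshold crossing; a polarity flag switches to swing
onsets. A stance already in progress at the first sample has no observable
onset and yields no event (unless the foot is static for the entire
recording), which prevents spurious simultaneous "strikes" at recording
start when participants stand before walking. The default threshold is
20% of the 95th percentile of the run's pooled heel speed ("manually set"
in the original procedure); an absolute override exists. Foot-on-floor
assignment takes the latest strike at or before the event and refuses
(`"none"`) when the strike sequence does not alternate, since a missed
contact cannot be excluded.

## Aggregate statistics

**Crossing law.** Offsets are folded onto the side of origin (side sign
from the approach angle; straight approaches are excluded by default or
side-assigned by the offset's own sign) and regressed on width. The
derived `shift_per_10cm` is slope × 10 in cm.

**Amplitude law and critical ratio.** |γmax| against *R* = *w*/*s* is
fitted with *a* e^(−*b R* + *c*) + *d*. Since *a* and *c* are jointly
unidentifiable, the three-parameter form *a*′ e^(−*b R*) + *d* is fitted
(Levenberg–Marquardt, multi-start over *b* ∈ {0.5, 1, 2, 4, 8}, *a*′ ≥ 0)
and reported with *c* = 0. Constant input degenerates to *d* = mean,
*a*′ = 0, flagged. The critical ratio evaluates the fitted curve on 180
evenly spaced points over [0.8, 2.6], partitions them into 36 consecutive
intervals of width 0.05, and compares all interval pairs with
studentized-range tests at the 0.95 level, using the fit's residual sd and
per-interval observation counts (Tukey–Kramer denominator,
df = Σn − k, floored at 2 where qtukey is defined). *R*crit is the lower
edge of the earliest interval from which on no pairwise difference is
significant; a single-interval suffix is trivially non-significant, so a
strictly decreasing curve yields the domain's last interval edge and a
globally flat curve yields 0.8. The error model inside this grid procedure
is this package's own normative interpretation of an under-specified
published recipe, and is documented as such.

**Correlations.** Pearson (Spearman via config) on encoded variables
(binary → ±1, angle in degrees), pairwise-complete, masked at *p* ≥ 0.05,
split at the literature value *R* = 1.3.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
with a ground-truth channel for recovery testing.

- **Path**: straight entry from the starting position (4 m radius at the
  approach angle; pulled to *y* ≥ 0.3 m at ±90°, where the circle touches
  the crossing line that the wall panels occupy) towards a corner above
  the crossing point, a circular-arc fillet, and a straight vertical exit
  through the crossing offset drawn from the linear law (Gaussian noise
  sd 0.05 m, resampled then clamped to ±(*w*/2 − 2 cm)). The heading is
  tangent to the exit line at the crossing.
- **Speed**: rest → constant acceleration (normal: 1.25 m/s² for 1.2 s →
  1.5 m/s; hurried: 1.4 m/s² for 1.5 s → 2.1 m/s, matching the reported
  median maxima) → cruise with i.i.d. speed noise → a braking pulse drawn
  from the five-category mixture. Pulse shapes are raised cosines whose
  durations and peaks clear the classifier thresholds with ≥ 20% margin
  *after* smoothing (long 1.5 s, short 0.2 s; strong peaks 0.6–0.67 m/s²,
  weak 0.005 m/s²; long pulses trigger 2.4 m, short 2.0 m before
  crossing). The hurried mixture assigns zero probability to `long_weak`:
  with cruise at 2.1 m/s and acceleration ending ~2.5 m before crossing,
  the 0–3.5 m window cannot contain a weak negative group longer than 1 s
  (the group truncates at the crossing), so the category is unrealisable
  there — consistent with its rarity in hurried walking.
- **Positions are stepped so that consecutive-sample chords equal
  v·Δt exactly** (fixed-point sub-stepping along the arc), so the
  analysis-side chord-sum metric is exact on noiseless runs and margin
  properties can be asserted without tolerance gymnastics. The time base
  is computed from the sample index to avoid accumulated float drift.
- **Rotation**: facing = path heading + gait-locked baseline sinusoid
  (default 4° at the stride period, positive during left-foot swing — the
  natural pattern; the literature gives no amplitude, so it is
  configurable) + a triangular turn ramp that starts `onset_lead` before
  the crossing (defaults 0.41 s normal, 0.46 s hurried) and peaks
  `peak_lag` after it (0.075 s / 0.02 s), with amplitude from the
  exponential law (defaults *a*′ = 205, *b* = 1.9, *d* = 8° — chosen once
  to give ~43° at *R* ≈ 0.9 falling to ~10° at *R* ≈ 2.3, plausible for
  this literature) plus 3° scatter, or from an explicit ramp slope. The
  turn direction couples to the stance foot at the peak (left turn ↔
  right foot) with probability `p_couple` = 0.8.
- **Gait**: strikes at 2 steps/s from 0.25 s, first step with the right
  foot (the instructed start); stance 60% of the stride; swings are cosine
  eases to ground targets on alternating sides of the path (step width
  0.12 m). The right heel starts 0.4 m behind its first target so the
  first swing is detectable at speed.
- **Noise**: band-limited Gaussian position noise (15-sample moving
  average rescaled to a marginal sd of 5 mm) on every body point —
  tracking jitter is low-frequency, and white position noise at 60 Hz
  would inflate chord-sum path lengths — plus band-limited orientation
  noise (default sd 1°) on the shoulder line.

For the onset-recovery conditions (approach at constant final speed with
a 200°/s ramp and "straight-phase rotation noise sd 1°"), the 1° is
composed as a 1.2° gait-locked oscillation plus 0.53° band-limited noise.
In real gait the straight-phase rotation variability is dominated by the
periodic oscillation; a pure Gaussian sd-1° signal would false-trigger a
3σ rule in over a tenth of runs and shift the mean onset by several
centimetres, which contradicts the clean published means this condition
reproduces. The residual difference between the recovered onset distance
and the nominal lead × speed product is the detector's structural lag:
threshold crossing at 3σ on a finite ramp plus one-sample quantisation,
about 0.02 s.

What the generator does **not** emulate: biomechanically validated
whole-body dynamics, hip/head rotation and shoulder–hip phasing,
participant-specific gait idiosyncrasies, heteroscedastic tracking
dropouts, or interactions between pedestrians. Passing recovery tests
therefore shows that the detectors invert this generative structure, not
that they are robust to every artefact of real motion-capture data. With
the default measurement noise the weak/strong boundary of the
deceleration classifier blurs exactly as it would on real data; the 100%
category-recovery guarantee holds for noiseless runs only, by design.

## Problem sizes and seeds

The test suite validates operators on arrays and on synthetic batches of
20–200 runs; the acceptance script uses 200 runs per onset condition and
100 per speed condition, matching the scale at which the corresponding
means and medians stabilise (standard errors an order of magnitude below
the comparison tolerances). All randomness flows from one root seed via
`sample.int`-derived per-run seeds, so any single run is reproducible in
isolation; `generate_run` restores the caller's RNG state.

## Known limitations

- At large approach angles the movement-direction chord deviates from the
  instantaneous heading inside the arc, contributing curvature-induced
  apparent rotation; onset statistics at ±60–90° partly reflect path
  curvature, as they do in real data.
- The critical-ratio error model (residual-sd based, equal-correlation
  Tukey grid) is one defensible reading of an under-specified procedure;
  absolute *R*crit values depend on it, though plateau localisation is
  tested to one interval width.
- `long_weak` braking cannot be generated under the hurried profile (see
  above); the classifier itself still recognises the category wherever the
  data contain it.
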