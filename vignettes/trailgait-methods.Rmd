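---
title: "Methods: from raw wearable streams to footwear contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw wearable streams to footwear contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Footwear effects on trail running are usually studied in the lab, which
removes exactly the terrain the shoes are designed for. The alternative is a
field design: each runner covers a fixed trail loop several times in an
A-B-B-A counterbalanced order, once per lap in one of two closure
configurations of the same shoe (a Wrap and a Lace), instrumented with

* a heel-counter IMU: a ±16 g accelerometer and ±2000 °/s gyroscope at
  1125 Hz, plus a ±200 g accelerometer at 1600 Hz (13-bit), all samples
  UNIX-timestamped;
* capacitive plantar-pressure insoles at 100 Hz;
* a GPS watch with an optical heart-rate sensor at 1 Hz.

`trailgait` implements the complete processing chain from these raw streams
to per-stride biomechanical outcomes and mixed-effects contrasts, together
with a synthetic-study generator that carries known ground truth so that
every stage — and the chain as a whole — is testable without access to raw
recordings.

## Processing pipeline

**Accelerometer fusion.** Running impacts saturate a ±16 g accelerometer.
The high-g stream is linearly interpolated onto the low-g timestamps and
substituted, per sample and per axis, wherever the low-g reading is at the
rail (|a| ≥ 16 g − ½ LSB, catching rail-limited quantized codes). Clipping
is a per-channel ADC phenomenon, which is why the test is per axis rather
than on the vector norm.

**Hop gate.** Each lap starts with three synchronization hops. They are
detected as bursts of |‖a‖ − g| above 3 g with a refractory gap; everything
before a short settle time after the third burst is excluded from analysis.

**Stride segmentation.** Foot contacts are peaks of the squared jerk
magnitude (first difference of the fused acceleration × rate, summed over
axes), smoothed with a 9-sample moving average, above an adaptive threshold
of 10 × the 1-s rolling median, with a 0.4 s refractory period. The short
moving average matters: the squared jerk of white sensor noise is
χ²-distributed and its extreme tail crosses 10 × the median a few times per
lap; averaging 9 samples drives that false-positive probability to
negligible levels while leaving impact peaks (coherent over ~10–20 ms)
essentially untouched. A stride is contact to next contact of the same
foot; stride times outside 0.4–2.0 s are flagged by QC.

**Running speed.** Speed is stride length over stride time. Stride length
comes from double integration between consecutive midstance instants: the
orientation is initialized at midstance from the accelerometer gravity
direction (the foot is quasi-static at foot-flat), propagated by gyroscope
integration (exact per-step Rodrigues rotations, compiled), gravity is
subtracted in the aligned frame, and the velocity integral is corrected by
subtracting the linear ramp that forces velocity to zero at both
zero-velocity-update (ZUPT) anchors. Midstance is the minimum of the
smoothed gyro magnitude within the central 25–75 % of the stride, with the
accelerometer's deviation from gravity added as a secondary quiescence term
— both are minimal at foot-flat, and the extra term keeps the anchor
well-defined on degenerate windows where the gyro is near-zero throughout.
Stride length is the horizontal norm of the net displacement: on sloped
terrain "running speed" is conventionally a ground-plane quantity, and the
horizontal projection also discards the vertical velocity impulse injected
by impact transients, which a linear de-drift cannot fully remove. The
integration window is midstance-to-midstance (where the ZUPT anchors live)
while metric windows are contact-to-contact (where outcomes are defined).

**IMU stride metrics.** From the 50 Hz zero-phase-filtered fused signal:
peak acceleration norm, peak jerk norm (central differences), and the
medial-lateral axis max − min range. Peak eversion velocity is computed
from the raw gyroscope filtered at 30 Hz (transient impact spikes would
otherwise dominate), as the signed maximum toward eversion within the first
20 % of the stride. For a right foot with the frontal channel measuring
roll about the anterior axis, eversion is a negative roll rate; the axis
map mirrors the sign for the left foot, so the metric is side-agnostic.
All filters are second-order Butterworth applied forward and backward
(zero net phase; squared magnitude response, hence gain ½ at the cutoff),
with odd reflection padding at the edges.

**Plantar pressure.** Stance phases are detected on the total insole force:
candidate crossings at 5 % of the lap's median peak force are refined by
descending the force curve from the adjacent steepest-gradient frame to the
local baseline, giving contact and toe-off to about one frame on ramp-like
onsets. The heel and toe regions are the rear and front 20 % of sensor
rows. Contact area is the percentage of a region's sensels above 2.5 kPa (a
typical capacitive noise floor), averaged over stance frames; regional peak
pressure is the stance maximum over the region's sensels.

**Course segmentation.** The loop is a closed triangle of three legs
(uphill 580 m at +4°, technical top 520 m at +2°, downhill 470 m at −6°).
Each GPS sample is assigned to the nearest leg (point-to-segment distance
in a local planar frame); per-section path length is the haversine sum over
consecutive samples sharing a label (sphere radius 6371 km). GPS time zero
is aligned to the detected run start, and every stride or step inherits the
section label of the GPS sample covering its contact time. Subjects whose
lap times range over more than 60 s (strictly) are excluded.

## Statistical models

Outcomes are compared per trail section, because all of them are speed
dependent. Three model forms are available, with Lace as the reference
level so the `Config` coefficient is the Wrap − Lace effect:

* `Outcome ~ Config + (1 | Subject)` for heart rate and questionnaire
  items (one observation per lap-section or per subject-condition);
* `Outcome ~ Config + (Config | Subject)` for all stride/step-level
  biomechanical outcomes — a random intercept plus a subject-specific
  response to the closure change;
* `Outcome ~ Config + Speed + (Config | Subject)` as a sensitivity form
  adding speed as a covariate for IMU outcomes.

Fits are REML via `lmerTest`/`lme4`. Inference on the `Config` coefficient
uses the Satterthwaite t-test rather than a normal reference: with the
effective denominator degrees of freedom near the number of subjects, a
z-test rejects a true null in roughly 8 % of datasets at a nominal 5 % for
a 10-subject design, while the Satterthwaite test holds its size (the test
suite verifies this over 500 null simulations). When the random-slope fit
is singular — usually a boundary estimate of the intercept–slope
correlation — the model is refit with uncorrelated random effects, and
only if that is also singular does it fall back to random intercepts, with
a warning and a flag in the output. Contrasts and percent differences are
computed from estimated marginal means (`emmeans`), never raw means; for
these balanced designs the emmean difference equals the `Config`
coefficient, which the tests assert against a paired-subject-means oracle.
α = 0.05 throughout; no multiplicity correction is applied.

## The synthetic study

The generator draws stride-level truth and then renders raw signals from
it, so the pipeline's estimates can be compared against exactly known
values.

**Truth model.** For each outcome, per-section × per-configuration
population cell means are the study conditions; each subject adds a random
intercept (shared across sections) and a random condition slope, and each
stride adds residual noise:

`value = cell_mean(section, config) + intercept_s + slope_s · 1(Wrap) + ε`.

The condition effects are therefore carried by the cell means themselves —
about a 5 % eversion-velocity reduction, a +2 pp heel-contact-area gain and
a +0.03 m/s speed gain in the Wrap. The published tables give
between-subject SDs (used for the intercepts) but no variance components
for the condition response, so the slope SDs are a design choice. They are
set power-first: small enough (speed 0.008 m/s, eversion 6 °/s, heel area
0.8 pp) that a 29-subject round trip has >99 % power and its recovery error
is dominated by pipeline bias rather than by which 29 subjects were drawn.
This is deliberate: the round-trip acceptance checks are meant to test the
measurement chain, not statistical luck. The flip side is stated plainly —
with these SDs the synthetic p-values are far smaller than a real study
would produce, and the generator understates the terrain-induced
stride-to-stride variability of real trail running.

**Waveform template.** Each stride of duration T renders as:

* a foot-flat window (contact to 0.40 T) with zero velocity and rotation —
  the ZUPT assumption holds by construction;
* a swing phase (0.40–0.98 T) whose anterior velocity is a sin² bump
  integrating exactly to the true stride length; the medial-lateral channel
  is the second derivative of a compactly supported displacement profile
  (h(u) = sin(2πu)·sin²(πu)), so it is continuous at the swing boundaries
  and contributes exactly zero net velocity and displacement while setting
  the M/L range; a sagittal pitch rotation (±36°) makes swing
  rotationally "loud" so midstance detection is realistic;
* a biphasic frontal-plane gyro pulse — eversion peaking at 8 % of the
  stride (inside the measured first-20 % window), inversion returning the
  net angle to zero by 0.28 T — whose amplitude is pre-compensated for the
  30 Hz measurement filter;
* a landing impact on the vertical axis: a raised-cosine bump plus a
  45 Hz windowed ringing rider. The bump width and rider amplitude are
  solved per stride against the numerically computed 50 Hz filter response
  so that the *filtered* peak acceleration and peak jerk equal the drawn
  truth. The rider is needed because a smooth unimodal bump cannot produce
  the jerk-to-acceleration ratios observed through a 50 Hz filter
  (~215 s⁻¹); real impacts carry near-cutoff oscillatory content.

Emitted accelerometer samples are the world-frame specific force rotated
through the orientation implied by the emitted gyroscope; because the roll
and pitch windows are time-disjoint and single-axis, this rotation is
closed-form, while the pipeline inverts it by general numerical
integration — the two paths are independent, so the speed tests are a real
check of the orientation code. The low-g stream is clipped at ±16 g and
quantized to 16 bits; the high-g stream is quantized to 13 bits over
±200 g and never clipped, so heavy downhill impacts genuinely exercise the
fusion path. A generator self-check trapezoid-integrates the emitted
template and errors if the displacement misses the truth by more than 1 %.

**Pressure, GPS, heart rate.** Stance lasts 0.35 T; the number of loaded
heel/toe sensels per frame encodes the true contact areas (rounded to the
25 × 9 grid), and one reference sensel's profile peaks at the true regional
peak pressure. GPS positions walk the course triangle at the true stride
speeds with AR(1) position noise (ρ = 0.99, stationary SD 2 m): consumer
GPS error drifts slowly, and white noise of that SD would inflate a 1 Hz
haversine path length by tens of percent, which real watches do not show.
Heart rate is the per-section truth plus AR(1) noise. Questionnaire
responses are latent-normal draws rounded onto the 0–10 scale. One
optional subject slows a single lap so their lap-time range is ≈143 s,
exercising the one-minute exclusion rule (29 of 30 retained).

**What the generator does not emulate.** Terrain-resolved foot placement,
soft-tissue artifacts, sensor drift between laps, heart-rate physiology
beyond section means, and realistic response heterogeneity (see above).
Passing round-trip tests therefore demonstrates correctness of the
processing chain under its stated assumptions, not validity on real trail
data.

## Numerical choices and degenerate inputs

* Sampling rates are derived from the mean timestamp interval
  (span / (n−1)), which is robust to per-sample jitter from timestamp
  serialization; rates more than 1 % off nominal are a load error.
* Orientation propagation uses trapezoid-averaged angular rates and exact
  Rodrigues steps; at 1125 Hz the commutation error over a stride is
  ≪0.1 % of stride length.
* The de-drifted velocity is exactly zero at both ZUPT anchors (machine
  precision), and a constant world-frame acceleration bias is provably
  absorbed by the linear de-drift — both are asserted in tests.
* An all-zero force trace yields zero stances; a stationary IMU yields
  zero strides; an empty GPS track leaves strides unlabeled and the
  statistics skip them; an empty section gives NA heart rate, not an
  error.
* Laps are treated as independent (no rest-period or drift modeling).

## Problem sizes

The packaged configuration reproduces the full loop geometry (1.57 km,
~700 strides per lap). The round-trip study used by the acceptance checks
runs at `lap_scale = 0.12` — geometrically similar laps of ~190 m with
identical speeds, slopes, rates and effect structure, 29 subjects × 4 laps,
~9 500 strides and steps in total — which keeps a full simulate + process +
analyze cycle at a few minutes on one core. Course-geometry checks
(the 580 m uphill path length) run at full scale, where GPS noise is small
relative to the legs. The statistical calibration check runs 500 null
simulations of a 10-subject, 50-strides-per-condition design.

## Known limitations

* Stride-time jitter of a few milliseconds arises because the detected
  contact rides on the impact's filtered shape, which varies stride to
  stride; this propagates to ~1 % speed noise, comparable to published
  foot-IMU estimators.
* Strides adjacent to a section boundary can inherit the neighboring
  section's larger impact through the zero-phase filter's backward smear,
  slightly inflating their peak acceleration/jerk; two strides per lap at
  most.
* The final stride of each lap has no following midstance anchor and gets
  no speed estimate.
* Peak-jerk truth beyond what a 50 Hz filter can pass (given the drawn
  peak acceleration) is clamped to the achievable shape family; extreme
  tail draws are rendered best-effort.
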