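---
title: "Methods: course mapping, power decomposition and poling kinematics in sit-skiing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: course mapping, power decomposition and poling kinematics in sit-skiing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitski)
```

## Scope and data model

`sitski` analyses cross-country sit-skiing sessions from three streams: a
1 Hz GNSS track with elevation and heart rate, a wrist IMU stream
(3-axis gyroscope and accelerometer), and a course definition that cuts one
lap into contiguous terrain sections. The analysis chain is: map the track
onto a common reference polyline, interpolate virtual split times at
section boundaries, derive section speeds, decompose external power,
detect pole plants and build cycle statistics, and summarise intensity per
terrain. Every stage can be exercised against the synthetic session
generator, which emits all three streams together with the exact ground
truth that produced them.

## Course representation

A course is an ordered sequence of sections with along-surface lengths and
signed mean grades (rise/run percent). Grade enters all trigonometry as
α = atan(grade/100); no small-angle shortcut is used because real courses
reach 16% grades, where sin α and tan α differ by ~1%. When terrain labels
are not given explicitly, sections are classified by a flat band defaulting
to (−3%, +3%): courses of this kind have near-level "flat" sections while
labelled downhills start around −6%, so ±3% separates the populations with
margin on both sides. The band is configurable per call.

Printed course tables sometimes disagree with the surveyed lap total (the
bundled 16-section demonstration lap sums to 1,915 m while the associated
survey total is 1,918 m). `build_course()` therefore accepts a
`lap_length` override that rescales all section lengths proportionally;
the default is the arithmetic sum, which keeps the printed lengths exact.

Course files are JSON (`read_course()`/`write_course()`). YAML is not
supported because no YAML parser is available in the package's dependency
budget; JSON expresses the same schema.

## Track mapping and virtual splits

Receiver-measured path lengths differ between laps and accumulate error,
so all timing uses one **common reference polyline** with known
along-course distances. Geographic coordinates are projected to a local
planar frame (equirectangular about the polyline origin; sub-decimetre
distortion below ~10 km, verified by an origin-invariance test), and each
track point is assigned the along-course distance of its nearest point on
the polyline.

Projection is **forward-monotonic**: candidate segments are limited to a
window from 5 m behind to 50 m ahead of the running along-course position,
which disambiguates self-crossing and out-and-back layouts; among
equally-near candidates the smallest advance wins. The first sample is
anchored to the candidate nearest the course start (closed loops tie the
first and last segment there), allowing a slightly negative start offset
when the recording begins behind the line. A sample farther than a 30 m
gate from the polyline aborts the mapping with the sample index — that is
a wrong-course or corrupted-fix condition, not noise.

Raw projected distances are smoothed with a centred rolling mean of 3
samples (edges kept raw, so noise-free constant-speed tracks are
reproduced exactly), made non-decreasing, and interpolated linearly at
section boundaries to give virtual split times. Boundaries falling just
outside the sampled distance range (up to 10 m) are recovered by linear
extrapolation with the local slope; beyond that a section is reported as a
*missing split* rather than silently dropped. Within a lap the exit time
of one section is by construction the entry of the next, so section
durations sum exactly to the lap time. Instantaneous speed is the central
difference of the smoothed distance, median-filtered over 3 samples; no
smoothing scheme is prescribed by the sensor, so these windows are package
choices sized to 1 Hz sampling.

With 2 m-per-axis isotropic position noise at 1 Hz — the quality of a
wrist GNSS watch — the per-section mean absolute timing error on
20–180 m sections stays below 0.9 s (tested over 20 seeded replicates),
consistent with published error bands for common-trajectory timing.

## Power decomposition

Total external power is modelled as

$$P_{tot} = \underbrace{m g \sin\alpha\, v}_{P_g}
          + \underbrace{m g \cos\alpha\, \mu_s v}_{P_f}
          + \underbrace{\tfrac12 \rho v^3 A C_d}_{P_d}$$

with total moving mass $m$ (athlete + sledge + poles + skis), friction
coefficient $\mu_s$, air density $\rho$ and posture-specific drag area
$A C_d$ (only the product is ever used, so only the product is stored).
Downhill sections are excluded from power reporting by default: the skier
does not pole downhill, so the expression would not describe propulsive
work. Drag areas may differ per terrain (poling postures uphill and on the
flat; a tuck downhill).

Reproduction runs use $m = 71.7$ kg — the midpoints of the published
ranges (65–70 kg body, 2.2/0.7/1.3 kg equipment) — because the exact body
mass is anonymised to a range. Sensitivity: ±2.5 kg moves the uphill
sprint power by roughly ±11 W (~3%).

**Friction from glide tests.** In a passive glide through a zone of length
$d$, ignoring drag (which is small in a tucked posture at glide speeds),
the energy balance gives
$\mu = [(v_{in}^2 - v_{out}^2)/(2 g d) - \sin\alpha]/\cos\alpha$.
The $\cos\alpha$ division makes the inversion exact against the forward
deceleration model on any grade; on the level zones where glide tests are
actually run it changes nothing. Ignoring drag biases $\mu$ upward by
exactly the drag work spread over the zone, $W_d/(m g d)$; with a
*poling*-posture drag area this would be ~0.007, so the assumption is only
sound for the tucked posture in which the tests are performed (the package
tests verify the bias identity against an independent ODE integration
rather than assuming it negligible). Repeated bouts are combined by
arithmetic mean.

**Maxima.** A terrain's maximal speed is the best of repeated 20-m sprint
trials; maximal power is the power model evaluated at that speed on that
section's grade. Session values are reported as percent of these maxima.

## Pole-plant detection and cycle statistics

The wrist IMU shows a stereotyped signature per poling cycle: a smooth
roll-rate peak (gyroscope x) as the arm is raised, followed within a
fraction of a second by a sharp specific-force transient (accelerometer z)
at pole impact. Detection is two-stage: gyro-x local maxima with
prominence ≥ 100 deg/s over a 0.2 s neighbourhood gate a search for the
first accel-z crossing of 10 m/s² within 0.3 s; plants closer than 0.4 s
are merged keeping the larger spike. The stage *logic* (peak → next
spike) and the cycle acceptance gate of 0.6–3 s are the field-validated
part; the amplitude thresholds are package defaults with no published
values behind them — they are chosen so the clean synthetic signature is
detected with an order-of-magnitude margin, and all are configurable in
`detector_config()`. Misclassification sources (turns, arm stretches,
tucked descents) are handled only through the acceptance gate and
refractory period; no movement classifier is built.

Cycle rate is 60/cycle time for accepted cycles. Cycle length is the
containing section's mean speed × cycle time (midpoint rule for cycles
straddling a boundary): 1 Hz GNSS supports section-mean speeds but not
per-cycle distances. Terrain statistics pool all accepted cycles in that
terrain; a terrain with no accepted cycles is reported absent (count 0,
`NA` statistics), not as zero — downhill rows are typically absent because
the skier descends tucked. IMU and GNSS clocks are aligned by a
configurable constant offset (default 0); no automatic synchronisation is
attempted.

## Heart rate and statistics

Section heart rate is the time-weighted (trapezoidal) mean over the split
window, as % of the athlete's laboratory peak; sections with under 80%
heart-rate coverage are flagged. No lag correction is applied for delayed
heart-rate kinetics — the delay is a real feature of the physiology that
the terrain summary is meant to expose, not an artefact to remove.

Matched section × lap values between two sessions are compared with a
classical paired t test; terrain-vs-terrain contrasts use the Welch
(unequal-variance) independent t test, a deliberate choice where the
variance assumption of the pooled form cannot be checked — the pooled form
is available via `var_equal = TRUE`. Zero-variance inputs are reported as
degenerate results rather than errors. Both implementations are tested
against the textbook closed forms to 1e-9 and the paired test's type-I
error is verified to sit at the nominal 5% under a simulated null. No
multiple-testing correction is applied, matching standard practice in
single-athlete monitoring reports.

## The synthetic world

The generator emulates exactly the stated conditions of a field session:

* the 16-section, 1,915 m demonstration lap (or any course profile),
  realised geometrically as a circular loop — chosen over fancier layouts
  because it is smooth, non-self-crossing and identical in testing value —
  or a straight out-and-back that *does* exercise the self-crossing logic;
  horizontal advance per vertex is ds·cos α with the elevation channel
  climbing ds·sin α, so the 3-D arc length equals the lap length;
* per-terrain target speeds with linear ramps over 5 m at boundaries
  (high-intensity defaults 2.4/5.7/7.1 m/s uphill/flat/downhill,
  low-intensity 1.7/4.2/5.7 m/s — the published terrain means);
* pole plants as a renewal process at the configured rate (spacing
  60/rate, 5% CV jitter — deterministic enough to test means, variable
  enough to be realistic), suppressed downhill;
* first-order heart-rate kinetics dHR/dt = (HR\*(terrain) − HR)/τ with
  τ = 30 s, a mid-range value for moderate-to-heavy exercise transitions
  (the field literature discusses the delay only qualitatively);
* GNSS at 1 Hz with isotropic horizontal position noise (elevation kept
  noise-free, standing in for barometric altimetry), IMU at 128 Hz with
  Gaussian channel noise; the session continues ~10 s past the finish so
  the 1 Hz sampling covers the final boundary.

All randomness flows from one seed (Mersenne-Twister, inversion), making
output byte-identical across runs and platforms.

What the generator does **not** emulate — and hence what a green test does
not establish: multipath and autocorrelated GNSS error (white noise only),
full 6-DOF biomechanics of the poling arm (only the two detection-relevant
signatures are synthesised), fatigue and pacing drift, wind, and
snow-condition changes. Detector performance on synthetic noise therefore
validates the algorithm's logic and thresholds, not its field success rate
on arbitrary athletes.

## Numerical choices and degenerate inputs

* Splits: interpolation tolerance 1e-6 s on noise-free input; boundary
  extrapolation capped at 10 m; partially covered final laps keep their
  reached sections and report the rest missing; tracks covering less than
  one lap are an error.
* Mapping: 5 m backtrack tolerance, 50 m look-ahead, 30 m gate; ties
  broken toward the smallest along-course advance.
* Power: v = 0 is legal (all-zero breakdown, undefined shares reported as
  `NA`); component additivity is exact by construction.
* Glide: a skier stopping inside the zone is flagged with the stopping
  distance; negative friction estimates are returned with a warning, not
  suppressed.
* Detector: empty streams yield empty results; non-increasing timestamps
  are an error; plateau peaks are collapsed to their first sample.
* Dropouts: sampling gaps above 30 s are flagged on the mapped track;
  shorter gaps are bridged by the linear interpolation inherent in split
  timing.

## Known limitations

Single wrist unit — no left/right asymmetry; no pole-force estimation; no
barometric/GNSS elevation fusion; course profiles must be pre-cut into
sections (no changepoint detection on the altimetry trace); cycle length
is section-mean-based, not per-cycle; heart rate is a proxy for metabolic
intensity with known kinetic delay. The statistical comparisons describe
one athlete's sessions and do not generalise beyond them.
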