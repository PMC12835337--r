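---
title: "Methods: running gait analysis from a single foot-mounted IMU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: running gait analysis from a single foot-mounted IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitIMU)
```

## The estimation problem

A single inertial measurement unit strapped to the instep observes the foot's
specific force and angular velocity in its own (moving) frame. From those two
tri-axial signals the package estimates, per stride: stride velocity (SV, m/s),
stride length (SL, m), stride frequency (SF, steps/min), stride time (ST),
contact time (CT), swing time (SWT), flight time (FT, all seconds), and the
peak vertical ground reaction force (vGRF, multiples of body weight). The
processing chain has four stages, each a classical component of
strapdown pedestrian navigation and IMU gait analysis; what is distinctive is
the fused event detector (here called MFD-GED) that combines gyroscope and
accelerometer event signatures, implemented alongside the conventional
angular-velocity baseline (AVGS) so the two can be compared on equal terms.

## Orientation: Mahony complementary filter

The orientation quaternion $q$ (sensor to navigation, scalar-last) is
propagated from the gyroscope and corrected towards the accelerometer's
gravity direction. At each step the expected gravity in the sensor frame is
$\hat g_s = C_{ns}(q)\,(0,0,g)^\top$ with $g = 9.81$ m/s$^2$ exactly; the
error vector is the cross product $e = \hat a_s \times \hat g_s$ of the
*unit-normalized* measured acceleration and expected gravity, which makes the
correction magnitude scale-invariant and bounded by 1. The corrected rate
$\omega + K_p e + K_i \int e\,dt$ drives a first-order quaternion update
followed by explicit renormalization (which bounds the linearization error;
the norm stays within $10^{-9}$ of 1 over $10^5$ steps in the test suite).
Free-fall or dropout samples (near-zero accelerometer norm) propagate
gyro-only.

Gains: $K_p = 2.0$, $K_i = 0.1$, both exposed in `gait_config()`. $K_p$ is a
conventional mid-range choice — large enough to converge from a cold start
within a couple of seconds of quiet standing, small enough not to chase the
large swing-phase accelerations. $K_i$ was set so that a constant gyroscope
bias of order 0.01 rad/s (consumer-grade) is absorbed by the integral term
within a 20 s recording; much smaller values (e.g. 0.005) leave a visible
residual tilt at that horizon, which the package's own convergence tests
reject.

The initial attitude comes from averaging accelerometer samples over
quasi-stationary periods — samples whose gyro norm is strictly below
0.0436 rad/s (2.5 deg/s) — and rotating that mean onto navigation $+z$ with
zero yaw. Yaw is unobservable without a magnetometer and is irrelevant here:
stride length is taken as the horizontal *resultant*, which is invariant to
heading.

Gravity compensation then yields navigation-frame acceleration
$a_n = C_{ns}^\top a_s - (0,0,g)^\top$. The orientation filter consumes raw
samples; the 6 Hz event filter below is never applied before integration,
because a low-pass at that corner would visibly shrink double-integrated
displacement amplitudes.

## Event detection

Both detectors run on zero-phase filtered signals: fourth-order Butterworth,
6 Hz corner, applied forward and backward. Zero phase matters because a
causal pass would delay every event timestamp by a signal-dependent group
delay; the cost is that the effective attenuation is the squared single-pass
magnitude. The implementation pads edges by odd reflection with steady-state
initial conditions, so constants pass through exactly and filtered extrema
are not displaced.

**Stride segmentation (MSW).** Positive local maxima of the sagittal
(medial-lateral axis) angular velocity $\omega_x$ above the adaptive
threshold $\bar\omega_x + k_\sigma \mathrm{SD}(\omega_x)$, with
$k_\sigma = 1$, deduplicated at a minimum separation of 0.4 s (running
stride times are 0.6–1.0 s; ties resolve to the larger, then earlier peak).
Consecutive mid-swing peaks delimit strides.

**Initial contact.** The AVGS baseline takes the negative $\omega_x$ peak
after mid-swing (searched over the first half of the stride window, so the
following toe-off dip cannot capture it); its classical refinement is the
first positive-to-non-positive zero crossing, linearly interpolated. The
fused detector searches a window of 30% of the stride duration centred on
the AVGS estimate and combines two candidates: the zero crossing nearest the
coarse estimate (kinematic, phase-stable) and the largest-magnitude
anterior-posterior acceleration peak (kinetic — the braking impact
transient, temporally sharp, and sign-agnostic so both rearfoot and
forefoot strikes trigger it). The final timestamp is the weighted mean with
weight 0.7 on the acceleration candidate. The weights are a design choice
(dominance of the kinetic marker), config-exposed, and deliberately not 1.0:
the kinematic candidate tethers the estimate when the impact peak is
distorted.

**Terminal contact.** A forward window of 10%–60% of the stride after IC
(bracketing plausible running contact ratios) is searched for the toe-off
dip (the $\omega_x$ minimum; this is the AVGS toe-off), the curvature
inflection *entering the dip's valley floor* — the zero crossing of the
second difference from negative to non-negative nearest the minimum — as the
kinematic candidate, and the positive (propulsive) anterior-posterior
acceleration peak as the kinetic candidate; the fused TC is again their
0.7/0.3 weighted mean. The crossing direction is pinned deliberately: a
smooth dip has inflections on *both* shoulders at near-equal distances from
its minimum, so "nearest inflection" without a direction is a coin flip that
geometry and noise can toss either way; the entry-side crossing is unique
and stable.

**Mid-stance.** Over the stance with its first and last 10% trimmed, a
sliding window of 30% of stance length minimizes (a) mean tri-axial
angular-velocity energy and (b) horizontal-plane (navigation $x,y$)
acceleration variance. The two window centres $t_\omega$ and $t_v$ are
blended with the adaptive weight
$w = \sigma_a^2 / (\sigma_a^2 + |\sigma_a^2 - \sigma_{a,\mathrm{prev}}^2|)$,
clamped to $[0,1]$; the absolute value and the clamp guard the printed form
of this weight against negative or exploding values when the variance
changes sharply between strides. The first stride initializes
$\sigma_{a,\mathrm{prev}}^2 := \sigma_a^2$, giving $w = 1$. Ties in either
detector resolve to the earliest window. Too-short stances fall back to the
stance midpoint with a flag.

## Stride reconstruction (ZUPT)

Navigation-frame acceleration is integrated (cumulative trapezoid) between
consecutive *mid-stance* anchors with zero initial velocity — the
zero-velocity-update assumption is physically valid only at mid-stance, not
at mid-swing, which is why MS anchors are the default (`integration$anchors`;
the mid-swing alternative is retained behind the switch). The endpoint
velocity error is redistributed linearly, $v_j \mapsto v_j - (j/n) v_n$ per
axis, which zeroes both boundaries exactly, annihilates any purely linear
drift, and is idempotent. A second trapezoid gives the displacement;
$SL = \sqrt{d_x^2 + d_y^2}$ uses horizontal components only. Only zero
*velocity* is enforced at the anchors; zero acceleration, though part of the
idealized ZUPT premise, is not enforceable on measured data and is not
assumed anywhere.

## Parameters and the spring-mass force model

With contacts $t_{IC,i} < t_{TC,i} < t_{IC,i+1}$:
$ST = t_{IC,i+1} - t_{IC,i}$, $CT = t_{TC,i} - t_{IC,i}$,
$SWT = t_{IC,i+1} - t_{TC,i}$, $SF = 120/ST$ (two steps per stride),
$SV = SL/ST$. A single instrumented foot cannot observe the contralateral
contact, so flight time uses the symmetry assumption $FT = (SWT - CT)/2$.
The parenthesization is fixed by arithmetic on typical running values:
$SWT = 0.432$, $CT = 0.308$ give $FT = 0.062$ s, consistent with observed
running flight times, whereas the alternative reading $SWT - CT/2 = 0.278$ s
is not. Negative FT (grounded gait) is reported with a `no_flight` flag, not
clamped — except inside the force model, which clamps it to zero to stay
physical.

The stance vGRF is modelled as the spring-loaded inverted pendulum (SLIP)
half-sine $F(t) = \frac{\pi}{2} m g (FT/CT + 1) \sin(\pi t / CT)$, zero at
touchdown and toe-off, with peak $F_{max} = \frac{\pi}{2}(FT/CT + 1)$ body
weights. The sine argument $\pi t/CT$ is the only form consistent with
$F(0) = F(CT) = 0$; its time integral over stance, $m g (CT + FT)$, is the
impulse a symmetric runner must deliver per stance, and the test suite
verifies both identities numerically.

## Agreement statistics

`agreement_report()` computes the validation set used for wearable gait
systems, with differences oriented reference minus estimate: Bland-Altman
bias and 95% limits of agreement ($\pm 1.96$ sample SD), MAE, a normal-theory
95% CI of the bias ($\pm 1.96\,SE$, not a $t$ quantile — matching the common
reporting convention), Pearson's $r$, the two-way mixed-model consistency
ICC in both single-rating and mean-of-$k$ forms, a paired $t$ test and
Cohen's $d$. Both ICC forms are always emitted because the field's reporting
is genuinely ambiguous between ICC(3,1) and ICC(3,k) labels; emitting both
surfaces rather than resolves that ambiguity. Shapiro-Wilk normality of the
differences is reported informationally and never gates anything.

## The synthetic gait generator

No public raw data exist for foot-mounted IMU running trials with
synchronized force-plate truth, so `simulate_run()` builds one from first
principles: a planar sagittal foot trajectory composed of raised-cosine
acceleration and pitch-rate pulses,

* quiet stance (exact zero velocity — the ZUPT premise made literal),
* a propulsive acceleration pulse around toe-off and a braking pulse at
  landing, whose amplitudes solve exactly for the prescribed stride length,
* a pitch-rate profile with the classic foot signature: a sharp-onset
  plantarflexion dip at toe-off whose recovery spans ~65% of swing (one
  continuous feature, hence a single valley-floor inflection), a positive
  mid-swing peak (default 8 rad/s), a small terminal dorsiflexion bump, and
  a landing dip; pulse areas balance so net pitch per cycle is exactly zero,
* gravity projected analytically into the rotating sensor frame, plus
  seeded Gaussian noise (defaults $\sigma_{acc} = 0.3$ m/s$^2$,
  $\sigma_{gyr} = 0.01$ rad/s) and a constant gyro bias (0.005 rad/s,
  random fixed direction) of consumer-IMU magnitude.

Defaults reproduce the population means of comfortable-speed overground
running: stride time 0.740 s, contact 0.308 s, stride length 1.929 m
(≈2.6 m/s), 200 Hz sampling, 2% stride-to-stride variability. Because the
sensor signals derive from one analytic trajectory, every event time and
parameter is known exactly and double-integrating the noise-free
acceleration reproduces the stride length to under 0.1 mm.

Pulse placement follows impact physiology and is a fixed convention of the
generator, documented here because downstream timing statistics depend on
it: the braking acceleration peak sits 15 ms after touchdown and the
propulsive peak 20 ms after toe-off (impact transients peak slightly after
the contact change, not at it); the rearfoot landing dip is centred 5 ms
after touchdown, while the forefoot variant attenuates that dip (8 → 2.5
rad/s) and advances it to 45 ms *before* touchdown with a nearly unshifted
braking peak — the failure mode that makes angular-velocity-only detection
trigger early on forefoot strikers, and exactly the regime where the fused
detector's acceleration weighting pays off.

What the generator does *not* emulate: soft-tissue and mounting resonance,
magnetometer-visible heading drift, treadmill belt dynamics, medio-lateral
foot motion, curved running paths, and pathological or walking gait.
Passing recovery tests on this generator therefore demonstrates internal
consistency of the pipeline under its stated assumptions — not clinical
validity on human data. Two of its conventions deliberately trade textbook
idealization for detectability: stance is only ~60% gyro-stationary
(the landing and toe-off dips necessarily overlap the stance edges, as real
feet do during loading and push-off; the middle third is exactly still),
and the AVGS baseline lands ~10–20 ms from truth on rearfoot signals rather
than exactly on it, because a 6 Hz zero-phase filter cannot keep a dip
narrow enough for sharper agreement.

## Numerical choices and degenerate inputs

* Units are converted from declared input units (g, deg/s) only — never
  guessed from magnitudes.
* Sub-sample event times are kept as float seconds; zero crossings are
  linearly interpolated.
* Quaternion validity is enforced at $10^{-6}$ on entry to rotations and
  restored by renormalization each filter step.
* Empty recordings, missing stationary periods, absent zero crossings,
  too-short stances, stances shorter than the mid-stance window, negative
  flight times, and zero-variance correlation inputs all produce either a
  typed error or a flagged fallback, as listed in each function's
  documentation; flags propagate to the per-stride table.
* Stride alignment between estimate and reference matches nearest initial
  contacts greedily within a 50 ms gate; unmatched strides are dropped with
  a warning rather than imputed.

## Problem sizes in the test suite

The packaged tests run the full pipeline on cohorts chosen to finish
comfortably on one CPU while still exercising every claim: a 15-runner ×
3-trial recovery study with 6 strides per trial (270 strides), one 45-stride
forefoot comparison, a 50-stride drift study, and 200 randomized 3-stride
profiles for the ordering invariant. These sizes are the package's own
choices for a deterministic, reproducible suite; the statistics they produce
(CT bias ≈ 7 ms, SL error ≈ −1.5% ± 1%) are computed fresh on every run and
also by `scripts/acceptance.R`.

## Known limitations

* The fused detector inherits a small systematic CT overestimate (≈5–9 ms
  on rearfoot synthetic data) from the opposing biases of its two IC
  candidates; it does not cancel exactly.
* Peak vGRF is only as good as the SLIP half-sine: real waveforms with
  pronounced impact peaks deviate from it most for rearfoot strikers.
* Heading (yaw) is unobservable; only the horizontal resultant of
  displacement is meaningful, not its direction.
* All validation is against the synthetic generator; no human data ship
  with the package.
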