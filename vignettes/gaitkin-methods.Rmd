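---
title: "Step and stride lengths from body-worn IMUs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Step and stride lengths from body-worn IMUs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitkin)
library(dplyr)
```

`gaitkin` implements a pedestrian dead-reckoning pipeline built on
*multiple* cheap inertial/magnetic sensors strapped to the lower limbs
(pelvis, both thighs, both shanks, both feet), rather than the single
foot-mounted unit of classical strapdown pedestrian navigation. The
chain is: detect gait events from the foot sensors, estimate each
segment's orientation with a Kalman filter, and turn orientations into
step and stride lengths through the forward kinematics of a
five-segment skeletal model. Two acceleration-based step-size
regressions and a per-stride zero-velocity-update (ZUPT) strapdown
filter are included as comparison methods. This vignette records the
models, the tunable parameters and the design decisions; everything
quantitative stated here is computed by the package's test suite or by
`scripts/acceptance.R`.

## Frames and attitude conventions

All attitudes are roll--pitch--yaw Euler angles in the aerospace
(Z-Y-X) sequence relating a sensor body frame (x forward, y right, z
down) to a local-level frame (forward--across--down, arbitrary heading
origin). `dcm_from_euler()` builds the body-to-local direction cosine
matrix; its third row is
$(-\sin\theta,\ \sin\phi\cos\theta,\ \cos\phi\cos\theta)$.
At rest the accelerometer senses $f = C^\top(0,0,-g)$, so
$\phi = \operatorname{atan2}(-f_y, -f_z)$ and
$\theta = \operatorname{atan2}\!\big(f_x, \sqrt{f_y^2+f_z^2}\big)$;
the positive square root keeps pitch in $[-\pi/2, \pi/2]$, and
four-quadrant arctangents are used everywhere else, including the
tilt-compensated magnetic heading. Magnetic declination is ignored:
yaw is a local, arbitrary heading, and all step-size quantities are
invariant under a common yaw rotation. Gravity is fixed at
$g = 9.80665\ \mathrm{m/s^2}$.

## Gait event detection

Quasi-static (foot-flat) intervals of a foot trace are found with a
windowed generalized likelihood ratio test on the accelerometer and
gyroscope jointly,
$$S_k = \frac{1}{N}\sum_{i\in W_k}\left[
  \frac{1}{\sigma_a^2}\Big\|f_i - g\,\frac{\bar f}{\|\bar f\|}\Big\|^2
  + \frac{1}{\sigma_\omega^2}\|\omega_i\|^2\right] < T,$$
with $\bar f$ the window-mean specific force. Decisions that the
standard formulations of this detector leave open, and the choices
made here:

* window placement: centred, odd $N$, default $N = 5$ (about 0.19 s at
  26 Hz), so detection latency is symmetric around foot-flat;
* threshold: $T$ is dimensionless and data-dependent; the default
  $3\times 10^4$ separates standstill from swing by several orders of
  magnitude at the supported noise levels and is exposed in
  `detector_params()`;
* $\bar f$ is the window mean (the standard GLRT form), not a
  longer-horizon gravity estimate;
* mask runs shorter than `min_stance`/`min_swing` (0.2 s defaults) are
  merged into their neighbours to suppress irregular motion.

Each static run paired with the following moving run forms one gait
cycle. Within a cycle the gyroscope *magnitude* is low-pass filtered
(first order, ~5 Hz cutoff, applied forward--backward: a causal single
pass would delay every detected peak by $\alpha/(1-\alpha)$ samples,
which is an artifact of the filter rather than of the gait) and its
peaks are located with a prominence threshold (0.5 rad/s) and a 0.1 s
minimum separation. A swing showing at least two peaks is a proper
step: the first peak is toe-off, the last heel-strike; foot-flat is the
contiguous sub-threshold run from the stance start and heel-off the
last supra-threshold sample scanning back from the stance end. Cycles
with fewer peaks are skipped.

Large turn-on gyro biases (the supported sensor class specifies up to
±20--30 °/s) would saturate $S_k$ at standstill, so the detector and
the filters estimate the constant bias from the initial standstill mean
(`estimate_gyro_bias()`) — standard MEMS practice — and the orientation
filter initialises its bias states from the same quantity.

## The lower-limb orientation filter

The filter stacks, for the pelvis and both thighs and shanks, three
states per axis: attitude $\Psi$, attitude rate $\omega$, and gyro bias
$b$ — 45 states. The transition is linear: angles integrate the rates,
rates persist, and biases decay as a first-order Gauss--Markov process;
the process noise uses the standard white-noise discretisation
($\Delta t^3/3,\ \Delta t^2/2,\ \Delta t$ blocks) for the angle/rate
pair, with the rate block $\Delta t\, S_\omega$ — the discretisation
consistent with the neighbouring $\Delta t^3/3$ and $\Delta t^2/2$
blocks. Body rates are treated as attitude rates
($\omega_{nb}\approx\omega_{ib}$): no earth-rate or transport-rate
terms, appropriate for consumer MEMS.

Three measurement families update the state sequentially (scalar
updates, innovations wrapped to $(-\pi,\pi]$):

* **gyroscope**: observes rate + bias per axis, variance
  $\sigma_\omega^2$;
* **accelerometer tilt**: observes roll and pitch via the at-rest model,
  variances $(2°)^2$;
* **magnetic heading**: observes yaw where a magnetometer is mounted
  (pelvis and right foot in the supported layout), variance $(5°)^2$.
  Yaw is otherwise unobservable and allowed to drift.

Parameter choices that matter, and why:

* `sw` (rate process noise, default 3 (rad/s)²/Hz) is a *motion*
  parameter, not a sensor parameter: it bounds how fast limb rates may
  slew between samples. Walking limb rates change by several rad/s per
  tenth of a second; using the gyroscope's tiny noise density here
  makes the filter treat rates as constants, after which the
  rate/bias pair diverges.
* Tilt updates are gated to quasi-static samples:
  $\big|\,\|f\|-g\,\big| < 0.2\ \mathrm{m/s^2}$ *and*
  $\|\omega - \hat b\| < 0.3$ rad/s. The magnitude test alone admits
  tangentially accelerated samples whose apparent gravity direction is
  tilted by up to $\operatorname{atan}(\|a\|/g)$; the rate gate
  restricts anchoring to the double-support dwells, where the
  measurement is clean.
* During the same quasi-static samples a **zero-angular-rate update**
  (variance $(0.1\ \mathrm{rad/s})^2$) re-anchors the rate states at
  zero. The gyroscope alone observes only rate + bias; without the
  re-anchoring, the Gauss--Markov decay slowly re-attributes turn-on
  bias to the rate states and the unobservable yaw of
  magnetometer-less segments drifts at the residual-bias rate, which
  corrupts the kinematic chain over a minute of walking.
* Initialisation: angles from the mean accelerometer tilt over the
  first second (assumed standstill), yaw 0 (or from the magnetometer
  where present), rates 0, biases from the standstill gyro mean.
  $P_0$ diagonal: $(10°)^2$, $(0.5\ \mathrm{rad/s})^2$,
  $(0.05\ \mathrm{rad/s})^2$.

## Forward kinematics and step sizes

The skeletal model has five segments; the feet are replaced by shanks
extended to the heel. Body-frame segment vectors are
$(0,0,-\ell)$ for shank (heel→knee) and thigh (knee→hip) and
$(0,-\ell_P,0)$ for the pelvis (right hip→left hip), so the zero-angle
pose is a vertical stance. With the stance foot pinned at the origin,
positions accumulate shank→thigh→pelvis→thigh→shank; for left stance
the left/right roles swap. From the chain, per detected swing:

* **step length** — 3-D distance between the heels at heel-strike;
* **stride length** — displacement of the swing foot from toe-off to
  heel-strike (plus the world displacement of the stance anchor, zero
  on a treadmill-fixed stance foot);
* **hip step lengths** — horizontal displacement of the stance-side or
  swing-side hip across the swing. Horizontal rather than 3-D because
  it is the heading-relevant component; the model does not force this
  choice either way.
* the 2-D thigh-only model
  $(\ell_T+\ell_S)\sin|\theta_T| + \ell_T\sin|\theta_T| +
  \ell_S\sin|2\theta_T|$, which substitutes twice the thigh pitch for
  the trailing shank pitch.

Pose read-out uses a settling offset (`eval_offset`, default 0.1 s):
the heel-strike pose is evaluated just *after* heel-strike and the
toe-off pose just *before* toe-off, inside double support where both
heels are grounded and the inter-heel distance is stationary. This
makes the step estimate insensitive to sample-level event-timing
jitter; real double support lasts 0.1--0.15 s at normal speeds, so the
offset stays within it. The first and last steps of a session are
flagged and excluded from summary statistics (treadmill spin-up and
spin-down are not representative).

The empirical models use the gravity-free acceleration magnitude
$a_i = \|f_i\| - g$: the Weinberg step model
$k(a_{max}-a_{min})^{1/4}$ over pelvis-sensor heel-strike-to-heel-strike
windows, and the Kim stride model $k(\sum|a_i|/N)^{1/3}$ over
foot-sensor toe-off-to-heel-strike windows (published default
$k = 0.98$). The window choices match each model's sensor placement;
`calibrate_k()` fits $k$ by least squares through the origin, the
minimiser of squared residuals for a one-parameter proportional model.

## Foot strapdown with per-stride ZUPT

The comparison method mechanizes the raw foot IMU (exact axis-angle
attitude increments, trapezoidal velocity/position integration, gravity
$(0,0,+g)$) and runs a 9-state error-state EKF (attitude, velocity,
position; deliberately *no* bias states) reset for each stride: the
attitude is initialised from the tilt averaged over the preceding
foot-flat with yaw 0 (stride length is yaw-invariant), velocity and
position start at zero at the end of that foot-flat, and a single
zero-velocity update with closed-loop correction is applied at the
first post-swing foot-flat sample. The stride is the endpoint
displacement of the pass — the foot is motionless from heel-strike to
foot-flat, so this equals the toe-off→heel-strike displacement — which
is also why Rauch--Tung--Striebel smoothing changes the trajectory but
not the stride: the smoothed estimate at the final (updated) epoch is
the filtered one by construction. Between samples the signals are
reconstructed with cubic splines and integrated in 4 sub-steps; foot
accelerations during swing peak at tens of m/s², near the limit of
what a 26 Hz log can represent, and the sub-stepping recovers most of
the band-limited part. The residual per-stride aliasing error
(~0.5--2 cm, alternating in sign with the sampling phase of each
stride) is irreducible at this rate and is the main noise-free error
source of this method.

## The synthetic treadmill walk

The simulator is the package's test bed; it emulates the study
conditions (0.82 Hz per-foot cadence, 26 Hz logging, low-cost MEMS
noise) and provides exact ground truth. Design:

* Joint-angle trajectories are C² transitions (quintic smoothstep)
  between mirror poses, alternating feet, with genuine double-support
  *dwells* (~12% of the half-cycle) in which all five segments freeze —
  this is what gives each foot a true foot-flat interval and both feet
  zero velocity during double support. Thigh pitch swings ±25°; the
  stance leg stays straight while the swing shank adds a knee-flexion
  bump (sin³) reaching 45°. Pelvis roll/pitch/yaw move 2/3/5° with the
  step rhythm. The legs are straight at both toe-off and heel-strike;
  the ~2:1 trailing shank:thigh ratio seen in real toe-off poses is
  not reproduced, because with a footless five-segment chain on flat
  ground unequal heel heights at heel-strike would make the ground
  plane drift vertically step over step.
* Node positions follow the FK chain with the stance foot pinned;
  at each heel-strike the pin hands over to the landing foot at its
  landed position (the chain is continuous through the handover).
* The foot sensors pivot about the grounded heel before toe-off
  (heel-off) and after heel-strike (forefoot lowering): the sagittal
  foot rate is three sin³ bumps — negative at toe-off and heel-strike,
  positive mid-swing, with the mid-bump amplitude chosen so each swing
  integrates to zero net rotation. Centring the outer bumps at the
  events means a correct detector finds toe-off and heel-strike at
  their true times; bump widths (30/40/30% of the swing) keep the
  signal representable at the 26 Hz logger rate.
* Angular rates and specific forces are derived on a 20× oversampled
  grid (central differences of the orientation and position histories)
  and decimated, so the emitted signals are dynamically consistent:
  re-differentiating the logged positions reproduces the specific
  forces to the O(dt²) accuracy of the differencing.
* Noise (optional, seeded): white accelerometer/gyroscope noise at the
  data-sheet densities (300--400 µg/√Hz, 0.005--0.01 °/s/√Hz, taken at
  the 13 Hz bandwidth), constant per-axis turn-on gyro biases drawn
  uniformly within ±20 °/s, and 0.3 µT magnetometer noise on the
  pelvis and right-foot field. Kinematics and ground truth are
  noise-independent: different seeds change only the noise.

What passing tests on this generator do and do not show: they verify
the pipeline's internal consistency, its error propagation, and the
relative ranking of methods under data-sheet noise; they cannot show
robustness to soft-tissue artifact, sensor-to-segment misalignment,
magnetic disturbance indoors, or gait variability, none of which the
generator models.

## Problem sizes and numerical choices

The validation walks are ~62 s (49 cycles per foot at 0.82 Hz, the
cycle count a one-minute walk actually contains at that cadence);
property sweeps use 200--1000 random draws under fixed seeds. Angle
innovations are wrapped before the gain multiply; covariances are
symmetrised every step (the suite asserts eigenvalues above −1e−9);
gimbal lock and degenerate inputs (zero specific force, vertical
magnetic field, zero-mean force windows) raise typed errors rather
than producing silent nonsense. Duplicate timestamps within one sensor
are rejected at I/O; per-sample dt comes from the timestamps, so an
irregular logger rate is handled without resampling.

## Known limitations

* Yaw of magnetometer-less segments is unobservable; it is kept
  *bounded* by the zero-angular-rate updates but not accurate, and
  heading-dependent quantities from those segments should not be
  trusted.
* The 2-D thigh-only model inherits its fixed 2:1 shank/thigh
  assumption; on the simulator's straight-leg poses it overestimates
  steps by ~12 cm, a model bias, not a bug.
* At 26 Hz the foot strapdown is aliasing-limited (above); per-stride
  errors of a few cm noise-free and several cm under turn-on bias are
  expected, which is precisely the motivation for the multi-sensor
  kinematic route.
* Turning gaits, running, stairs, and overground heading estimation
  are out of scope.
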