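---
title: "Estimating head kinematics from helmet-shell accelerometers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating head kinematics from helmet-shell accelerometers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During a helmeted head impact — a motorcycle crash, a fall — the quantities
that drive traumatic brain injury are the *head's* linear and rotational
acceleration histories. Sensors rigidly coupled to the head are accurate but
unacceptable to everyday users; sensors in the helmet shell are easy to fit
but measure the *shell's* motion, which differs from the head's because of
liner compression, chin-strap tension and helmet–head friction: the shell
may see peak accelerations several times the head's, and can rotate tens of
degrees relative to it during the event.

`helmetkin` implements a full methodology for recovering head kinematics
from twelve single-axis accelerometers mounted tangentially on the inner
surface of the shell, in orthogonal pairs at six locations:

1. **Scenario design** — stratified (Latin Hypercube) sampling of impact
   conditions over five parameters;
2. **Impact simulation** — a lumped-parameter two-body surrogate that
   generates paired shell-channel / head ground-truth signals;
3. **Signal conditioning** — phaseless SAE J211 channel-frequency-class
   (CFC) filtering;
4. **Estimation** — bidirectional-LSTM sequence-to-sequence networks mapping
   the 12 shell channels to the 3 head acceleration components, one network
   for linear (A) and one for rotational (B) acceleration;
5. **Assessment** — squared-Pearson R² between target and estimated summary
   parameters (component peaks, resultant peaks, HIC, RIC), with an optional
   exclusion of physiologically unsurvivable impacts.

## Scenario space and stratified design

An impact scenario is five numbers: the ground orientation relative to the
(fixed) head frame, obtained by rotating the reference ground plane about
the X-axis by β ∈ [−100°, 100°] and then about the Y-axis by
γ ∈ [−125°, 115°]; the normal and tangential impact-speed components
Vn ∈ [2, 12] m/s and Vt ∈ [3, 18] m/s; and the in-plane orientation
θ ∈ [0°, 360°) of the tangential component. The speed-component ranges span
roughly 13–78 km/h of impact-speed magnitude, the envelope of urban crash
reconstructions.

`lhs_scenarios()` places exactly one sample in each of *n* equal-probability
strata per parameter (a Latin hypercube on the probability scale, via the
`lhs` package) and then maps the stratified uniforms through each
parameter's marginal quantile function. Sampling the orientation angles
uniformly concentrates impact points near the helmet crown; to cover the
lateral, rear and chin regions evenly, the β and γ marginals default to a
**u-shaped density** — symmetric piecewise-linear, with density at the range
ends three times the density at the center (`tail_to_center_ratio = 3`).
The functional form is a design choice of this package: any symmetric
center-thinning density achieves the same spatial-coverage goal, and the
piecewise-linear family has a closed-form quantile function, which keeps the
stratification property exact. θ and the speed components stay uniform.

```{r, eval = FALSE}
library(helmetkin)
scenarios <- lhs_scenarios(2000, seed = 1)
```

## The impact surrogate

High-fidelity finite-element models of a specific helmet and headform are
proprietary, so the package generates data with an explicitly invented — and
fully documented — lumped-parameter surrogate (`simulate_impact()`). It is
not a validated substitute for any particular helmet; it is a physically
consistent generator whose batch statistics are calibrated to the published
envelope of helmeted-impact measurements.

Geometry and bodies. Head and helmet are rigid bodies with spherical contact
surfaces: head radius 0.085 m, mass 4.54 kg and crash-dummy-like principal
inertias (0.0171, 0.0160, 0.0220) kg·m²; shell outer radius 0.135 m, liner
(inner) radius 0.12 m, helmet mass 1.5 kg. Twelve degrees of freedom total;
quaternion attitude; fixed-step RK4 at `dt = 1e-6` s. The step is set by the
stiffest element in the model — the regularized friction of a bottoming-out
liner patch — and was chosen so that the impulse–momentum balance of the
worst-case severe impact closes to better than 0.1 %.

Couplings.

* **Ground contact** on the shell outer sphere: penalty normal force
  `k·δ + c·δ̇` (no adhesion) with regularized Coulomb friction
  `μ Fn tanh(v/v_eps)`, `v_eps = 0.01` m/s.
* **Liner**: 64 radial viscoelastic patch elements on the shell inner
  sphere, active in compression only, each with its own regularized friction
  element driven by the local head-surface slip. The elastic term hardens as
  compression approaches the liner gap —
  `F = k δ (1 + h (δ/g₀)²)` — mimicking the bottoming-out of crushable foam.
* **Chin strap**: a weak centering spring/damper between body centers; the
  strap's only modeled role is keeping the helmet captured.

Gravity is excluded: over a 30 ms event the contact forces exceed weight by
three orders of magnitude, and excluding it makes the no-contact limit
exactly zero-signal, which is also why the virtual accelerometer channels
are plain coordinate accelerations of their attachment points
(`point_acceleration()`, projected onto the two tangential axes per location
by `project_channels()`).

Calibration. The default contact parameters
(`contact_params()`: liner 1.2e4 N/m per patch, hardening 18, μ = 0.5;
ground 2.5e6 N/m, μ = 0.5) were chosen once so that a default 100-scenario
batch shows (i) a median shell-to-head peak-resultant ratio between 2 and
10, the attenuation range reported across helmeted-impact studies, and
(ii) head rotational peaks exceeding 40 krad/s² in roughly 7–10 % of
impacts, so that extreme rotations exist but are rare, matching the
structure of published FE impact datasets. These are batch-statistics
targets, not fits to any specific measurement.

What the surrogate does **not** emulate: shell deformation and its modal
content, padding geometry and fit, strap dynamics, scalp compliance, sensor
noise and mounting resonance. Passing tests therefore demonstrate that the
estimation pipeline recovers kinematics generated by a nonlinear,
friction-coupled two-body system — not that it is field-ready for any
physical helmet.

## Signal conditioning

Crash-test practice filters channels by *channel frequency class*. The CFC
filter here is the SAE J211 2-pole Butterworth with warped coefficients
(design frequency 2.0775 × class), applied forward and backward
(`cfc_filter()`): phaseless, 4-pole effective, unit DC gain, −3 dB near
1.65 × class Hz. Edges are handled by odd-mirror padding of three settling
lengths, then trimmed. Head channels default to CFC 1000, the convention
for head accelerations; the shell-channel class is deliberately an explicit
argument (`helmet_class`) rather than a constant, because no single shell
convention exists across test houses — the package defaults to 1000.

The simulator emits records at 20 kHz, comfortably above what CFC 1000
requires. After filtering, `decimate_record()` reduces the rate (default
choice in the examples: factor 10, to 2 kHz). The surrogate's post-filter
spectral content is far below 1 kHz, so decimation loses nothing, and
ten-fold shorter sequences make recurrent training an order of magnitude
cheaper.

## The estimator

Both networks are sequence-to-sequence stacks built from three layer types
(`estimator_config()`): bidirectional LSTM (forward and backward passes
concatenated), unidirectional LSTM, and time-distributed linear
(fully-connected) layers. The cells are standard LSTMs — forget / input /
output gates with logistic sigmoid, candidate and output squashing with
tanh. The reference architecture (`dann_architecture()`) is
BLSTM(200) – LSTM(200) – LSTM(200) – FC(200) – FC(3); deeper variants
(e.g. four LSTM layers and two FC layers) are expressible through the layer
list. The forward pass, back-propagation through time and the training loop
are implemented in the package (RcppArmadillo), and the gradients are
verified against central finite differences in the test suite.

Training (`train_estimator()`):

* loss: mean squared error over all time steps and components (the monotone
  twin of the RMSE that is monitored on validation data);
* optimizer: RMSprop, mini-batches of 16, smoothing constant 0.99,
  epsilon 1e-8;
* learning rate: 0.001 initially, halved every 45 epochs
  (`lr_schedule()`);
* early stopping: training ends when validation RMSE has not strictly
  improved for 30 consecutive epochs (`stopping_epoch()`), or at 1000
  epochs; the best-validation weights are restored — a deliberate
  strengthening of plain "stop", since the last weights of a stopped run
  are rarely the best ones;
* dropout (default p = 0.5) on non-recurrent connections only, i.e. on the
  activations passed between layers, never on the recurrent state;
* normalization: inputs are z-scored per channel with training-set
  statistics; outputs are scaled by their per-component training standard
  deviation. Unscaled rotational targets are O(10⁴) rad/s² and destabilize
  training; the statistics travel with the fitted model
  (`NormalizationStats`), and predictions are returned in physical units.

Records are trained full-length — the simulator emits uniform-duration
sequences, so no padding or masking machinery is needed.

`fit_pair()` trains the two networks — identical configuration, independent
weights — on the linear and rotational targets respectively.

## Injury metrics and assessment

`hic()` and `ric()` maximize
\((t_2 - t_1)\,\big[\tfrac{1}{t_2-t_1}\int_{t_1}^{t_2} a\,dt\big]^{2.5}\)
over all sample-aligned windows (cumulative trapezoid; optional window bound
for HIC15/HIC36; ties resolved to the earliest start, then the shortest
window). HIC takes the resultant linear acceleration in g, RIC the
rotational resultant in rad/s². The implementation is verified against an
exhaustive O(T²) window search on random signals to 1e-9 relative error.
Component peaks are reported signed (value of largest magnitude, original
sign); resultant peaks are plain maxima.

`assess()` predicts every test record with both networks, computes the
summary parameters on target and estimate, and reports per-quantity squared
Pearson correlation — which, for the ordinary least-squares line of
estimate on target that accompanies it, coincides with the coefficient of
determination. Split hygiene is enforced: the fitted models carry their
training scenario ids, and assessment refuses any overlap. A *reduced*
variant excludes records whose **target** peak rotational resultant exceeds
40 krad/s² — the threshold sits at more than double published
moderate-to-severe injury tolerances, so such impacts are beyond the
device's diagnostic purpose. The rule is defined on the simulated truth,
not the estimate, because its rationale is the physiological limit of the
true motion. Excluding records may move R² either way; the report always
carries both variants, plus a flag for quantities whose regression slope
falls below 1 (systematic underestimation at high severities, a known
failure mode of regression-to-the-mean in sequence models).

## Problem sizes and numerical choices

The package's own validation (test suite and `scripts/acceptance.R`) runs a
scaled-down study: 300 / 50 / 50 train / validation / test records, networks
with 64 hidden units (BLSTM(64) – FC(64) – FC(3)), dropout 0, learning rate
0.005, at most 100 epochs with patience 30, records decimated to 2 kHz.
These sizes were chosen as the smallest at which the pipeline's behavior is
representative — stratified coverage of the full scenario space, a
clear minority of super-threshold rotations, and stable R² — while keeping
a complete desk-scale rerun in minutes. With this configuration the linear
resultant-peak R² lands above 0.85 and the rotational one above 0.7, with
the same qualitative signature reported for FE-trained networks at full
scale: rotational quantities are harder than linear ones, and high-severity
peaks are systematically underestimated.

Numerical details worth knowing:

* the solver aborts (with the failing step named) on non-finite state or
  interpenetration beyond 95 % of the liner gap; `generate_dataset()`
  records such failures in its manifest instead of dropping them silently;
* friction is regularized (tanh), so stick is approximated by creep below
  `v_eps`; this bounds the friction element's effective stiffness and keeps
  the explicit integrator stable;
* LHS determinism: the scenario table is a pure function of `(n, ranges,
  shapes, seed)`; training determinism additionally fixes shuffling and
  dropout streams from the configuration seed;
* the u-shaped quantile function is evaluated in closed form (quadratic
  inversion), so stratification tests can assert *exact* one-per-stratum
  counts.

## Limitations

The estimators are trained and assessed on the surrogate's distribution; no
claim transfers to physical helmets without retraining on validated data.
The surrogate's spheres cannot reproduce location-specific shell compliance,
so the difficulty of the real estimation problem is likely understated. HIC
and RIC are used purely as curve-comparison functionals; the package
deliberately computes no injury-risk probabilities.
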