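---
title: "Methods: image-based 3D sample stabilization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based 3D sample stabilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nanolock)
```

This vignette is the package's account of its science: the estimation
and control models, the parameters that matter, what the virtual
microscope does and does not emulate, and the numerical decisions taken
where the design was genuinely open. It states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## 1. The measurement model

A stabilization camera images a static reference structure through the
microscope objective. The only things that change between frames are
the 3D position of the sample (stage motion + drift), defocus blur, and
camera noise. The estimator's job is to turn one frame into a 3D
displacement estimate relative to a setpoint.

**Normalization.** Every frame is divided by its pixel sum before any
comparison. Slow changes of illumination or camera gain scale all
pixels together; without normalization they leak directly into the
match curves and masquerade as displacement. `normalize_frame()`
enforces this and refuses all-zero frames; the z path additionally
requires normalization *before* sorting, and `sorted_profile()` errors
on unnormalized input to keep the order fixed.

**Lateral axes.** The reference stack for x (or y) holds normalized
frames at 11 stage positions spanning ±100 nm in 20 nm steps. The
unshifted cross-correlation `CC(a,b) = sum(a*b)` between the live frame
and each entry is maximal for the best-matching plane. No shift search
is performed — the stack itself plays the role of the shift axis, which
is what makes the method cheap enough for a ~16 Hz loop on modest
hardware.

Over a ±100 nm window the scene autocorrelation is almost flat
(reference features are micrometers wide), so the raw curve varies by
only ~0.01% of its magnitude. Min–max scaling to [0, 1] removes the
enormous common baseline; the peak position is unaffected.

**Axial axis.** Sorting a frame's pixels discards geometry but retains
the intensity distribution, whose shape varies smoothly with defocus.
The z stack stores sorted profiles at 11 axial positions; the live
profile's MSE against each is convex with its minimum at the current
axial position. The pipeline follows the fixed order: normalize →
flatten → sort → MSE curve → invert (multiply by −1) → min–max scale →
peak fit. Inversion before scaling turns the minimum into a maximum so
one fitting routine serves all three axes.

Because sorting is order-stable on identical multisets, any fixed
spatial permutation applied to the frame leaves the z estimate
bit-identical — asserted as a test, since it is the formal statement of
"the axial readout uses no spatial information".

**Peak fit.** A four-parameter Gaussian `A exp(-(u-mu)^2/(2w^2)) + c`
is fitted to (plane index, scaled value) pairs with
Levenberg–Marquardt (`minpack.lm::nls.lm`). The offset `c` is needed
because scaled curves sit on a strong baseline. Numerical choices,
each of which was forced by observed failures:

* **Fit window.** The fit uses the points within ±3 planes of the
  argmax (ties: lowest index), clipped at the curve ends, rather than
  the full curve. With the peak one plane from the stack edge, the
  far tail of an asymmetric curve pulls the full-curve least-squares
  center inward by up to a quarter plane (≈5 nm at 20 nm spacing); the
  windowed fit reduces this to a few hundredths of a plane. The far
  tail carries no information about the peak position, so nothing is
  lost.
* **Width bound.** `w` is capped at the curve length. On shallow,
  near-parabolic curves the Gaussian family is degenerate: `A, w → ∞`
  with `c → −A` reproduces a parabola with the center unchanged, and
  unbounded fits either run away or exhaust the optimizer.
* **Multi-start.** The width is started both narrow (1 plane) and broad
  (n/4 planes) and the lower-SSR solution wins; a single start can
  settle into a spike or plateau local minimum when the true peak is
  narrow.
* **Boundary argmax.** A peak at either end of the curve means the
  sample has left the stack range; the peak position cannot be
  interpolated there and an out-of-range error is raised. Downstream,
  the axis is flagged invalid.

**Setpoint referencing and calibration.** The error signal is the
displacement relative to the *setpoint frame* captured before stack
acquisition: `e = cal * (displacement - offset)`, where the per-axis
offsets are the setpoint frame's own measured displacements against the
fresh stacks. This cancels drift that occurred while the stacks were
being recorded. The per-axis calibration factors `cal` are estimated by
`calibrate()` from a feedback-off staircase (below) rather than by
manual tuning — an automated equivalent of the same procedure targeting
the same quantity. On the simulator's holey-carbon scene the Gaussian
fit on the shallow lateral curves shrinks displacements by a linear,
scene-dependent factor; the measured factors (~1.14 in x, ~1.06 in y,
~0.99 in z at the 128 px test field) sit in the same band as is typical
for hardware implementations of this estimator class.

## 2. The controller

Discrete-time, per iteration and axis:

```
I  += e
II += I
u   = -(kp*e + ki*I + kii*II)    # clamped to output_limit_nm
```

There is no dt scaling because the loop is iteration-clocked. The
`kii` term (integration of the summed error) is kept an order of
magnitude below `ki`; it removes the residual error a plain PI leaves
under accelerating drifts. Open question resolved: the second-order
term enters with its own independent gain `kii` rather than as a fixed
fraction of `ki` — the two readings are equivalent up to
reparameterization, and an explicit gain is the more transparent
configuration surface.

Defaults `kp = 0.6, ki = 0.05, kii = 0.001` were chosen on the discrete
linear loop model (error halts within ~5 iterations after a step,
undershoot ≈ −10%, averaged step response well described by a delayed
exponential, complete rejection of constant-rate drift). They are
config values, not constants.

Robustness policy: an axis with a failed fit contributes zero
correction and its integrators freeze — a transient estimator fault
must not kick the stage. Integrators are clamped at the stage travel
bound (anti-windup); a non-finite error on an axis claimed valid is an
estimator fault and aborts the update. A loop with no valid axis for
more than `max_consecutive_failures` (default 25) iterations aborts
with a diagnostic.

## 3. The virtual microscope

The simulator exists so the estimator and controller can be tested
end-to-end with known ground truth. It emulates:

* **Reference structures.** A holey carbon film (2 µm holes, 2 µm
  edge-to-edge spacing on a square lattice → 4 µm center pitch, dark
  holes on bright film, bimodal histogram), a sparse bead field, and a
  10 µm tile target. Edges are logistic with ~100 nm width so
  sub-pixel shifts vary pixel values smoothly.
* **Image formation.** The pattern is evaluated analytically on a 4×
  supersampled grid displaced by the lateral position (an exact
  sub-pixel shift — no interpolation kernel and hence no kernel bias),
  area-binned to camera pixels (default 75/78 nm in x/y; anisotropy
  supported), then blurred with an isotropic Gaussian kernel of width
  `w(z) = w0 * sqrt(1 + (zeff/zR)^2)`, `w0 = 500 nm`, `zR = 2000 nm`,
  `zeff = z + defocus_nm`. A margin of 3.5 kernel widths is rendered
  and discarded so structure flows correctly across the ROI border.
* **Noise.** Poisson shot noise with the brightest scene pixel mapped
  to 70% of a 16-bit sensor's saturation (the 60–80% operating band),
  Gaussian read noise, constant offset, clipping.
* **Stage and drift.** First-order settling toward the commanded
  position, travel clamping with a warning flag, and seeded drift
  models (linear, random walk with counter-based seeding, sinusoidal
  for temperature-coupled periodic motion, composites).

The defocus kernel is a *surrogate*, not a physical diffraction model:
the axial estimator only needs a smooth, monotone dependence of the
intensity histogram on |defocus|, which this provides. Two consequences
mirror real behavior and are asserted in tests: exactly in focus the
model is even in z, so the axial readout is sign-blind — the reason the
operating point is a deliberate defocus of ~2 µm, where axial precision
is measurably better than in focus (the acceptance script computes the
ratio). What the simulator does **not** capture: the true scattering
redistribution mechanism, vectorial/astigmatic PSFs, camera warm-up
drifts, fan vibrations, cryo-stage physics, and loop-timing jitter.
Passing tests therefore demonstrate the correctness and closed-loop
behavior of the *computation*, not the performance of any physical
instrument.

Scene geometry parameters are specified in micrometers (the natural
unit for these structures) and converted to nanometers at construction;
all positions, displacements and logs are nanometers throughout.

## 4. Protocols and analysis

**Engagement** captures the setpoint frame, acquires the three stacks
(x, y, z, each with a 100 ms settle buffer per move, converted to
settle iterations at the 62.5 ms loop period), returns the stage to the
start, measures setpoint offsets, and zeroes the integrators. If any
axis fails, nothing is engaged.

**Staircase** (`staircase_protocol()`): after a baseline period the
injected stage offset cycles `+20, 0, −20, 0` nm. Every transition is a
20 nm step and both sides of the setpoint are sampled symmetrically —
this matters for calibration because the estimator's local gain can
differ slightly on either side; one-sided stepping was observed to bias
the z calibration by ~2%. Five cycles give ten steps in each direction.

**Calibration** (`calibrate()`): plateau levels are estimated as the
median of each linearly detrended segment (drift immunity), transition
amplitudes are compared to the commanded 20 nm, and the scale gets a
t-based confidence interval from the per-transition spread. Plateaus
indistinguishable from noise raise an error rather than returning a
garbage factor.

**Step response** (`fit_step_response()`): segments after each
disturbance are aligned, folded by sign, averaged, and fitted with the
delayed exponential that holds `alpha` until dead time `t0` and decays
as `alpha * exp(-(t-t0)/tau)` afterwards. The model is continuous at
`t0` (the response is at its plateau before the loop reacts, zero only
before the disturbance itself). Because the dead-time kink defeats
gradient-based model setup, `alpha` is profiled in closed form over a
(t0, tau) grid and the best grid point is polished with
Levenberg–Marquardt. A flat averaged response or a decay constant
larger than the observable window raises a fit-failure diagnostic.
Recovery after a disturbance is defined as |e| < 3 times the
steady-state sigma, since a bare "noise floor" is not a number.

**Stability statistics** (`stability_stats()`): per-axis standard
deviation over valid samples (invalid samples are excluded, not
zeroed), plus rolling mean/sd over a centered window (default 1000
samples) with a shrink-at-edges policy so the rolling series has one
entry per record; for even windows the window covers
`[i - w/2, i + w/2 - 1]`.

**Drift reduction** (`drift_reduction()`): per-axis rms of
mean-centered tracks of equal duration; factors are rms(off)/rms(on),
and a perfectly still stabilized track reports a lower-bound flag
instead of infinity.

## 5. Problem sizes and reproducibility

The package defaults describe the instrument-scale configuration: a
300 × 300 px ROI, 75/78 nm pixels, 200 nm / 20 nm / 11-plane stacks per
axis, 70% saturation, 2 µm operating defocus, 62.5 ms loop period. The
test suite and the acceptance script run the same pipeline on a
128 × 128 px field (9.6 µm, ~2.4 hole pitches of the holey-carbon
lattice): this is the smallest field at which the lateral match curves
remain well-conditioned — at 96 px the estimator gain leaves the
0.85–1.15 band and lateral-to-axial crosstalk appears — while keeping a
full closed-loop run to seconds. Closed-loop characterizations use 400
iterations; recovery statistics use 200 seeded trials; calibration
coverage uses 100 seeded synthetic staircases.

Every stochastic element consumes an explicit seed: sessions seed the
ambient RNG once, random-walk drift uses counter-based (seed,
iteration) seeding so trajectories are independent of how much noise
the camera consumed, and every loop log embeds its fully resolved
configuration and seed in the header line, from which
`config_from_header()` reproduces the run bit-identically.

## 6. Known limitations

* The estimator's usable range is the stack range minus one step per
  axis; estimates within one plane of the stack edge are noticeably
  compressed toward the interior even with the windowed fit, and beyond
  the edge the axis goes invalid. In closed-loop operation the error is
  held near zero, far from this regime.
* Under simultaneous large displacements on all three axes (each near
  the range edge) a few nanometers of lateral-to-axial crosstalk
  remain: content leaving the field changes the sorted profile. The
  effect shrinks with field size.
* Calibration factors are engage-specific: frozen noise in the
  reference stacks perturbs the effective estimator gain by a few
  percent, which is why calibration is re-measured per engagement
  rather than stored as a constant.
* The TIFF writer stores 32-bit samples with ~2⁻³² quantization;
  stack round-trips are exact to ≈1e−9 absolute rather than
  bit-identical. Loop logs (JSONL) round-trip exactly.
* In-focus engagement can fail outright (the sign-blind regime): the
  axial match curve is nearly flat and its argmax may sit on the
  boundary. This is the expected behavior of the method, not a defect;
  operate at a defocus.
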