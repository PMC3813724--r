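---
title: "Quantifying and modelling mitotic wavefronts in syncytial embryos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and modelling mitotic wavefronts in syncytial embryos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitowave)
```

## The phenomenon and the question

During the early, syncytial division cycles of the *Drosophila* embryo
(roughly cycles 9–13), the surface nuclei do not enter mitosis
simultaneously: mitosis sweeps across the embryo as a wavefront, starting
near the two poles and travelling inward at a well-defined speed.  Two
shape-based markers of the wavefront can be read out from GFP-histone
movies: the onset of metaphase (the chromatin condenses into a compressed
ellipse, the metaphase plate, lying across the embryo's long axis) and the
onset of anaphase (a sudden ~90° flip of the fitted-ellipse orientation
followed by strong elongation and the split into two daughters).  Both
onsets are followed by collective displacements of the nuclei along the
long axis that obey the same wavefront pattern.  Crucially, the wavefront
speed *decreases* from cycle to cycle, by a roughly constant factor per
cycle, while the nuclear spacing shrinks as the number of nuclei doubles.

`mitowave` implements this analysis end to end and asks which class of
excitable-medium model can reproduce the observed slowing: biochemical
signalling (threshold-triggered release of a diffusing chemical species) or
mechanical signalling (threshold-triggered force dipoles in an overdamped
elastic cytoskeleton).

## Synthetic embryos as the testbed

No public raw movies exist for this system, so the package ships a
first-class generator (`place_nuclei()`, `assign_front_onsets()`,
`synthesize_shape_timeline()`, `synthesize_displacements()`,
`render_movie()`, and the orchestrating `synth_embryo_movie()`) whose
output carries full ground truth.  Design choices, in the package's own
terms:

* **Lattice.** Nuclei sit on a jittered triangular lattice because its
  nearest-neighbour spacing is single-valued; spacing follows
  `d_n = d_n0 * 2^(-(n - n0)/nu_spacing)` with `nu_spacing = 2` by
  default — the exact value for density doubling of a planar layer.
  Projection of the curved embryo surface onto the imaging plane would
  make the measured exponent slightly smaller, which is why the generator
  exposes it as a parameter rather than hard-coding 2.
* **Units and conventions.** Physical units (µm, s) everywhere; x runs
  along the long axis with the origin at the left pole; image row 1 is the
  top of the frame; time is `frame_index × frame_interval` at 1 frame/s by
  default, matching 8-bit confocal acquisition at 1 Hz.
* **Shape sequence.** Interphase circle (default radius 2.2 µm) →
  area-preserving metaphase ellipse (aspect 1.8, major axis across the
  embryo) → orientation flip of π/2 with aspect ramping to 3.2 →
  two daughter circles (radius 1.3 µm) at the endpoints of the mother's
  long axis.  The sizes are chosen as realistic condensed-chromatin
  dimensions and deliberately leave the daughters of *adjacent* mothers
  optically resolvable at the default spacings; with larger blobs the
  rendered daughters of neighbouring nuclei merge at half-height, which is
  an imaging limitation, not a tracking one.
* **Displacements.** `dx(t) = A * sign(x_mid - x) * (1 - exp(-(t - t0)/tau))`
  after each nucleus's onset: a monotone relaxation towards a new
  equilibrium, towards the midplane, along x only.
* **Rendering.** Each ellipse becomes an anisotropic Gaussian blob whose
  half-height contour *is* the stated ellipse (the PSF width is added in
  quadrature), so the detector's half-height convention round-trips the
  truth by construction.  Intensities are quantized to 8 bits; Gaussian
  and Poisson noise are optional and seeded.

What the generator does **not** emulate: photobleaching, focus drift,
curved-surface projection, z-sectioning, and the post-anaphase nuclear
reorganisation.  A pipeline that is perfect on these movies is therefore
demonstrably correct in its geometry and bookkeeping, but untested against
those real-data artefacts.

## Detection, tracking, staging

Detection follows the classic contour recipe: optional band-pass
(difference of Gaussians, `bandpass()`), a multi-level contour plot
(16 levels between the 1st and 99th intensity percentiles), the *locally
highest* closed contours (no other closed contour inside) as one seed per
nucleus, and a direct least-squares conic fit (`fit_ellipse()`) to the
closed contour at half-height.  "Half-height" is defined per region as the
midpoint between the local peak and the median intensity on a surrounding
ring, since the raw-image baseline is not otherwise defined; seeds whose
prominence over that background falls below 20% of the frame's intensity
range are discarded as noise.  The minimum-area filter applies to the
half-height contour, where area is physically meaningful.

Linking is greedy mutual-nearest-neighbour with a displacement gate of one
nuclear radius — justified because at 1 frame/s nuclei move far less than
their own radius between frames.  Divisions are recognised when an ended
track was highly elongated (aspect ≥ 2.5) and two nearly circular
detections appear near its long-axis endpoints; all simultaneous divisions
in a frame are resolved by a single global endpoint-candidate assignment
(greedy on distance with uniqueness on both sides) so that adjacent
mothers cannot claim each other's daughters.

Staging converts tracks to onset events.  The staging observable is the
*oriented* axes ratio ρ = (extent along x)/(extent along y), not the raw
a/b, so the anaphase flip maps to ρ crossing 1 — white/black in the
kymograph convention.  Metaphase onset is the first persistent deviation
|ρ − 1| > 0.15 (3 frames); anaphase onset is the first orientation jump
> π/4 followed by non-decreasing aspect.  Both a per-slice detector
(`detect_metaphase_onset()` on slice-averaged ρ, matching the figure-style
analysis) and a per-track detector (`detect_metaphase_onset_track()`,
`stage_tracks()`) are provided; the per-track path is used for wavefront
fitting because each nucleus then contributes an event at its own
position, which is the sharper input for the front fit.  A refractory
exclusion window after each detected event (default half the interphase)
prevents re-detection of the same transition in multi-cycle series.

## Wavefront kinematics

Onset events of one cycle form two lines in the x–t plane.
`fit_two_fronts()` scans candidate split coordinates (event x-values
between the 10th and 90th percentiles), fits least-squares lines `t(x)` on
each side — time is regressed on position because the onset time is the
noisy coordinate — and keeps the split with the smallest total squared
residual; speed = |1/slope|.  A best split whose two slopes share a sign
is diagnosed as single-front data.  Per-cycle statistics follow:
`fit_speed_decay()` (log-linear fit, per-cycle factor `exp(slope)`),
`fit_spacing_law()` (`nu = -1/slope` of `log2 d` vs n, with an infinite-ν
flag for non-decaying spacing), `fit_cycle_durations()`, and
`front_speed_ratio()` with residual-based standard errors (optional seeded
bootstrap).

## The biochemical-signalling model

A nucleus whose local concentration of a signalling species exceeds `C_th`
is triggered and, after a delay `tau_d`, releases a quantity `Q` as a
point pulse; pulses spread by free diffusion (heat kernels, superposed).
The engine (`simulate_chemical_front()`) is event-driven on the *analytic*
field — there is no spatial discretization; threshold crossings are found
by an adaptive time scan plus bisection (tolerance `1e-3·min(tau_d,
d²/D)`).  An explicit finite-difference solver exists in the test suite
purely as an independent oracle; the two agree to better than 2% on a
10-nucleus chain.

Nondimensionalization: `C* = C_th d^dim / Q` (power 3 in three
dimensions) and `v* = v d / D`.  The dimensionless front speed
`v*(C*, tau*)` is measured on a 40-nucleus chain at unit spacing and
diffusion constant — the steady slope of release position vs time over the
far half, with a steadiness check — and cached per session.  Because the
released species never decays, the 2D field at a fixed point grows
logarithmically with the number of past releases; fronts at moderate `C*`
are steady to within the 5% check over 40 spacings, and the
monotonicity of `v*` in `C*` holds throughout the tabulated range.

The model's per-cycle prediction is the paper-level argument in code: with
fixed `(D, C_th, Q)` and spacing halving every two cycles, `C*` falls and
`D/d` rises, so the zero-delay speed *increases* with cycle — the opposite
of the observation.  A delay caps the speed at `d/tau_d` (the simulator
reproduces `v·tau_d/d → 1` in the delay-dominated limit at moderate
`C*`), so a small fixed delay yields a rise-then-level-off crossover, and
only a per-cycle-fitted delay (`fit_delay_per_cycle()`, bisection per
cycle) can match a decaying speed sequence — at the cost of an
unexplained, trendless delay schedule.

## The mechanical-signalling model

The cytoskeleton is a homogeneous linear elastic sheet with drag:
`gamma du/dt = mu lap(u) + (mu + lam) grad(div u) + div S`, i.e. vector
diffusion with transverse and longitudinal constants `D_t = mu/gamma`,
`D_l = (2mu + lam)/gamma`.  A nucleus is triggered when the largest
eigenvalue of the local elastic stress `sigma = lam (div u) I +
mu (grad u + grad uᵀ)` exceeds `sigma_th`; it then switches on its own
force dipole `S = P I + (A/2) R(2phi)` (isotropic plus traceless
anisotropic part), Gaussian-regularized with width `d/4` — sub-spacing but
resolvable on the default grid `h = d/8`.

Numerics: the solver is fully spectral; every Fourier mode is split into
longitudinal and transverse projections and advanced with its **exact**
exponential relaxation towards the source-balanced steady state, so free
relaxation is exact per mode (the mode-decay tests hold to 1e-6),
stability is unconditional, and the time step only controls
activation-time resolution (`dt = 0.01 d²/D_t` by default, refined once
automatically when a front crosses a column in fewer than eight steps).
Dipoles have no monopole moment, so the k = 0 force vanishes identically
and the mean displacement is conserved.  Crossing times are refined by
linear interpolation within a step; simultaneous activations are processed
in (time, x, y, id) order; random anisotropy angles are seeded.  The 2D
constitutive form used is the plane-strain one; the choice is a
convention switchable at the module boundary and does not affect any
dimensionless result.

Boundary conditions: the bulk speed law uses a periodic strip (front
speed is a bulk property).  For embryo-like runs, `bc = "mirror_x"`
doubles the domain and mirrors every source, which enforces a slip wall
(zero normal displacement, zero shear traction) at the two poles — a
stand-in for the stress-free pole surfaces that, like them, transmits no
net x-force; the fully traction-free edge is not implemented and front
speeds near the poles should be read with that in mind.

The dimensionless speed `Psi(sigma*)` with `sigma* = sigma_th d²/P` is
measured like the chemical one (planar front on a periodic strip, far-half
slope, steadiness check, session cache).  The per-cycle prediction couples
it to the concentration argument: filament concentration doubles with the
nuclei each cycle, and the displacement diffusion constant is assumed to
scale as `D_n = D_n0 · 2^(-nu_visc (n - n0))`.  Since `Psi(sigma*_n)` does
not involve `nu_visc` or `D_n0`, fitting `v_n = (D_n/d_n) Psi(sigma*_n)`
to observed speeds (`fit_nu()`) reduces to a linear regression in log
space — least squares in relative speed error, solved in closed form.
`nu_visc = 0` reproduces the chemical model's failure (speeds
non-decreasing); `nu_visc` of order 2–3 gives the observed geometric
slowing.  The first-cycle dimensionless threshold defaults to 0.1 — a
threshold stress of about ten percent of the source stress — which is the
regime where the displacement profile of the passing front is also
reasonable.

## Pipeline and problem sizes

`run_pipeline()` chains the tabular stages: synthetic per-cycle onset
events → per-cycle two-front fits → observed speeds and decay factor →
chemical predictions and per-cycle delay fits → mechanical `nu_visc` fit →
`compare_models()`, which reports per-model log-space residual norms (the
overall speed scale is profiled out) and trend signs, flagging the
chemical zero/fixed-delay modes whenever they predict non-decreasing
speeds against an observed decrease.  Every stochastic stage receives a
seed derived deterministically from the global seed and the stage name, so
a fixed-seed run is bit-identical on re-execution and intermediate CSVs
regenerate identically.

Default problem sizes — 200 events per cycle for kinematics, 40-nucleus
chains for the chemical speed law, a 32 × 4 strip at `h = d/8` for the
mechanical one, and a 220 × 60 µm, ~200-frame movie with ~50 dividing
nuclei for the imaging round trip — were chosen so that each measured
quantity is comfortably inside its statistical tolerance while a full test
run stays fast on a single CPU; all are parameters, not constants.

## Known limitations

* The detector assumes blob-like nuclei; heavily overlapping chromatin
  (for example daughters of adjacent mothers at unrealistically large
  blob-to-spacing ratios) merges at half-height and is not split.
* No gap-closing: a nucleus missed in one frame starts a new track.
* The chemical speed law is tabulated on a chain geometry; a full 2D
  lattice shifts `v*(C*)` by a geometry factor but not its monotonicity
  or scaling collapse.
* The mechanical free-pole boundary is approximated by a slip wall, and
  the medium is strictly linear; the model is not meant to reproduce the
  much larger displacements that follow anaphase, when the cytoskeleton
  is rebuilt.
* Timing-clock alternatives to excitable-front propagation are out of
  scope; the model comparison here is between the two propagation
  mechanisms.
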