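---
title: "Shoot-through static proton arcs: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shoot-through static proton arcs: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`starc` is a desk-scale planning and simulation toolkit for upright static
proton arcs augmented with *shoot-through* (ST) layers: for each of the
discrete beam directions of a step-and-shoot arc, one extra energy layer at
the machine's maximum energy (230 MeV) whose protons traverse the whole
patient, deposit only plateau dose inside, and exit with a measurable
residual range. The ST layers serve two purposes at once. Dosimetrically,
energy selection in the nozzle makes low-energy spots broad, while the
230 MeV spots stay narrow; giving the optimizer narrow transmission beamlets
at the field edge sharpens the lateral penumbra without a mechanical
collimator. Diagnostically, the exiting protons can be ranged by a detector
behind the patient, turning every fraction into a water-equivalent-thickness
(WET) measurement along hundreds of rays.

This vignette documents the models the package implements, the tunable
parameters, the numerical choices, and what the synthetic phantom does and
does not probe. All empirical statements below are the ones computed by the
package's own test suite and acceptance script.

## The virtual phantom

`build_phantom()` rasterizes a fully specified geometry onto an isotropic
stopping-power-ratio (SPR) grid in the patient frame (x = left,
y = anterior, z = superior, cm; half-open voxel boxes, 0-based indices).
The body is a water ellipsoid with half-axes 10 x 8.5 x 10 cm; inscribed are
an air cylinder (d = 2 cm, l = 5 cm), a bone cylinder (d = 3.5 cm,
l = 8 cm), an OAR ellipsoid (half-axes 2 x 3 x 4 cm) anterior of the
target, and one of three targets centred at the origin: a 3 cm cube
(27 cm^3), a 4.5 cm H-shaped block (60.75 cm^3) and a 6 cm H-shaped block
(168 cm^3). SPR values are water 1.0, air 0.001, bone 1.6 — standard
clinical magnitudes.

Placement of the inclusions is a declared design choice (air cylinder
centred at (+5.5, +3, 0), bone at (-5, -3, 0), both with axes along x; OAR
at (0, +5, 0), abutting the target anteriorly with the H-notch facing it):
the layout guarantees that some beam directions traverse air and bone while
others see homogeneous water. The bone cylinder's far corner would poke
slightly outside the body ellipsoid, so every inclusion mask is clipped to
the External contour at rasterization; this also enforces the containment
invariant that all ROIs are subsets of External. Default spacing is
0.25 cm; all shipped tests and the acceptance script run at 0.5 cm, where a
full verification chain takes seconds and an optimization chain minutes on
one core. Rasterized volumes converge to the analytic solids as the grid is
refined (checked at both spacings).

An `asymmetric = TRUE` variant welds a 4 cm-radius half-cylinder "shoulder"
onto the right-inferior body surface. It is a synthetic stand-in for
patient anatomy change (no CT is shipped or read): displacing it by 2 cm
exercises the anatomy-change detection scenario.

## Machine model

`beam_model()` encodes the deliverable machine:

* **Range-energy**: Bragg-Kleeman `R = 0.0022 E^1.77` (R in cm, E in MeV),
  5-230 MeV. R(230) = 33.3 cm exceeds any phantom chord, so ST protons
  always exit.
* **Energy ladder**: 64 levels uniform in range between R(5) and R(230)
  (~0.53 cm spacing). The physical machine selects energy with binary
  degrader plates close to the patient; 64 levels keeps layer spacing below
  the voxel scale of the phantom. The count is a declared choice, not a
  published machine datum.
* **Depth dose**: the fluence-derivative profile `(R - z)^(1/p - 1)`
  convolved with a range-straggling Gaussian `sigma_R = 0.012 R^0.935` cm
  and normalized to unit depth integral. The integrable singularity at
  `z = R` is integrated exactly per bin before smearing, and the profile is
  continued to negative depths before convolution so the entrance value has
  no edge artifact. For 230 MeV the curve varies by less than a factor 1.5
  over any 20 cm chord — the quasi-flat ST plateau.
* **Lateral spread**: entrance sigma `0.40 + 0.90 (1 - (E-5)/225)` cm
  (0.40 cm at 230 MeV, 1.30 cm at 5 MeV), quadrature-summed with in-patient
  scattering `0.021 R (wed/R)^1.5` cm (~2.1% of range at end of range).
  The entrance model encodes the premise that nozzle energy selection
  broadens low-energy beams; the numbers are plausible magnitudes for a
  degrader-based system, declared rather than commissioned.
* **Monitor units**: 0.0683 MU = 5.63e6 protons — the minimum deliverable
  spot — giving 8.24e7 protons/MU; charge via the elementary charge. A
  constant RBE of 1.1 multiplies all dose.
* **Absolute calibration**: a single constant (6 Gy cm^3/MU) chosen so an
  optimized phantom plan totals a few thousand MU. Every reported metric
  (CI, HI, percentages, ratios) is relative, so this constant only sets the
  MU scale and, weakly, beam-on time.

The dose engine is an analytic pencil beam, not Monte Carlo: each spot
deposits `calib * DD(wed) * Gaussian(r; sigma(E, wed)) * T_aperture * 1.1`
per MU, with the water-equivalent depth taken from the spot's central-axis
ray (computed by exact voxel-walking). Kernels are cut at 3.5 lateral sigma.
Consequences: no nuclear halo, no lateral distortion from heterogeneity
off-axis, and absolute plan metrics (e.g. CI ~0.5 on the 5 mm grid with this
beam's 0.9-1.0 cm Bragg sigmas) are *not* comparable to published values
from commercial Monte-Carlo engines with sharper beams — only trends across
plan types are.

## Plans and optimization

A plan is a tibble of spots: 20 uniformly spaced directions (0 deg = beam
from anterior, clockwise from superior), per direction an initial budget of
24 Bragg layers sampling the target's WET interval uniformly in range
(deduplicated against the 64-level ladder; on the 5 mm phantom ~8-9 unique
layers per direction survive deduplication), spots on a rectangular 0.6 cm
lattice covering each layer's WET-slab projection dilated by
`margin_factor * sigma_air(E)` (1.0 uncollimated, 1.25 collimated).
`add_st_layer()` appends one 230 MeV layer per direction covering the full
target projection. Collimated plans get a per-layer aperture: the dilated
projection as a binary field with an error-function edge
(`edge_sigma` = 0.1 cm), evaluated at each voxel's beam's-eye-view position.

The objective set mirrors the study configuration: robust uniform dose
(60 GyRBE, weight 20), robust min-DVH 60 to 95% (weight 5) and max-DVH 60
to 2% (weight 10) on the CTV, robust max-EUD (A = 1) of 4 GyRBE on the OAR
(weight 3), and two non-robust dose fall-offs on the External (60 to 0 over
1 cm, weight 0.5; 60 to 10 over 0.5 cm, weight 1), the fall-off weights
scalable by a factor 1-4. Robustness is minimax over nine optimization
scenarios (nominal, six axial 3 mm shifts, +/-3.5% SPR), evaluated per
term. The DVH penalties use the classic "cheapest-to-fix" construction —
only violators beyond the allowed volume count are penalized — normalized
by ROI size so the gradient stays continuous as the violation set changes.

Weights are optimized in phases by bound-constrained quasi-Newton descent
(L-BFGS-B) from a deterministic warm start (uniform at twice the MU floor,
scaled to put the CTV mean at prescription): all spots; then energy-layer
filtering (keep the largest-MU Bragg layers down to the 240-layer budget,
ST layers exempt, each direction keeping its strongest layer); then
minimum-MU spot filtering; then re-optimization; finally sub-floor
stragglers are dropped and the survivors re-optimized with the floor as a
hard lower bound, starting from the naively clipped point so the result can
never be worse than naive clipping. Setup-shift scenarios translate the
beam geometry rather than resampling the patient grid, keeping influence
columns artefact-free; density errors scale the SPR globally (the package
deliberately uses one semantics for both optimization and evaluation
perturbations).

Because every term is piecewise smooth (minimax and DVH sets introduce
kinks), the line search typically terminates at a kink after the objective
has plateaued; the recorded history keeps only accepted, improving values
and is non-increasing by construction. Iteration caps default to 200 per
phase, tolerance 1e-6 relative; the seed only matters for APIs downstream
(initialization is deterministic).

## Evaluation, timing and range verification

`plan_metrics()` reports the study's table columns: layer/spot counts, ST
percentage of irradiated protons (MU fraction — identical by linearity),
total protons, delivery time, Paddick CI
(`overlap^2 / (|TV| |PIV|)` with PIV scored inside the patient), HI
(`D95/D5` on raw voxel samples; `D_v` is the (floor(Nv/100)+1)-th largest
dose, the reproducible integer convention), mean External dose, and the
worst-case CTV D95 over 28 evaluation scenarios: 14 shift directions
(6 axial + 8 diagonals, all normalized to 3 mm) crossed with +/-3.5% SPR.
The 28-member composition is not published; this 14 x 2 factorization is
the only natural one with the stated magnitudes and is declared as such.

Delivery time follows the positioner/nozzle parameters (6 deg/s with
5 deg/s^2, trapezoidal or triangular profile per step; 0.2 s energy switch;
600 mm/s serpentine scanning; 55 nC/s beam current; 500 mm/s aperture
leaves, with per-layer leaf travel bounded by the Hausdorff displacement of
consecutive contours). Park-to-start counts as one nominal step. A
20-direction arc therefore spends 84 s rotating regardless of spot count;
collimation can only add time — the mechanism behind the finding that
ST-based plans, which need no aperture, deliver faster.

Range verification simulates the measurement the concept relies on: for
each ST spot, the residual range is `R_max - WET` along its parallel ray
(source at infinity — the nozzle geometry is unspecified, and parallel rays
keep the WET geometry exact), once on the planning grid and once on a
perturbed grid standing in for the measurement. The per-spot statistic is
`(r_plan - r_meas) / (R_max - r_plan)`, i.e. the relative WET change.
Summaries per angle use Tukey box-plot conventions (whiskers at the most
extreme data within 1.5 IQR); spot maps cap the display at +/-15%. Spots
whose planned ray misses the body have an undefined statistic (vanishing
denominator) and are flagged, reported as zero, and excluded from
summaries. The detector is ideal; a Gaussian range-noise sigma is available
for sensitivity studies but defaults to zero.

Three analytic properties anchor the simulator and are asserted in the
tests: a uniform SPR scale by 1+s yields exactly s for every body-crossing
spot (the acceptance script reproduces the 5% scenario as 5.0%); swapping
the two grids maps the statistic to
`-delta (R_max - r_plan)/(R_max - r_plan')`; and a rigid anterior shift of
the ellipsoid leaves the 0/180 deg medians at zero by symmetry while the
largest |median| appears within one direction step of 90/270 deg — on a
symmetric phantom the medians at exactly 90/270 also vanish by left-right
symmetry, so the extreme sits at the adjacent directions, consistent with
the perpendicular-shift sensitivity the concept predicts.

## Numerical choices and degenerate inputs

* WET uses exact Siddon voxel walking; a 0.01 cm step-summation oracle
  agrees to <0.5% on random oblique rays through the heterogeneous phantom.
* Geometry shifts round to whole voxel pitches (nearest-neighbour), which
  preserves material classes exactly; sub-voxel rigid shifts are therefore
  quantized at 0.5 cm spacing — use finer grids if sub-voxel setup errors
  matter. Beam-side shifts in the dose engine are continuous.
* Sub-volume displacement vacates to air and overwrites at the
  destination; a destination outside the grid is an error.
* Layer-slab assignment windows each Bragg layer at half the inter-layer
  range spacing; empty projections yield empty layers, not errors.
* Aperture transmission is bilinear on a 0.25 cm field grid with signed
  distance to the contour; points outside the field grid are opaque.
* Ties in layer filtering break toward lower energy; serpentine ordering
  sorts rows by v then alternates u direction.

## What the phantom results do and do not show

The synthetic phantom emulates controlled heterogeneity (air/bone
inclusions), a fully specified target/OAR geometry, and exact perturbation
scenarios; determinism makes every number reproducible to the byte. It does
not emulate real CT noise and calibration uncertainty, nuclear interaction
products, organ deformation (perturbations are rigid or piecewise-rigid),
detector physics, or patient-realistic anatomy — the published
patient-case numbers (delivery minutes, patient CI/HI values, per-angle
error maxima tied to a specific anatomy) are outside what this package can
or tries to reproduce. Passing tests demonstrate the *mechanisms*:
transmission layers sharpen penumbra enough that collimation adds little
for ST arcs on this phantom (CI ordering Arc+ST >= Arc uncollimated,
External mean dose Arc+ST >= Arc+Coll), and the range-verification
statistic detects global SPR errors exactly, setup shifts directionally,
and local anatomy changes only where rays cross them.

Problem sizes in the shipped tests (0.5 cm grid, 20 directions, CTV_small,
~6-7k spots, nine robust scenarios) are the package's chosen desk-scale
study conditions; the same code runs the 0.25 cm geometry unchanged.
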