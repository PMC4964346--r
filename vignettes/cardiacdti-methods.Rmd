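---
title: "Models and numerical methods in cardiacdti"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in cardiacdti}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cardiacdti` simulates and analyses high-resolution *ex vivo* cardiac DTI.
This vignette records the models behind each stage, the parameters that
matter, and the numerical and design decisions a maintainer would want to
know — especially where the design was genuinely open.

## Sequence model

A pulsed-gradient spin-echo (PGSE) acquisition is described by a rectangular
diffusion lobe pair (duration δ = 2 ms, start-to-start separation
Δ = 5.5 ms, amplitude G in T/m along a unit direction) placed symmetrically
about the refocusing pulse, plus an optional symmetric rectangular crusher
pair flanking the pulse (duration 1.5 ms and gap 0.2 ms by default, axis +z).
The effective gradient is sign-inverted after the refocusing pulse; q(t) is
accumulated per waveform *source* (diffusion vs. imaging/crusher), and
b = ∫qqᵀdt is integrated exactly per piecewise-constant segment, giving full
3×3 matrices for the diffusion self-term, the imaging self-term and their
interaction. Scalars are traces, in s/mm², and satisfy
b_eff = b_d + b_i + b_c to rounding error — the decomposition is tested
against the Stejskal–Tanner closed form at 1e−9 relative.

Only diffusion and crusher lobes contribute: readout-train gradients are out
of scope, matching the manipulation the model is meant to study (crushers
strengthened until b_imaging = 61 s/mm², or minimized to 12 s/mm², both
reachable via `calibrate_crusher()`). The crusher *shape* is a design choice
— symmetric rectangles with a configurable gap — because published protocols
rarely specify the waveform; consequences that depend on the exact crusher
geometry (e.g. the spread of effective b in an uncorrected scan) are
configuration-dependent and are not asserted anywhere.

Prospective adjustment exploits that b_eff(G) = αG² + βG + b_i is an exact
quadratic: α and β are read off from one evaluation at G = 1, the root is
taken directly, and a Newton loop with the analytic derivative verifies
|b_eff − b_nom| < 0.001·b_nom (it converges in one or two steps; 50
iterations is a hard cap). Directions orthogonal to the crusher axis have
β = 0; anti-parallel directions flip its sign, which the tests use as an
exactness check.

Gradient calibration uses the square law: measured ADC along one axis scales
with the square of that axis' actual gradient amplitude, so the inferred
scaling is s = √(D_meas/D_ref) and the correction factor 1/s. The shipped
cyclooctane reference-diffusivity table is a synthetic stand-in of plausible
magnitude (file name and docs say so); laboratory reference data should
replace it for real calibration.

## The phantom

The left ventricle is a hollow cylinder: wall between radii 1.2 and 2.6 mm,
4.8 mm tall, at 0.1 mm isotropic voxels in a 64³ volume by default (the test
suite uses a 32³, 7-voxel-wall variant for speed; the end-to-end acceptance
checks run the 64³ default). The wall sits in buffer fluid inside a sample
tube; outside the tube is signal-free air. The air region is deliberate:
the segmentation thresholds are normalized to global map maxima, and those
maxima are only meaningful when the field of view contains noise-dominated
voxels, as a real scan's always does.

The transmural depth of the phantom is the analytic Laplace potential of the
annulus, ln(ρ/a)/ln(b/a), so that the prescribed helix-angle ramp
(+60° endo to −60° epi, linear in depth) is linear in the same coordinate
the analysis pipeline recovers. The local frame is (r, c, l) with r pointing
endo→epi, c = l_global × r (counter-clockwise viewed from base) and
l = r × c toward the base; this orientation makes subendocardial HA positive,
the conventional right-handed helix. v₁ follows from HA (and a constant
transverse angle, default 0); v₃ is built by rotating the radial direction
about v₁ by a sheet angle, constant, transmurally ramped, or piecewise over
angular sectors (the latter emits a ground-truth domain id for clustering
validation). Note that with a non-zero helix angle the *measured* sheet
elevation and azimuth of a constant sheet rotation vary with HA — they are
projections — so the clustering validation phantom uses a constant HA, for
which SE and SA are exactly piecewise constant.

Eigenvalues are parameterized as λ = ADC·(1+2a, 1−0.75a, 1−1.25a) (shape
ρ = 0.25 keeps λ₂ > λ₃ strictly so the sheetlet frame is always defined) and
a is solved by bisection so FA hits its target exactly; FA = 0.19 and
ADC = 1.3×10⁻³ mm²/s are the myocardial defaults.

**Buffer diffusivity is 2.2×10⁻³ mm²/s by default**, free water at the
sample's heated steady state near 24 °C (water is ~2.0 at 20 °C and rises
~2.4 %/°C). This is not arbitrary: the segmentation rule
`0 < ADC/max < 0.6` can only pass myocardium at 1.3 if the global ADC
maximum sits comfortably above 1.3/0.6 ≈ 2.17, which is exactly what a
heated buffer plus noise provides. With a 20 °C buffer at 2.0 the rule would
exclude the myocardium outright — a useful reminder that these thresholds
encode the acquisition's temperature regime.

**SNR semantics.** SNR is defined the way it is measured: mean signal over
the standard deviation of a noise-only *magnitude* volume. The generator
therefore sets the complex-channel σ to mean(S)/(SNR·√(2−π/2)) for Rician
noise, so a stack synthesized at `snr_b0 = 47` measures 47 by
`compute_snr()` (round-trip tested at ±5 %). The dynamic-gain acquisition is
emulated with a separate, smaller DW-volume σ (`snr_dw = 24` default, against
the mean myocardial DW signal) and a matching DW-gain noise volume, because a
single σ cannot produce the non-DW/DW SNR pair of a dynamic-gain protocol.

The receiver gain chain is y = quantize(g·x + pre-ADC noise) + post-ADC
noise with g = 10^(dB/20), clipping counted at full scale. The temperature
model is first-order exponential: heating toward the steady state during DW
scans, cooling toward ambient otherwise. The heating time constant defaults
to 17.4 min so that six consecutive 13.5-min warm-up scans reach just beyond
99 % of the steady-state rise; reported per-volume temperatures are
mid-volume values (the representative temperature of a 13.5-min scan), and
the diffusivity factor is 1 + 0.024·(T − T_ref). How much the *non-DW signal
amplitude* changes per °C (a T2/gain confound) is left as configuration with
no default asserted.

## Tensor fitting and uncertainty

The fit minimizes Σ(Sᵢ − S₀e^{−Bᵢ:D})² per voxel by damped Gauss–Newton
(Levenberg diagonal scaling, step acceptance on cost decrease), initialized
from the log-linear solution; the objective is Gaussian even under Rician
noise — a documented approximation, adequate at the SNRs studied but biased
near the noise floor. No positivity constraint is imposed; negative
eigenvalues simply appear in the eigen metrics (as they do in real noisy
fits) and are handled by the masking rules. Voxel loops run in C++
(RcppArmadillo); convergence is declared on relative cost change below
1e−12 within 50 iterations.

Eigenvalues are sorted descending; eigenvector sign is normalized to a
deterministic axial representative. Masking follows the three normalized
open intervals (b0 signal, mean ADC, FA against their global maxima) with a
sheetlet-validity submask at λ₂/λ₃ ≥ 1.05.

The wild bootstrap flips residual signs with i.i.d. Rademacher draws per
voxel-and-volume (a per-volume variant is available) and refits from the
original estimate. Eigenvector correspondence across replicates is by
eigenvalue rank; the mean axis is the principal eigenvector of the mean
dyadic E(vvᵀ), which removes the sign ambiguity, and the 95 % COU is the
95th percentile of acute angles to that axis (a percentile-of-angles
estimator; a fitted-cone variant is not implemented). The estimator is
validated against a direct-sampling oracle on Watson-distributed axes at
0.5°. Default 1000 replicates; the tests use 120–200 replicates on voxel
subsamples, which widens Monte-Carlo error but leaves orderings and
monotonicities intact.

## Frames, angles, regional statistics

The Laplace solve uses the 7-point stencil over wall voxels with Dirichlet
values imposed at voxel *faces* (ghost value at half spacing, coefficient 2):
face-located boundaries cut the discretization bias near endo/epicardium
roughly in half a voxel and are what lets the solver match the analytic
annulus solution within 1 % mean absolute error at the 100 µm grid. Faces
touching neither boundary (wall ends) are reflecting. The sparse system is
solved by Cholesky factorization; a system with no Dirichlet contact errors
out rather than returning an arbitrary constant.

Angles are computed from projections with the axial sign resolved by
flipping the eigenvector so the denominator component is non-negative;
results lie in (−90°, 90°], with −90° folded to +90°. Whether one should
instead use signed atan2 on (−180°, 180°] before folding is a convention
choice; the one above is stated, tested for axial invariance and rotation
equivariance, and applied identically to phantom truth and pipeline output,
so round-trips are exact.

AHA-17 labels divide the long-axis extent above the apical cap into equal
thirds with 6/6/4 sectors from the RV-insertion landmark; segment 17 is the
wall distal to the cavity's apical extent (empty for the capless cylinder).
Transmural profiles take doubled-angle circular means per depth bin and
regress them against the *within-bin mean depth* — not the bin centre —
because under nonuniform transmural sampling the bin-centre regression
inflates the slope; with mean-depth regression a linear ramp is recovered
exactly up to the O(spread³) curvature of circular means. The transmural
range is reported as the fitted-line endpoint difference over depth 0→1,
robust to end-bin noise. Profiles need at least 5 populated bins (10 bins
default); zero-variance profiles report R² = 0 with a flag.

## Tracking and clustering

Streamlines integrate the axial eigenvector field by the midpoint (RK2)
method with trilinear interpolation; every interpolated vector (including
each of the eight corner vectors) is sign-aligned to the incoming direction,
which makes tracking invariant to per-voxel sign flips. Defaults — step of
half a voxel, 35° turning threshold, 0.5 mm minimum length, one seed per
mask voxel — are exposed configuration, since tracking parameters are tool
conventions rather than physics. Output writers cover TrackVis `.trk`
(version 2, voxel-mm convention) and CSV polylines.

Sheetlet clustering maps each angle to the doubled-angle circle
(A* = e^{2iA}), unwraps the phase by region growing over the mask, and
halves it back, so +89° and −89° become neighbours 2° apart. Six features —
x, y, z (mm), unwrapped SE and SA, transmural depth — are scaled by their
bandwidths (10 mm spatial, 0.3 doubled-angle radians ≈ 8.6° in angle units,
10 % depth) and clustered by flat-kernel mean-shift over the unit ball of
the scaled space, with modes merged below half a bandwidth, sub-0.1 mm³
clusters merged into their largest-contact 26-neighbourhood neighbour (ties
to the larger cluster), and a final 3³ mode filter (ties keep the centre
label). A literal 0.3° bandwidth is selectable
(`angle_bandwidth_unit = "deg"`) but makes the angle features dominate all
others by two orders of magnitude; the radian reading is the default for
that reason. Two behaviours worth knowing: a 10 % depth bandwidth
*intentionally* partitions structures that span the wall (the validation
phantom therefore widens the depth bandwidth for its full-depth angular
domains), and a 3D checkerboard is not a tie case for the mode filter — a 3³
neighbourhood holds 13 centre-parity versus 14 opposite-parity voxels, so
strict majority flips interior voxels; genuine ties (truncated boundary
neighbourhoods) keep the centre label.

## What the phantom does and does not emulate

It emulates: the acquisition geometry (61 directions at b = 1000 s/mm², 8
non-DW volumes, 100 µm voxels), Rician magnitude noise at measured-SNR
semantics with static or dynamic gain, gradient miscalibration, gain-chain
quantization and clipping, temperature-driven diffusivity drift, a helical
fibre architecture with prescribed FA/ADC, and sheetlet domains with exact
ground truth. It does not emulate: partial-volume and Gibbs effects, coil
B1 inhomogeneity, eddy currents or susceptibility distortions, vessels and
valves, an anatomically shaped apex (the cylinder has none, so segment 17
is empty by construction), or spatially varying T2. Passing tests therefore
demonstrate correctness of the estimators under the stated noise model, not
robustness to artefacts real data may add.

## Problem sizes and runtime choices

The package's own validation runs the full pipeline on the 64³ default
phantom (about 80,000 wall voxels) and module-level checks on a 32³
variant; bootstrap checks use 120–200 replicates over subsampled voxel sets,
and the mean-shift validation clusters 4000 voxels, all chosen so the whole
suite completes in a couple of minutes while keeping every comparison at
the study's stated conditions (SNR pair 47/24, b = 1000 s/mm², 100 µm
voxels at the default grid).

## Known limitations

Gaussian objective under Rician noise (bias at low SNR); no per-component
Laplace warning for disconnected walls (components are solved jointly, and
a wall with no boundary contact errors out); `classify_lv_boundaries()`
assumes an annulus-like topology per slice; mean-shift is quadratic in the
number of clustered voxels (cap or subsample beyond ~10⁴); and the AHA
sector naming fixes the landmark at the anterior RV insertion without
checking handedness against anatomy — on a synthetic phantom the labels are
conventions, not anatomy.
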