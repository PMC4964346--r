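# cardiacdti

High-resolution *ex vivo* cardiac diffusion tensor imaging (DTI), from
acquisition physics to microstructural statistics, as a tested R pipeline.

## The problem

DTI of fixed hearts at ~100 µm resolution can resolve the helical
arrangement of cardiomyocytes and the laminar sheetlets they assemble into —
but only if a chain of acquisition-physics effects is controlled: crusher and
imaging gradients add cross-terms to the diffusion weighting so the effective
b-value varies by direction; gradient miscalibration biases diffusivities and
inflates anisotropy; the receiver gain chain sets how much ADC quantization
noise contaminates the weak diffusion-weighted (DW) signal; and strong
diffusion gradients heat the sample, drifting its diffusivity by ~2.4 % per
°C. `cardiacdti` is for researchers who want to quantify these effects, test
correction strategies, and run the downstream cardiac analysis — tensor
fitting with eigenvector uncertainty, local-frame angle mapping, AHA-17
regional statistics, tractography, and sheetlet-domain segmentation — against
a synthetic left-ventricle phantom with known ground truth.

## The models

**Effective diffusion weighting.** For a spin-echo sequence with piecewise-
constant gradient lobes, q(t) = γ∫g(t′)dt′ (sign-inverted at the refocusing
pulse) and the b-matrix is b = ∫q(t)q(t)ᵀdt, decomposed by waveform source:

    b_effective = b_diffusion + b_imaging + b_cross-terms

The rectangular PGSE self-term is the Stejskal–Tanner value
γ²G²δ²(Δ − δ/3); the package integrates arbitrary diffusion + crusher lobe
configurations exactly and adjusts G per direction by Newton iteration until
|b_effective − b_nominal| < 0.001·b_nominal, mirroring on-scanner prospective
adjustment. Acquiring a second scan with reversed diffusion-gradient polarity
and taking the voxelwise geometric mean cancels b_cross exactly under the
monoexponential model.

**Tensor estimation.** S = S₀·exp(−B:D) is fitted per voxel by damped
Gauss–Newton nonlinear least squares (log-linear initialization), all 8 non-DW
+ 61 DW volumes simultaneously. Eigenvalues λ₁ ≥ λ₂ ≥ λ₃ with eigenvectors
v₁ (myocyte long axis), v₂ (sheetlet), v₃ (sheetlet normal); FA and mean ADC
follow. Eigenvector precision is estimated by wild bootstrap: residuals are
sign-flipped with i.i.d. Rademacher draws, the tensor refitted (1000
replicates by default), and the 95 % cone of uncertainty (COU) taken as the
95th percentile of angles between each replicate's axis and the principal
eigenvector of the mean dyadic tensor E(vvᵀ).

**Cardiac frames and angles.** A Laplace equation over the wall (endocardium
φ=0, epicardium φ=1) gives the transmural depth and the radial direction r;
c = l_global × r and l = r × c complete the local frame. With components
(v·c, v·r, v·l), the helix angle HA = atan(v_l/v_c) and transverse angle
TA = atan(v_r/v_c) describe v₁; the sheet elevation SE = atan(v_l/v_r) and
sheet azimuth SA = atan(v_c/v_r) describe v₃. Profiles of each angle against
depth are summarized per AHA-17 segment by linearity (R²) and transmural
range.

**Sheetlet domains.** SE/SA maps are unwrapped on the doubled-angle circle
(A* = e^{2iA}), combined with spatial position and transmural depth into six
features, and segmented by flat-kernel mean-shift (bandwidths 10 mm /
0.3 rad doubled-angle / 10 % depth), followed by merging of clusters below
0.1 mm³ and a 3³ mode filter.

## Worked example

```r
library(cardiacdti)

spec   <- phantom_spec(grid_dim = 32, endo_radius = 0.6,
                       epi_radius = 1.3, wall_height = 2.4)
truth  <- generate_lv_phantom(spec)
scheme <- gradient_scheme()          # 8 b0 + 61 directions, b = 1000 s/mm^2

# prospective gradient adjustment against 61 s/mm^2 crushers
adj <- prospective_adjust(scheme, calibrate_crusher(sequence_timing(), 61))
range(adj$table$b_effective)
#> [1] 1000 1000

# synthesize at the dynamic-gain SNR pair, fit, segment
dwi <- synthesize_dwi(truth, scheme, snr_b0 = 47, snr_dw = 24,
                      noise_model = "rician", seed = 1)
fit <- fit_tensor_nlls(dwi)
eig <- eigen_metrics(fit)
seg <- segment_myocardium(fit$s0, eig$mean_adc, eig$fa, eigen = eig)
seg
#> myocardium mask: 10272 voxels; sheetlet-valid 7930 (0.228 excluded by lambda2/lambda3)
mean(eig$fa[seg$mask]); mean(eig$mean_adc[seg$mask])
#> [1] 0.191      # true FA 0.19
#> [1] 1.299      # true mean ADC 1.3e-3 mm^2/s

# transmural frames and angle maps
bnd <- classify_lv_boundaries(seg$mask)
dp  <- solve_laplace_depth(seg$mask, bnd$endo_boundary, bnd$epi_boundary)
fr  <- build_local_frames(dp, global_long_axis(bnd$endo_boundary, 0.1))
am  <- compute_angle_maps(eig, fr)
am
#> angle maps over 10272 voxels (HA -15.7+/-33.3, TA -0.0+/-3.6,
#>                               SE -0.2+/-11.5, SA 0.1+/-8.8 deg)

aha <- aha17_labels(seg$mask, c(0, 0, 1), truth$landmark, 0.1,
                    truth$lv_cavity_mask)
pr  <- transmural_profiles(am, dp$phi, aha)
ha  <- pr[pr$angle == "HA" & pr$flag == "ok", ]
min(ha$r_squared); mean(abs(ha$range_deg))
#> [1] 0.998      # helix ramp linear in every segment
#> [1] 122.8      # fitted endo-to-epi range, true ramp +60 to -60 deg
```

The numbers mean: the recovered myocardial FA and ADC match the phantom's
prescribed values, the segmentation recovers the wall exactly at this noise
level, 22.8 % of wall voxels fail the λ₂/λ₃ ≥ 1.05 sheetlet-definition rule,
and the helix-angle ramp reads back linear (R² ≥ 0.998) with a transmural
range close to the prescribed 120°.

`run_pipeline(pipeline_config(...))` chains all stages (including bootstrap
COU, tracking and clustering) and returns a JSON-serializable report;
`inst/scripts/run_pipeline.R` wraps it for shell use with a YAML config.

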