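# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small LV phantom: 32^3 at 100 um, 7-voxel wall
small_spec <- function(...) {
  phantom_spec(grid_dim = 32, endo_radius = 0.6, epi_radius = 1.3,
               wall_height = 2.4, ...)
}

small_truth <- function() fixture("small_truth", function()
  generate_lv_phantom(small_spec()))

scheme61 <- function() fixture("scheme61", gradient_scheme)

# noise-free synthesis + fit on the small phantom
noisefree_fit <- function() fixture("noisefree_fit", function() {
  dwi <- synthesize_dwi(small_truth(), scheme61(), noise_model = "none")
  fit_tensor_nlls(dwi)
})

# noisy acquisition at the dynamic-gain SNR pair (b0 47 / DW 24)
noisy_dwi <- function() fixture("noisy_dwi", function()
  synthesize_dwi(small_truth(), scheme61(), snr_b0 = 47,
                 noise_model = "rician", seed = 7, snr_dw = 24))

noisy_fit <- function() fixture("noisy_fit", function()
  fit_tensor_nlls(noisy_dwi()))

noisy_eigen <- function() fixture("noisy_eigen", function()
  eigen_metrics(noisy_fit()))

# Laplace depth + frames on the true mask of the small phantom
small_depth <- function() fixture("small_depth", function() {
  tr <- small_truth()
  solve_laplace_depth(tr$myocardium_mask, tr$endo_boundary, tr$epi_boundary)
})

small_frames <- function() fixture("small_frames", function()
  build_local_frames(small_depth(), c(0, 0, 1)))

# angular difference between two axial unit-vector matrices (degrees)
axial_angle_deg <- function(a, b) {
  acos(pmin(abs(rowSums(a * b)), 1)) * 180 / pi
}

mat3 <- function(vol, idx) matrix(vol, ncol = 3)[idx, , drop = FALSE]

unitv <- function(x) x / sqrt(sum(x * x))
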