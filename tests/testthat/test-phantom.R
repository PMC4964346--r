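# LV phantom construction, DW signal synthesis, gain chain and temperature.

test_that("phantom eigenvalues meet the FA and mean-ADC targets exactly", {
  tr <- small_truth()
  lam <- tr$eigenvalues_myocardium
  fa <- sqrt(3 / 2) * sqrt(sum((lam - mean(lam))^2)) / sqrt(sum(lam^2))
  expect_equal(fa, 0.19, tolerance = 1e-6)
  expect_equal(mean(lam), 1.3, tolerance = 1e-6)
  expect_true(lam[2] > lam[3])       # sheetlet frame strictly defined

  # isotropy limit
  expect_equal(solve_eigenvalue_spread(0, 1.3), rep(1.3, 3))
  # infeasible anisotropy
  expect_error(generate_lv_phantom(small_spec(fa_target = 0.99)),
               "infeasible")
  # too-thin wall
  expect_error(phantom_spec(endo_radius = 1.2, epi_radius = 1.35),
               "wall thickness")
})

test_that("helix angle ramps linearly in transmural depth by construction", {
  tr <- small_truth()
  idx <- which(tr$myocardium_mask)
  expect_equal(tr$angles$HA[idx], 60 - 120 * tr$depth[idx], tolerance = 1e-9)
  expect_equal(max(abs(tr$angles$TA[idx])), 0, tolerance = 1e-9)
  # midpoint of the ramp is 0 degrees
  mid <- which(abs(tr$depth - 0.5) < 0.02)
  expect_lt(max(abs(tr$angles$HA[mid])), 2.5)
})

test_that("true tensors reproduce prescribed eigensystem and angles", {
  tr <- small_truth()
  eig <- eigen_metrics(tr$tensors, mask = tr$myocardium_mask)
  idx <- which(tr$myocardium_mask)
  expect_equal(max(abs(eig$fa[idx] - 0.19)), 0, tolerance = 1e-9)
  expect_lt(max(axial_angle_deg(mat3(eig$v1, idx), mat3(tr$v1, idx))), 1e-5)
  expect_lt(max(axial_angle_deg(mat3(eig$v3, idx), mat3(tr$v3, idx))), 1e-5)

  # positive definiteness inside the mask
  expect_gt(min(eig$lambda[, , , 3][idx]), 0)

  # angle round-trip: recomputed from tensors + true frames to 1e-6 degrees
  fr <- build_local_frames(tr$r, c(0, 0, 1), mask = tr$myocardium_mask)
  am <- compute_angle_maps(eig, fr)
  ok <- am$mask & !am$flagged
  for (an in c("HA", "TA", "SE", "SA"))
    expect_lt(max(abs(am[[an]][ok] - tr$angles[[an]][ok])), 1e-6)
})

test_that("noise-free synthesis is inverted exactly by the tensor fit", {
  tr <- small_truth()
  fit <- noisefree_fit()
  idx <- which(tr$myocardium_mask)
  rel <- abs(mat3(fit$tensor[, , , 1:3], idx) -
               mat3(tr$tensors[, , , 1:3], idx)) / 1.3
  expect_lt(max(rel), 1e-8)
  expect_true(all(fit$converged[match(idx, fit$mask_index)]))
})

test_that("gradient miscalibration maps the tensor through S D S", {
  # isotropic buffer fitted with nominal b under actual scale (1, 0.9, 0.9)
  tr <- small_truth()
  dwi <- synthesize_dwi(tr, scheme61(), noise_model = "none",
                        gradient_scale = c(1, 0.9, 0.9))
  fit <- fit_tensor_nlls(dwi)
  buf <- which(tr$buffer_mask)[1:500]
  d <- tr$spec$buffer_adc
  expect_equal(mean(matrix(fit$tensor, ncol = 6)[buf, 1]), d,
               tolerance = 1e-6)
  expect_equal(mean(matrix(fit$tensor, ncol = 6)[buf, 2]), 0.81 * d,
               tolerance = 1e-6)
  expect_equal(mean(matrix(fit$tensor, ncol = 6)[buf, 3]), 0.81 * d,
               tolerance = 1e-6)
  eig <- eigen_metrics(fit)
  expect_equal(mean(eig$fa[tr$buffer_mask]), 0.1249513, tolerance = 1e-4)
  expect_error(synthesize_dwi(tr, scheme61(), noise_model = "none",
                              gradient_scale = c(1, 0, 0.9)),
               "gradient_scale")
})

test_that("rician noise has the Rayleigh mean in signal-free regions", {
  tr <- small_truth()
  dwi <- noisy_dwi()
  air <- tr$air_mask
  expect_gt(sum(air), 1e4)
  sig <- dwi$noise_sd[1]
  expect_equal(mean(dwi$data[, , , 1][air]), sig * sqrt(pi / 2),
               tolerance = 0.02)
  # paired noise-only volume has the same law
  expect_equal(mean(dwi$noise_volume), sig * sqrt(pi / 2), tolerance = 0.02)
})

test_that("fitted buffer FA rises as SNR falls (rician noise floor)", {
  tr <- small_truth()
  fa_at <- function(snr) {
    dwi <- synthesize_dwi(tr, scheme61(), snr_b0 = snr,
                          noise_model = "rician", seed = 5)
    eig <- eigen_metrics(fit_tensor_nlls(dwi, mask = tr$buffer_mask))
    mean(eig$fa[tr$buffer_mask], na.rm = TRUE)
  }
  fa <- vapply(c(50, 24, 10), fa_at, numeric(1))
  expect_true(all(diff(fa) > 0))
})

test_that("receiver gain chain scales, quantizes and clips as specified", {
  # the 2 -> 14 dB step is a 3.98x (about four-fold) amplitude factor
  ch <- gain_chain_spec(gain_db = 12, adc_bits = 24, full_scale = 10)
  out <- apply_gain_chain(c(0.5, 1, 2), ch)
  expect_equal(out$gain_factor, 3.981072, tolerance = 1e-6)
  expect_equal(out$signal_renormalized, c(0.5, 1, 2), tolerance = 1e-5)

  # identity at 0 dB up to the quantization step
  ch0 <- gain_chain_spec(gain_db = 0, adc_bits = 20, full_scale = 1)
  x <- runif(100)
  y <- apply_gain_chain(x, ch0)$signal
  expect_lt(max(abs(y - x)), 1 / 2^20)

  # everything above full scale is clipped and counted
  ch1 <- gain_chain_spec(gain_db = 0, adc_bits = 12, full_scale = 1)
  cl <- apply_gain_chain(rep(2, 50), ch1)
  expect_equal(cl$clipped_fraction, 1)
  expect_true(all(cl$signal == 1))
})

test_that("temperature schedule heats exponentially and scales diffusivity", {
  # no warm-ups and no DW volumes: everything stays at ambient, scale 1
  s <- temperature_schedule(warmup_count = 0)
  out <- simulate_temperature_schedule(s, n_b0 = 8, n_dw = 0)
  expect_equal(out$temperature, rep(20.2, 8))
  expect_equal(out$scale, rep(1, 8))

  # +1 degC is a 2.4% diffusivity increase
  s1 <- temperature_schedule(t_ambient = 20, t_steady = 21,
                             heat_time_constant = 0.01)
  o1 <- simulate_temperature_schedule(s1, n_b0 = 0, n_dw = 1)
  expect_equal(o1$scale[o1$phase == "dw"], 1.024, tolerance = 1e-6)

  # default time constant reaches 99% of the rise at warm-up scan 6
  s6 <- temperature_schedule()
  o6 <- simulate_temperature_schedule(s6, n_b0 = 0, n_dw = 0)
  expect_equal(attr(o6, "steady_volume"), 6)
  expect_lt(max(o6$temperature), 23.8 + 1e-9)

  # interleaving keeps b0 and DW temperatures matched (within 1 degC),
  # and closer than the non-interleaved ordering
  tdiff <- function(interleave) {
    o <- simulate_temperature_schedule(temperature_schedule(), n_b0 = 8,
                                       n_dw = 61, interleave = interleave)
    m <- o[o$phase != "warmup", ]
    abs(mean(m$temperature[m$phase == "b0"]) -
          mean(m$temperature[m$phase == "dw"]))
  }
  expect_lt(tdiff(TRUE), 1)
  expect_lt(tdiff(TRUE), tdiff(FALSE))
  expect_error(temperature_schedule(scan_duration = -1), "positive")
})
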