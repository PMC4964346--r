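# NLLS tensor fitting, eigen metrics, segmentation rules and SNR.

test_that("eigen metrics reproduce closed-form FA values", {
  mk <- function(lam) {
    a <- array(0, c(1, 1, 1, 6))
    a[1, 1, 1, 1:3] <- lam
    eigen_metrics(a)
  }
  expect_equal(mk(c(1, 1, 1))$fa[1], 0)
  expect_equal(mk(c(1, 0, 0))$fa[1], 1)
  expect_equal(mk(c(1, 0.81, 0.81))$fa[1], 0.1249513, tolerance = 1e-6)
  # descending eigenvalues, orthonormal vectors
  a <- array(0, c(1, 1, 1, 6))
  a[1, 1, 1, ] <- c(1.5, 1.1, 0.9, 0.2, -0.1, 0.05)
  e <- mk2 <- eigen_metrics(a)
  lam <- e$lambda[1, 1, 1, ]
  expect_true(all(diff(lam) <= 0))
  V <- cbind(e$v1[1, 1, 1, ], e$v2[1, 1, 1, ], e$v3[1, 1, 1, ])
  expect_equal(crossprod(V), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  # non-finite tensor is flagged, not fatal
  a[1, 1, 1, 1] <- NaN
  expect_true(eigen_metrics(a)$flagged[1])
})

test_that("fit preconditions are enforced", {
  dwi <- noisy_dwi()
  short <- dwi
  short$data <- dwi$data[, , , 1:6, drop = FALSE]
  short$b_matrices <- dwi$b_matrices[1:6, ]
  expect_error(fit_tensor_nlls(short), "insufficient")
  # 7 volumes spanning < 6 independent directions
  degen <- dwi
  degen$data <- dwi$data[, , , c(1, 9, 9, 9, 9, 9, 9)]
  degen$b_matrices <- dwi$b_matrices[c(1, 9, 9, 9, 9, 9, 9), ]
  expect_error(fit_tensor_nlls(degen), "rank")
})

test_that("FA and ADC are invariant under scheme-and-tensor rotation", {
  set.seed(31)
  sch <- scheme61()
  lam <- c(1.6, 1.2, 1.1)
  V <- qr.Q(qr(matrix(rnorm(9), 3)))
  D <- V %*% diag(lam) %*% t(V)
  fit_one <- function(dirs, D) {
    b6 <- t(vapply(seq_len(nrow(dirs)), function(i) {
      B <- 1000 * tcrossprod(dirs[i, ])
      c(B[1, 1], B[2, 2], B[3, 3], B[1, 2], B[1, 3], B[2, 3])
    }, numeric(6)))
    b6 <- rbind(matrix(0, 8, 6), b6)
    w <- b6 * rep(c(1, 1, 1, 2, 2, 2), each = nrow(b6))
    s <- exp(-1e-3 * as.numeric(w %*% c(D[1, 1], D[2, 2], D[3, 3],
                                        D[1, 2], D[1, 3], D[2, 3])))
    stack <- list(data = array(rep(s, each = 1), c(1, 1, 1, length(s))),
                  scheme = sch, b_matrices = b6, voxel_size = 0.1)
    class(stack) <- "dwi_stack"
    eigen_metrics(fit_tensor_nlls(stack))
  }
  e0 <- fit_one(sch$directions, D)
  for (k in 1:5) {
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    eR <- fit_one(sch$directions %*% t(R), R %*% D %*% t(R))
    expect_equal(eR$fa[1], e0$fa[1], tolerance = 1e-9)
    expect_equal(eR$mean_adc[1], e0$mean_adc[1], tolerance = 1e-9)
  }
})

test_that("offset scan scales mean ADC of random orientations by 0.873", {
  # 1e5 randomly oriented anisotropic tensors, synthesized with actual
  # gradient scale (1, 0.9, 0.9) and fitted with the nominal b-matrix:
  # each voxel maps through D -> S D S, so the expected mean-ADC factor is
  # (1 + 0.81 + 0.81)/3
  set.seed(99)
  n <- 1e5
  sch <- scheme61()
  lam <- solve_eigenvalue_spread(0.19, 1.3)
  # random orthonormal triads via QR of gaussian matrices
  b6n <- t(vapply(seq_len(nrow(sch$directions)), function(i) {
    B <- 1000 * tcrossprod(sch$directions[i, ])
    c(B[1, 1], B[2, 2], B[3, 3], B[1, 2], B[1, 3], B[2, 3])
  }, numeric(6)))
  b6n <- rbind(matrix(0, 8, 6), b6n)
  S <- diag(c(1, 0.9, 0.9))
  dirs_act <- sch$directions %*% S
  b6a <- t(vapply(seq_len(nrow(dirs_act)), function(i) {
    B <- 1000 * tcrossprod(dirs_act[i, ])
    c(B[1, 1], B[2, 2], B[3, 3], B[1, 2], B[1, 3], B[2, 3])
  }, numeric(6)))
  b6a <- rbind(matrix(0, 8, 6), b6a)
  wa <- b6a * rep(c(1, 1, 1, 2, 2, 2), each = nrow(b6a))
  D6 <- matrix(0, n, 6)
  G <- array(rnorm(9 * n), c(3, 3, n))
  for (i in seq_len(n)) {
    V <- qr.Q(qr(G[, , i]))
    D <- V %*% diag(lam) %*% t(V)
    D6[i, ] <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
  }
  sig <- exp(-1e-3 * (D6 %*% t(wa)))      # n x nvol, actual gradients
  stack <- list(data = array(t(sig), c(nrow(b6a), 1, 1, n)),
                scheme = sch, b_matrices = b6n, voxel_size = 0.1)
  # reshape to (n,1,1,nvol)
  stack$data <- array(sig, c(n, 1, 1, nrow(b6a)))
  class(stack) <- "dwi_stack"
  eig <- eigen_metrics(fit_tensor_nlls(stack))
  ratio <- mean(eig$mean_adc) / 1.3
  expect_equal(ratio, 0.8733333, tolerance = 0.005)
})

test_that("myocardium segmentation applies the normalized threshold rules", {
  dims <- c(4, 4, 1)
  s0 <- array(1, dims); adc <- array(0.3, dims); fa <- array(0.5, dims)
  s0[1, 1, 1] <- 2       # global max: excluded by the open upper bound
  adc[3, 1, 1] <- 1.12   # global max carrier
  adc[2, 1, 1] <- 0.9 * 1.12   # 0.9 of max: outside (0, 0.6)
  fa[4, 1, 1] <- 0.04    # below 0.1 of max fa (max = 1 below)
  fa[1, 2, 1] <- 1
  seg <- segment_myocardium(s0, adc, fa)
  expect_false(seg$mask[1, 1, 1])          # s0 = global max
  expect_false(seg$mask[2, 1, 1])          # adc 0.9 of max >= 0.6
  expect_false(seg$mask[4, 1, 1])          # fa below 0.1 of max
  expect_true(seg$mask[2, 2, 1])

  # all-zero input: empty mask with a warning
  expect_warning(se <- segment_myocardium(array(0, dims), adc, fa),
                 "empty")
  expect_equal(sum(se$mask), 0)
})

test_that("sheetlet submask applies the lambda2/lambda3 >= 1.05 rule", {
  dims <- c(3, 1, 1)
  lam <- array(0, c(dims, 3))
  lam[1, 1, 1, ] <- c(2, 1.04, 1)    # ratio 1.04: excluded
  lam[2, 1, 1, ] <- c(2, 1.06, 1)    # ratio 1.06: retained
  lam[3, 1, 1, ] <- c(2, 1.5, 1)
  eig <- list(lambda = lam)
  seg <- segment_myocardium(array(c(1, 1, 2), dims),
                            array(c(0.3, 0.3, 1), dims),
                            array(c(0.5, 0.5, 1), dims), eigen = eig)
  expect_true(seg$mask[1, 1, 1] && seg$mask[2, 1, 1])
  expect_false(seg$sheetlet_mask[1, 1, 1])
  expect_true(seg$sheetlet_mask[2, 1, 1])
  expect_equal(seg$excluded_fraction, 0.5)
})

test_that("SNR is mean signal over noise standard deviation", {
  dims <- c(10, 10, 10)
  set.seed(8)
  noise <- array(rnorm(prod(dims)), dims)
  sig <- array(47 * sd(noise), dims)
  mask <- array(TRUE, dims)
  expect_equal(compute_snr(sig, mask, noise), 47)
  expect_error(compute_snr(sig, array(FALSE, dims), noise), "empty mask")
  expect_error(compute_snr(sig, mask, array(1, dims)), "zero-variance")

  # generator round trip: a stack synthesized at snr_b0 = 24 measures 24
  tr <- small_truth()
  dwi <- synthesize_dwi(tr, scheme61(), snr_b0 = 24, noise_model = "rician",
                        seed = 12)
  snr <- compute_snr(dwi$data, tr$myocardium_mask, dwi$noise_volume)
  expect_equal(mean(snr[1:8]), 24, tolerance = 0.05 * 24)
})

test_that("parameter recovery at the acquisition SNR pair is accurate", {
  tr <- small_truth()
  eig <- noisy_eigen()
  idx <- which(tr$myocardium_mask)
  ang <- axial_angle_deg(mat3(eig$v1, idx), mat3(tr$v1, idx))
  expect_lt(median(ang), 5)
  expect_equal(mean(eig$fa[idx]), 0.19, tolerance = 0.02)
  expect_equal(mean(eig$mean_adc[idx]), 1.3, tolerance = 0.02)
})

test_that("segmentation recovers the true myocardium at acquisition SNR", {
  tr <- small_truth()
  fit <- noisy_fit()
  eig <- noisy_eigen()
  seg <- segment_myocardium(fit$s0, eig$mean_adc, eig$fa, eigen = eig)
  tm <- tr$myocardium_mask
  dice <- 2 * sum(seg$mask & tm) / (sum(seg$mask) + sum(tm))
  expect_gte(dice, 0.95)
  expect_gt(seg$excluded_fraction, 0)
})
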