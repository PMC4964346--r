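# Doubled-angle unwrapping, flat-kernel mean-shift, merging, mode filtering.

test_that("doubled-angle unwrapping is continuous across the +/-90 wrap", {
  dims <- c(2, 1, 1)
  mask <- array(TRUE, dims)
  expect_equal(unwrap_angle_features(array(0, dims), mask),
               array(0, dims))
  # +89 and -89 degree neighbours differ by 2 degrees, not 178
  a <- array(c(89, -89), dims)
  u <- unwrap_angle_features(a, mask)
  expect_equal(abs(diff(as.numeric(u))), 2, tolerance = 1e-9)

  # a smooth ramp crossing +/-90 unwraps without jumps
  n <- 60
  ramp_true <- seq(0, 170, length.out = n)          # crosses 90
  folded <- ((ramp_true + 90) %% 180) - 90
  dims2 <- c(n, 1, 1)
  u2 <- unwrap_angle_features(array(folded, dims2), array(TRUE, dims2))
  expect_lt(max(abs(diff(as.numeric(u2)))), 5)
  expect_equal(as.numeric(u2) - u2[1], ramp_true, tolerance = 1e-9)

  # empty mask: empty output
  expect_true(all(is.na(unwrap_angle_features(a, array(FALSE, dims)))))
})

test_that("mean-shift separates well-separated feature blocks", {
  dims <- c(6, 6, 12)
  mask <- array(TRUE, dims)
  # two slabs along z with sheet elevations far beyond the angle bandwidth
  se <- array(c(rep(0, 6 * 6 * 6), rep(60, 6 * 6 * 6)), dims)
  ft <- feature_table(se, array(0, dims), array(0.5, dims), mask,
                      voxel_size = 0.1)
  cl <- flat_meanshift(ft)
  expect_equal(cl$n_clusters, 2)
  expect_equal(length(unique(as.integer(cl$labels[, , 1:6]))), 1)
  expect_false(cl$labels[1, 1, 1] == cl$labels[1, 1, 12])

  # infinite bandwidths: a single cluster
  ft1 <- feature_table(se, array(0, dims), array(0.5, dims), mask,
                       voxel_size = 0.1, spatial_bandwidth = 1e6,
                       angle_bandwidth = 1e6, depth_bandwidth = 1e6)
  expect_equal(flat_meanshift(ft1)$n_clusters, 1)

  # deterministic: identical reruns
  cl2 <- flat_meanshift(ft)
  expect_identical(cl$labels, cl2$labels)
  expect_error(feature_table(se, array(0, dims), array(0.5, dims), mask,
                             spatial_bandwidth = 0), "positive")
})

test_that("small clusters merge into their largest-contact neighbour", {
  dims <- c(20, 10, 10)
  vs <- 0.1   # voxel volume 0.001 mm^3; threshold 0.1 mm^3 = 100 voxels
  mk <- function(nsmall) {
    lab <- array(1L, dims)
    lab[1:length(lab)] <- 1L
    sm <- which(array(seq_len(prod(dims)), dims) <= nsmall)
    lab[seq_len(nsmall)] <- 2L
    structure(list(labels = lab, n_clusters = 2, modes = NULL,
                   voxel_size = vs, audit = character(0)),
              class = "cluster_label_map")
  }
  # 90 voxels = 0.09 mm^3: merged away
  m1 <- merge_small_clusters(mk(90))
  expect_equal(m1$n_clusters, 1)
  # 110 voxels = 0.11 mm^3: kept
  m2 <- merge_small_clusters(mk(110))
  expect_equal(m2$n_clusters, 2)
  # nothing below threshold: identity
  expect_equal(sort(unique(as.integer(m2$labels))), c(1L, 2L))

  # nested small cluster inside one large cluster is absorbed by it
  lab <- array(1L, dims)
  lab[10:11, 5:6, 5:6] <- 2L
  nest <- structure(list(labels = lab, n_clusters = 2, modes = NULL,
                         voxel_size = vs, audit = character(0)),
                    class = "cluster_label_map")
  mn <- merge_small_clusters(nest)
  expect_equal(mn$n_clusters, 1)
  expect_true(all(mn$labels == 1L))

  # volume conserved through merging
  expect_equal(sum(!is.na(mn$labels)), prod(dims))
})

test_that("3-cubed mode filter respects majority and tie rules", {
  dims <- c(6, 6, 6)
  lab <- array(1L, dims)
  expect_equal(mode_filter_3cubed(lab), lab)   # uniform: unchanged

  # single dissenting voxel is replaced by the majority
  lab2 <- lab; lab2[3, 3, 3] <- 2L
  f2 <- mode_filter_3cubed(lab2)
  expect_equal(f2[3, 3, 3], 1L)

  # exact ties keep the centre label: a 2x2x2 volume split into halves has
  # a 4-4 neighbourhood count everywhere
  half <- array(c(1L, 1L, 2L, 2L), c(2, 2, 2))
  expect_equal(mode_filter_3cubed(half), half)

  # a 3D checkerboard is *not* a tie: each 3^3 interior neighbourhood holds
  # 13 centre-parity and 14 opposite-parity voxels, so interior voxels flip
  # while truncated boundary neighbourhoods tie and keep their labels
  idx <- arrayInd(seq_len(prod(dims)), dims)
  chk <- array(as.integer((rowSums(idx) %% 2) + 1), dims)
  fc <- mode_filter_3cubed(chk)
  interior <- array(FALSE, dims); interior[2:5, 2:5, 2:5] <- TRUE
  expect_true(all(fc[interior] == (3L - chk[interior])))
  expect_true(all(fc[!interior] == chk[!interior]))

  # volume conserved
  expect_equal(sum(!is.na(f2)), prod(dims))
})

test_that("piecewise sheetlet domains are recovered at acquisition SNR", {
  skip_if_not_installed("mclust")
  # three angular domains with distinct sheet rotations; constant helix
  # angle so SE and SA are exactly piecewise constant within each domain
  sp <- small_spec(ha_endo = 30, ha_epi = 30,
                   se_pattern = list(type = "piecewise_domains",
                                     angles = c(-40, 0, 40)))
  tr <- generate_lv_phantom(sp)
  dwi <- synthesize_dwi(tr, scheme61(), snr_b0 = 47, noise_model = "rician",
                        seed = 19, snr_dw = 24)
  fit <- fit_tensor_nlls(dwi, mask = tr$myocardium_mask)
  eig <- eigen_metrics(fit)
  dp <- small_depth()
  fr <- small_frames()
  am <- compute_angle_maps(eig, fr)
  cm <- tr$myocardium_mask & !am$flagged
  # subsample for the quadratic kernel scan
  idx <- which(cm)
  set.seed(4)
  keep <- sort(sample(idx, 4000))
  cm2 <- array(FALSE, tr$dims); cm2[keep] <- TRUE
  se_u <- unwrap_angle_features(am$SE, cm2)
  sa_u <- unwrap_angle_features(am$SA, cm2)
  # these domains span the full wall, so transmural depth carries no domain
  # information: its bandwidth is widened to cover the wall (a 10%-of-depth
  # bandwidth intentionally partitions depth-localized populations instead)
  ft <- feature_table(se_u, sa_u, dp$phi, cm2, voxel_size = 0.1,
                      depth_bandwidth = 1)
  cl <- flat_meanshift(ft)
  cl <- merge_small_clusters(cl, min_volume_mm3 = 0.1)
  cl <- mode_filter_3cubed(cl)
  pred <- cl$labels[cm2]
  truth <- tr$domain_id[cm2]
  ari <- mclust::adjustedRandIndex(pred, truth)
  expect_gte(ari, 0.9)
  # total labelled volume conserved through merge and filtering
  expect_equal(sum(!is.na(cl$labels)), length(keep))
})
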