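# Per-voxel diffusion tensor estimation, eigen-system metrics, myocardium
# segmentation and SNR.

# design matrix of the log-linear tensor model: columns
# (log s0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), b in s/mm^2, D in 1e-3 mm^2/s
tensor_design_matrix <- function(b6) {
  cbind(1, -1e-3 * b6[, 1], -1e-3 * b6[, 2], -1e-3 * b6[, 3],
        -2e-3 * b6[, 4], -2e-3 * b6[, 5], -2e-3 * b6[, 6])
}

#' Fit the diffusion tensor by nonlinear least squares
#'
#' Voxelwise minimization of sum_i (S_i - s0 exp(-B_i : D))^2 over all volumes
#' simultaneously, by damped Gauss-Newton initialized from the log-linear fit.
#' No positivity constraint is imposed; voxels whose fitted tensor has a
#' negative eigenvalue can be identified downstream from [eigen_metrics()].
#' Residual vectors are retained for reuse by the wild bootstrap.
#'
#' @param dwi A `dwi_stack`.
#' @param mask Optional logical volume restricting the fit (default: voxels
#'   with positive mean signal).
#' @param b_matrices Optional volumes x 6 b-matrix override (defaults to the
#'   stack's nominal b-matrices).
#' @param max_iter,tol Gauss-Newton iteration controls.
#' @return Object of class `tensor_field`: `s0` volume, `tensor` (x,y,z,6) in
#'   10^-3 mm^2/s, `mask`, `residuals` (volumes x masked voxels),
#'   `converged`, `iterations`, and the model design matrix.
#' @export
fit_tensor_nlls <- function(dwi, mask = NULL, b_matrices = NULL,
                            max_iter = 50, tol = 1e-12) {
  stopifnot(inherits(dwi, "dwi_stack"))
  dims <- dim(dwi$data)[1:3]
  nv <- dim(dwi$data)[4]
  if (nv < 7) stop("insufficient measurements: need >= 7 volumes")
  b6 <- if (is.null(b_matrices)) dwi$b_matrices else b_matrices
  stopifnot(nrow(b6) == nv, ncol(b6) == 6)
  X <- tensor_design_matrix(b6)
  if (qr(X)$rank < 7)
    stop("rank-deficient gradient scheme: b-matrices span < 6 directions")
  S4 <- matrix(dwi$data, nrow = prod(dims))      # nvox x nv
  if (is.null(mask)) mask <- array(rowMeans(S4) > 0, dims)
  stopifnot(all(dim(mask) == dims))
  idx <- which(mask)
  if (length(idx) == 0) stop("empty fit mask")
  S <- t(S4[idx, , drop = FALSE])                # nv x nmask
  floor_val <- max(S) * 1e-12
  theta0 <- solve(crossprod(X), crossprod(X, log(pmax(S, floor_val))))
  fit <- cpp_fit_tensor_nlls(S, X, theta0, max_iter, tol)
  s0 <- array(NA_real_, dims)
  s0[idx] <- exp(fit$theta[1, ])
  tensor <- array(NA_real_, c(dims, 6))
  for (k in 1:6) {
    sl <- array(NA_real_, dims)
    sl[idx] <- fit$theta[k + 1, ]
    tensor[, , , k] <- sl
  }
  out <- list(s0 = s0, tensor = tensor, mask = mask, mask_index = idx,
              residuals = fit$residuals, theta = fit$theta,
              converged = fit$converged, iterations = fit$iterations,
              design = X, dims = dims, voxel_size = dwi$voxel_size)
  class(out) <- "tensor_field"
  out
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("tensor field: %s, %d fitted voxels (%.1f%% converged)\n",
              paste(x$dims, collapse = "x"), length(x$mask_index),
              100 * mean(x$converged)))
  invisible(x)
}

#' Eigen-system, FA and mean diffusivity of a tensor field
#'
#' Eigenvalues are sorted descending; eigenvectors are unit, mutually
#' orthogonal and sign-normalized (axial vectors are flipped to a
#' deterministic representative) for reproducibility.
#'
#' @param tf A `tensor_field` (or an array (x,y,z,6) with a `mask` argument).
#' @param mask Logical volume when `tf` is a plain array.
#' @return Object of class `eigen_system`: `lambda` (x,y,z,3), `v1`, `v2`,
#'   `v3` (x,y,z,3), `fa`, `mean_adc` volumes, `mask`.
#' @export
eigen_metrics <- function(tf, mask = NULL) {
  if (inherits(tf, "tensor_field")) {
    tensor <- tf$tensor; mask <- tf$mask
  } else {
    tensor <- tf
    if (is.null(mask)) mask <- array(TRUE, dim(tensor)[1:3])
  }
  dims <- dim(tensor)[1:3]
  idx <- which(mask)
  T6 <- matrix(tensor, nrow = prod(dims))[idx, , drop = FALSE]
  bad <- !is.finite(rowSums(T6))
  T6[bad, ] <- 0
  eg <- cpp_eigen_batch(t(T6))
  lam <- eg$values                       # 3 x n
  V <- eg$vectors                        # 9 x n
  lam[, bad] <- NA_real_
  V[, bad] <- NA_real_
  put3 <- function(m) {                  # 3 x n -> (dims, 3)
    a <- array(NA_real_, c(dims, 3))
    for (k in 1:3) { sl <- array(NA_real_, dims); sl[idx] <- m[k, ]; a[, , , k] <- sl }
    a
  }
  fa <- array(NA_real_, dims); fa[idx] <- fa_from_eigenvalues(lam)
  md <- array(NA_real_, dims); md[idx] <- colMeans(lam)
  out <- list(lambda = put3(lam), v1 = put3(V[1:3, , drop = FALSE]),
              v2 = put3(V[4:6, , drop = FALSE]), v3 = put3(V[7:9, , drop = FALSE]),
              fa = fa, mean_adc = md, mask = mask, flagged = {
                fl <- array(FALSE, dims); fl[idx] <- bad; fl
              })
  class(out) <- "eigen_system"
  out
}

#' @export
print.eigen_system <- function(x, ...) {
  ok <- x$mask & !x$flagged
  cat(sprintf("eigen system: %d voxels, FA %.3f +/- %.3f, ADC %.3f +/- %.3f e-3 mm^2/s\n",
              sum(ok), mean(x$fa[ok]), sd(x$fa[ok]),
              mean(x$mean_adc[ok]), sd(x$mean_adc[ok])))
  invisible(x)
}

#' Segment the myocardium from fitted maps
#'
#' Applies the threshold rules on the b0 signal, mean ADC and FA maps, each
#' normalized to its global maximum: `0.1 < s0 < 1`, `0 < ADC < 0.6` and
#' `0.1 < FA < 1` (open intervals). When an `eigen_system` is supplied, a
#' sheetlet-valid submask additionally requires `lambda2/lambda3 >= 1.05`;
#' voxels below that ratio have poorly defined sheetlet structure and the
#' excluded fraction is reported.
#'
#' @param s0,mean_adc,fa Co-registered volumes.
#' @param eigen Optional `eigen_system` for the sheetlet submask.
#' @param lambda_ratio_min Sheetlet eigenvalue-ratio threshold (default 1.05).
#' @return Object of class `mask_volume`: `mask`, `sheetlet_mask`,
#'   `excluded_fraction` (of the myocardium mask failing the ratio rule) and
#'   a `rules` provenance data.frame.
#' @export
segment_myocardium <- function(s0, mean_adc, fa, eigen = NULL,
                               lambda_ratio_min = 1.05) {
  norm_max <- function(v) {
    m <- max(v[is.finite(v)], na.rm = TRUE)
    if (m <= 0) return(v * 0)
    v / m
  }
  if (all(!is.finite(s0) | s0 == 0)) {
    warning("all-zero input: empty mask")
    empty <- array(FALSE, dim(s0))
    return(structure(list(mask = empty, sheetlet_mask = empty,
                          excluded_fraction = NA_real_, rules = NULL),
                     class = "mask_volume"))
  }
  s0n <- norm_max(s0); adcn <- norm_max(mean_adc); fan <- norm_max(fa)
  ok <- function(v) is.finite(v)
  r1 <- ok(s0n) & s0n > 0.1 & s0n < 1
  r2 <- ok(adcn) & adcn > 0 & adcn < 0.6
  r3 <- ok(fan) & fan > 0.1 & fan < 1
  mask <- r1 & r2 & r3
  rules <- data.frame(rule = c("0.1 < s0/max < 1", "0 < adc/max < 0.6",
                               "0.1 < fa/max < 1"),
                      retained = c(sum(r1), sum(r2), sum(r3)))
  sheet <- mask
  excl <- NA_real_
  if (!is.null(eigen)) {
    ratio <- eigen$lambda[, , , 2] / eigen$lambda[, , , 3]
    keep <- is.finite(ratio) & ratio >= lambda_ratio_min
    sheet <- mask & keep
    excl <- if (sum(mask) > 0) sum(mask & !keep) / sum(mask) else NA_real_
  }
  structure(list(mask = mask, sheetlet_mask = sheet,
                 excluded_fraction = excl, rules = rules),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("myocardium mask: %d voxels", sum(x$mask)))
  if (is.finite(x$excluded_fraction))
    cat(sprintf("; sheetlet-valid %d (%.3f excluded by lambda2/lambda3)",
                sum(x$sheetlet_mask), x$excluded_fraction))
  cat("\n")
  invisible(x)
}

#' Signal-to-noise ratio of a volume
#'
#' SNR = mean signal inside the mask divided by the standard deviation of the
#' paired noise-only volume.
#'
#' @param signal 3D signal volume (or 4D stack: one SNR per volume).
#' @param mask Logical volume (e.g. the myocardium mask).
#' @param noise_volume Noise-only volume acquired without excitation.
#' @return SNR scalar (or vector for a 4D input).
#' @export
compute_snr <- function(signal, mask, noise_volume) {
  if (inherits(mask, "mask_volume")) mask <- mask$mask
  if (sum(mask) == 0) stop("empty mask")
  if (is.null(noise_volume) || length(noise_volume) == 0)
    stop("noise volume required")
  s <- sd(noise_volume)
  if (s == 0) stop("zero-variance noise volume")
  if (length(dim(signal)) == 4) {
    nv <- dim(signal)[4]
    vapply(seq_len(nv), function(i) {
      vol <- signal[, , , i]
      mean(vol[mask]) / s
    }, numeric(1))
  } else {
    mean(signal[mask]) / s
  }
}
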