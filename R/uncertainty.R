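# Wild bootstrap of the tensor fit and 95% cone-of-uncertainty maps.

#' Wild bootstrap of a tensor fit
#'
#' Generates replicate datasets S* = S_hat + eps * r with Rademacher signs r
#' in {-1, +1} (i.i.d. per voxel and volume by default; `per_volume = TRUE`
#' flips whole volumes instead), refits the tensor from the original estimate,
#' and stores each replicate's eigen-system. Eigenvector correspondence across
#' replicates is by eigenvalue rank.
#'
#' @param fit A `tensor_field` from [fit_tensor_nlls()] (with residuals).
#' @param n Number of replicates (the acquisition-matched default is 1000;
#'   smaller ensembles are adequate for phantom work).
#' @param seed Integer seed.
#' @param mask Optional logical volume restricting bootstrapped voxels to a
#'   subset of the fitted mask (memory: 9 doubles per voxel per replicate).
#' @param per_volume Rademacher signs per volume instead of per voxel-volume.
#' @param max_iter,tol Refit iteration controls.
#' @return Object of class `bootstrap_ensemble`: `vectors` (9 x voxels x n,
#'   rows v1,v2,v3 stacked), `values` (3 x voxels x n), `voxel_index`, `dims`,
#'   `n`, `seed`.
#' @export
wild_bootstrap <- function(fit, n = 1000, seed = 1L, mask = NULL,
                           per_volume = FALSE, max_iter = 30, tol = 1e-10) {
  stopifnot(inherits(fit, "tensor_field"))
  if (n < 2) stop("need at least 2 bootstrap replicates")
  sub <- seq_along(fit$mask_index)
  if (!is.null(mask)) {
    if (inherits(mask, "mask_volume")) mask <- mask$mask
    keep <- mask[fit$mask_index]
    sub <- which(keep)
    if (length(sub) == 0) stop("bootstrap mask does not intersect fit mask")
  }
  theta <- fit$theta[, sub, drop = FALSE]
  resid <- fit$residuals[, sub, drop = FALSE]
  set.seed(derive_seed(seed, "wild_bootstrap"))
  ens <- cpp_wild_bootstrap(fit$design, theta, resid, as.integer(n),
                            max_iter, tol, per_volume)
  out <- list(vectors = ens$vectors, values = ens$values,
              voxel_index = fit$mask_index[sub], dims = fit$dims,
              n = as.integer(n), seed = seed, per_volume = per_volume)
  class(out) <- "bootstrap_ensemble"
  out
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf("wild-bootstrap ensemble: %d replicates x %d voxels\n",
              x$n, length(x$voxel_index)))
  invisible(x)
}

#' 95% cone of uncertainty per eigenvector
#'
#' For each voxel and eigenvector, the mean axis is the principal eigenvector
#' of the mean dyadic tensor E(v v^T) over replicates (removing the axial sign
#' ambiguity), and the cone of uncertainty is the 95th percentile of the acute
#' angle between each replicate's axis and the mean axis.
#'
#' @param ens A `bootstrap_ensemble`.
#' @param probs Percentile of the cone (default 0.95).
#' @return Object of class `cou_map`: `cou` (voxels x 3, degrees), volumes
#'   `cou_v1`, `cou_v2`, `cou_v3` when `dims` are known, `degenerate` flags
#'   (isotropic dyadic spread), and `summary` (mean COU per eigenvector).
#' @export
cone_of_uncertainty <- function(ens, probs = 0.95) {
  stopifnot(inherits(ens, "bootstrap_ensemble"))
  nvox <- length(ens$voxel_index)
  cou <- matrix(NA_real_, nvox, 3)
  degen <- matrix(FALSE, nvox, 3)
  for (k in 1:3) {
    rows <- (3 * k - 2):(3 * k)
    Vx <- ens$vectors[rows[1], , , drop = TRUE]
    Vy <- ens$vectors[rows[2], , , drop = TRUE]
    Vz <- ens$vectors[rows[3], , , drop = TRUE]
    if (is.null(dim(Vx))) { Vx <- matrix(Vx, nvox); Vy <- matrix(Vy, nvox); Vz <- matrix(Vz, nvox) }
    M6 <- rbind(rowMeans(Vx * Vx), rowMeans(Vy * Vy), rowMeans(Vz * Vz),
                rowMeans(Vx * Vy), rowMeans(Vx * Vz), rowMeans(Vy * Vz))
    eg <- cpp_eigen_batch(M6)
    mu <- eg$vectors[1:3, , drop = FALSE]          # mean axis per voxel
    degen[, k] <- (eg$values[1, ] - eg$values[2, ]) < 1e-6
    dots <- abs(Vx * mu[1, ] + Vy * mu[2, ] + Vz * mu[3, ])
    angles <- acos(pmin(dots, 1)) * 180 / pi       # folded to <= 90 by abs()
    cou[, k] <- apply(angles, 1, quantile, probs = probs, names = FALSE)
  }
  colnames(cou) <- c("v1", "v2", "v3")
  vols <- NULL
  if (!is.null(ens$dims)) {
    vols <- lapply(1:3, function(k) {
      v <- array(NA_real_, ens$dims); v[ens$voxel_index] <- cou[, k]; v
    })
    names(vols) <- c("cou_v1", "cou_v2", "cou_v3")
  }
  out <- c(list(cou = cou, degenerate = degen,
                summary = colMeans(cou, na.rm = TRUE),
                voxel_index = ens$voxel_index, dims = ens$dims), vols)
  class(out) <- "cou_map"
  out
}

#' @export
print.cou_map <- function(x, ...) {
  cat(sprintf("95%% COU (mean over voxels): v1 %.2f deg, v2 %.2f deg, v3 %.2f deg\n",
              x$summary[1], x$summary[2], x$summary[3]))
  invisible(x)
}
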