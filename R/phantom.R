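# Synthetic left-ventricle phantom: annular wall geometry, prescribed local
# frames and angle fields, ground-truth tensor field.

#' Left-ventricle phantom specification
#'
#' Parameters of the synthetic hollow-cylinder LV phantom. The wall is an
#' annulus of inner radius `endo_radius` and outer radius `epi_radius`,
#' extruded over `wall_height` along z, immersed in isotropic buffer fluid.
#' The helix angle ramps linearly in transmural depth from `ha_endo` at the
#' endocardium to `ha_epi` at the epicardium; depth is the analytic Laplace
#' potential of the annulus, ln(rho/a)/ln(b/a), so that the prescribed ramp is
#' linear in the transmural coordinate the analysis pipeline recovers.
#'
#' @param endo_radius,epi_radius Inner/outer wall radii, mm.
#' @param wall_height Wall extent along the long axis, mm.
#' @param voxel_size Isotropic voxel size, mm (default 0.1).
#' @param grid_dim Volume dimension (isotropic, voxels).
#' @param ha_endo,ha_epi Helix angle at endo/epicardium, degrees.
#' @param ta_const Constant transverse angle, degrees.
#' @param se_pattern Sheetlet-rotation pattern: `list(type = "constant",
#'   angle = )`, `list(type = "transmural_ramp", from = , to = )`, or
#'   `list(type = "piecewise_domains", angles = )` (angular sectors of
#'   constant sheet rotation, one per element of `angles`). Degrees.
#' @param mean_adc Myocardial mean diffusivity, 10^-3 mm^2/s (default 1.3).
#' @param fa_target Myocardial fractional anisotropy (default 0.19).
#' @param eig_rho Asymmetry of the second/third eigenvalue deficit (fixed
#'   shape parameter of the eigenvalue spread; keeps lambda2 > lambda3).
#' @param s0_myocardium,s0_buffer Non-DW signal levels, arbitrary units.
#' @param buffer_adc Isotropic buffer diffusivity, 10^-3 mm^2/s. The default
#'   2.2 is free water at the sample's heated steady state (about 24 deg C);
#'   water at 20 deg C is about 2.0 and rises by 2.4% per deg C.
#' @param tube_radius Radius of the sample tube, mm; buffer fluid fills the
#'   tube and signal-free air lies outside it (`NULL`: midway between
#'   `epi_radius` and the volume edge). The air region anchors the
#'   noise-driven global maxima that the segmentation thresholds are
#'   normalized against, as in a real scan.
#' @param seed Integer seed recorded in the spec.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(endo_radius = 1.2, epi_radius = 2.6,
                         wall_height = 4.8, voxel_size = 0.1, grid_dim = 64,
                         ha_endo = 60, ha_epi = -60, ta_const = 0,
                         se_pattern = list(type = "constant", angle = 0),
                         mean_adc = 1.3, fa_target = 0.19, eig_rho = 0.25,
                         s0_myocardium = 1, s0_buffer = 1.5,
                         buffer_adc = 2.2, tube_radius = NULL, seed = 1L) {
  stopifnot(epi_radius > endo_radius, endo_radius > 0, voxel_size > 0,
            fa_target >= 0, fa_target < 1, mean_adc > 0, buffer_adc > 0,
            wall_height > 0, grid_dim >= 8, eig_rho > 0, eig_rho < 1)
  if ((epi_radius - endo_radius) < 2 * voxel_size)
    stop("wall thickness below 2 voxels")
  obj <- as.list(environment())
  class(obj) <- "phantom_spec"
  obj
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "LV phantom spec: annulus %g-%g mm x %g mm, %d^3 @ %g mm\n  HA %+g to %+g deg, TA %g deg, FA %g, ADC %g e-3 mm^2/s\n",
    x$endo_radius, x$epi_radius, x$wall_height, x$grid_dim, x$voxel_size,
    x$ha_endo, x$ha_epi, x$ta_const, x$fa_target, x$mean_adc))
  invisible(x)
}

# eigenvalue triple with prescribed FA and mean, lambda2 > lambda3 strictly:
# lambda = mean * (1 + 2a, 1 - a(1-rho), 1 - a(1+rho)), a solved by bisection
solve_eigenvalue_spread <- function(fa_target, mean_adc, rho = 0.25) {
  if (fa_target == 0) return(rep(mean_adc, 3))
  a_max <- 1 / (1 + rho) - 1e-9
  f <- function(a)
    fa_from_eigenvalues(mean_adc * c(1 + 2 * a, 1 - a * (1 - rho),
                                     1 - a * (1 + rho))) - fa_target
  if (f(a_max) < 0)
    stop("fa_target infeasible with positive eigenvalues")
  a <- stats::uniroot(f, c(0, a_max), tol = 1e-14)$root
  mean_adc * c(1 + 2 * a, 1 - a * (1 - rho), 1 - a * (1 + rho))
}

#' Generate the ground-truth LV phantom
#'
#' Builds masks, the true transmural depth and local frames, the prescribed
#' eigenvector fields and the positive-definite tensor volume. Eigenvalues are
#' solved by bisection so that FA equals `fa_target` and the mean diffusivity
#' equals `mean_adc` exactly. Buffer and cavity voxels carry an isotropic
#' tensor at `buffer_adc`. True angle maps are evaluated from the constructed
#' eigenvectors and frames with the same projection conventions as
#' [compute_angle_maps()].
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `phantom_truth`: masks, `depth`, frame arrays `r`,
#'   `c`, `l` (x,y,z,3), eigenvector arrays `v1`,`v2`,`v3`, eigenvalue array
#'   `lambda`, tensor array `tensors` (x,y,z,6: xx,yy,zz,xy,xz,yz), `s0`,
#'   angle volumes `angles$HA/TA/SE/SA`, `domain_id`, the anterior
#'   RV-insertion `landmark`, `l_global`, `voxel_size`, `origin`.
#' @export
generate_lv_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_dim
  vs <- spec$voxel_size
  dims <- c(n, n, n)
  # world coordinates of voxel centres, volume centred on the origin
  ax <- (seq_len(n) - (n + 1) / 2) * vs
  if (spec$epi_radius >= max(ax))
    stop("epi_radius does not fit inside the grid")
  X <- array(rep(ax, times = n * n), dims)
  Y <- array(rep(rep(ax, each = n), times = n), dims)
  Z <- array(rep(ax, each = n * n), dims)
  rho <- sqrt(X^2 + Y^2)
  tube_r <- spec$tube_radius
  if (is.null(tube_r)) tube_r <- (spec$epi_radius + max(ax)) / 2
  if (tube_r <= spec$epi_radius) stop("tube_radius must exceed epi_radius")
  inz <- abs(Z) <= spec$wall_height / 2
  myocardium <- inz & rho >= spec$endo_radius & rho <= spec$epi_radius
  cavity <- inz & rho < spec$endo_radius
  air <- rho > tube_r
  buffer <- !myocardium & !cavity & !air
  if (sum(myocardium) == 0) stop("empty myocardium mask")

  idx <- which(myocardium)
  x <- X[idx]; y <- Y[idx]; z <- Z[idx]
  rh <- rho[idx]
  th <- atan2(y, x)
  # analytic Laplace potential of the annulus = true transmural depth
  depth_v <- log(rh / spec$endo_radius) /
    log(spec$epi_radius / spec$endo_radius)
  depth_v <- pmin(pmax(depth_v, 0), 1)

  # local frames: r endo->epi, c = l_global x r, l = r x c (= +z here)
  r_v <- cbind(cos(th), sin(th), 0)
  c_v <- cbind(-sin(th), cos(th), 0)
  l_v <- cbind(0, 0, 1)[rep(1, length(idx)), , drop = FALSE]

  ha <- rad(spec$ha_endo + (spec$ha_epi - spec$ha_endo) * depth_v)
  ta <- rad(rep(spec$ta_const, length(idx)))
  # fibre direction from HA and TA in the local frame
  e_t <- cos(ta) * c_v + sin(ta) * r_v        # in-short-axis-plane direction
  v1 <- cos(ha) * e_t + sin(ha) * l_v

  # sheet rotation angle about v1, measured from the radial direction
  sp <- spec$se_pattern
  srot <- switch(sp$type,
    constant = rep(sp$angle, length(idx)),
    transmural_ramp = sp$from + (sp$to - sp$from) * depth_v,
    piecewise_domains = {
      k <- length(sp$angles)
      sector <- pmin(floor((th + pi) / (2 * pi) * k) + 1, k)
      sp$angles[sector]
    },
    stop("unknown se_pattern type: ", sp$type))
  domain_id_v <- if (sp$type == "piecewise_domains") {
    k <- length(sp$angles)
    pmin(floor((th + pi) / (2 * pi) * k) + 1, k)
  } else rep(1L, length(idx))
  srot <- rad(srot)
  # orthonormal completion: a = radial component orthogonal to v1, b = v1 x a
  a_v <- r_v - rowSums(r_v * v1) * v1
  a_v <- a_v / sqrt(rowSums(a_v^2))
  b_v <- cbind(v1[, 2] * a_v[, 3] - v1[, 3] * a_v[, 2],
               v1[, 3] * a_v[, 1] - v1[, 1] * a_v[, 3],
               v1[, 1] * a_v[, 2] - v1[, 2] * a_v[, 1])
  v3 <- cos(srot) * a_v - sin(srot) * b_v
  v2 <- cbind(v3[, 2] * v1[, 3] - v3[, 3] * v1[, 2],
              v3[, 3] * v1[, 1] - v3[, 1] * v1[, 3],
              v3[, 1] * v1[, 2] - v3[, 2] * v1[, 1])

  lam <- solve_eigenvalue_spread(spec$fa_target, spec$mean_adc, spec$eig_rho)

  # assemble volumes -------------------------------------------------------
  vol3 <- function(m) {
    a <- array(0, c(dims, 3))
    for (k in 1:3) {
      sl <- array(0, dims); sl[idx] <- m[, k]; a[, , , k] <- sl
    }
    a
  }
  depth <- array(NA_real_, dims); depth[idx] <- depth_v
  tensors <- array(0, c(dims, 6))
  d6 <- cbind(
    lam[1] * v1[, 1]^2 + lam[2] * v2[, 1]^2 + lam[3] * v3[, 1]^2,
    lam[1] * v1[, 2]^2 + lam[2] * v2[, 2]^2 + lam[3] * v3[, 2]^2,
    lam[1] * v1[, 3]^2 + lam[2] * v2[, 3]^2 + lam[3] * v3[, 3]^2,
    lam[1] * v1[, 1] * v1[, 2] + lam[2] * v2[, 1] * v2[, 2] +
      lam[3] * v3[, 1] * v3[, 2],
    lam[1] * v1[, 1] * v1[, 3] + lam[2] * v2[, 1] * v2[, 3] +
      lam[3] * v3[, 1] * v3[, 3],
    lam[1] * v1[, 2] * v1[, 3] + lam[2] * v2[, 2] * v2[, 3] +
      lam[3] * v3[, 2] * v3[, 3])
  iso <- which(buffer | cavity)
  for (k in 1:6) {
    sl <- array(0, dims)
    sl[idx] <- d6[, k]
    if (k <= 3) sl[iso] <- spec$buffer_adc
    tensors[, , , k] <- sl
  }
  lambda <- array(0, c(dims, 3))
  for (k in 1:3) {
    sl <- array(0, dims); sl[iso] <- spec$buffer_adc; sl[idx] <- lam[k]
    lambda[, , , k] <- sl
  }
  s0 <- array(0, dims)
  s0[iso] <- spec$s0_buffer
  s0[idx] <- spec$s0_myocardium
  domain_id <- array(NA_integer_, dims); domain_id[idx] <- domain_id_v

  ang <- angles_from_vectors(v1, v3, r_v, c_v, l_v)
  angles <- lapply(ang, function(a) {
    v <- array(NA_real_, dims); v[idx] <- a; v
  })

  landmark_theta <- 0
  landmark <- c(spec$epi_radius * cos(landmark_theta),
                spec$epi_radius * sin(landmark_theta), 0)

  # Laplace boundary sources: cavity (phi = 0) and the radially outward
  # buffer (phi = 1); buffer beyond the wall ends is neither, so the end
  # faces are reflecting
  epi_boundary <- inz & rho > spec$epi_radius
  out <- list(spec = spec, dims = dims, voxel_size = vs, axes = ax,
              myocardium_mask = myocardium, lv_cavity_mask = cavity,
              buffer_mask = buffer, air_mask = air, endo_boundary = cavity,
              epi_boundary = epi_boundary, depth = depth,
              r = vol3(r_v), c = vol3(c_v), l = vol3(l_v),
              l_global = c(0, 0, 1),
              v1 = vol3(v1), v2 = vol3(v2), v3 = vol3(v3),
              lambda = lambda, tensors = tensors, s0 = s0,
              angles = angles, domain_id = domain_id,
              landmark = landmark, eigenvalues_myocardium = lam)
  class(out) <- "phantom_truth"
  out
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "LV phantom truth: %s grid, %d myocardial / %d cavity / %d buffer voxels\n",
    paste(x$dims, collapse = "x"), sum(x$myocardium_mask),
    sum(x$lv_cavity_mask), sum(x$buffer_mask)))
  cat(sprintf("  eigenvalues %s e-3 mm^2/s (FA %.4f)\n",
              paste(signif(x$eigenvalues_myocardium, 4), collapse = "/"),
              fa_from_eigenvalues(x$eigenvalues_myocardium)))
  invisible(x)
}
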