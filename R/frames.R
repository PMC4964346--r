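# Local cardiac coordinate frames: global long axis, Laplace transmural
# potential, (r, c, l) triads and HA/TA/SE/SA angle maps.

#' Global left-ventricular long axis
#'
#' Total-least-squares line through the centres-of-mass of the segmented LV
#' cavity in 2D short-axis (z) planes; the direction is the principal
#' component of the per-slice centroids, oriented apex to base (toward the
#' wider cavity; for a uniform cavity, toward +z).
#'
#' @param lv_cavity_mask Logical volume of the LV cavity.
#' @param voxel_size Voxel size in mm (isotropic).
#' @return Unit 3-vector.
#' @export
global_long_axis <- function(lv_cavity_mask, voxel_size = 1) {
  dims <- dim(lv_cavity_mask)
  idx <- which(lv_cavity_mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty cavity mask")
  zs <- sort(unique(idx[, 3]))
  if (length(zs) < 2) stop("cavity spans fewer than 2 slices")
  cent <- t(vapply(zs, function(z) {
    sl <- idx[idx[, 3] == z, , drop = FALSE]
    c(colMeans(sl[, 1:2, drop = FALSE]), z, nrow(sl))
  }, numeric(4)))
  P <- cent[, 1:3] * voxel_size
  area <- cent[, 4]
  Pc <- sweep(P, 2, colMeans(P))
  d <- svd(Pc)$v[, 1]
  proj <- Pc %*% d
  # orient toward the wider cavity (base); degenerate taper -> +dominant axis
  s <- sum(proj * (area - mean(area)))
  if (abs(s) > 1e-8 * max(area)) {
    if (s < 0) d <- -d
  } else {
    k <- which.max(abs(d))
    if (d[k] < 0) d <- -d
  }
  unit(d)
}

#' Solve the Laplace transmural potential
#'
#' Discrete Laplace equation on the myocardial mask with Dirichlet boundary
#' values phi = 0 on endocardium-adjacent voxels and phi = 1 on
#' epicardium-adjacent voxels (7-point stencil; faces touching neither
#' boundary are reflecting). The potential doubles as the normalized
#' transmural depth, and its normalized gradient is the local radial
#' direction, oriented endocardium to epicardium.
#'
#' @param myocardium_mask Logical volume of the wall.
#' @param endo_boundary Logical volume: voxels outside the wall on the
#'   cavity side (phi = 0 sources).
#' @param epi_boundary Logical volume: voxels outside the wall on the outer
#'   side (phi = 1 sources).
#' @return Object of class `depth_field`: `phi` volume (NA outside the wall),
#'   `grad` (x,y,z,3) unnormalized gradient, `r` unit radial field, `mask`.
#' @export
solve_laplace_depth <- function(myocardium_mask, endo_boundary, epi_boundary) {
  dims <- dim(myocardium_mask)
  if (any(myocardium_mask & (endo_boundary | epi_boundary)))
    stop("boundary masks must lie outside the myocardium mask")
  idx <- which(myocardium_mask)
  n <- length(idx)
  if (n == 0) stop("empty myocardium mask")
  id <- array(0L, dims)
  id[idx] <- seq_len(n)
  co <- which(myocardium_mask, arr.ind = TRUE)
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  ii <- jj <- integer(0)
  xx <- numeric(0)
  diagc <- numeric(n)
  rhs <- numeric(n)
  n_dirichlet <- 0L
  for (k in 1:6) {
    nb <- sweep(co, 2, offs[k, ], `+`)
    inb <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
           nb[, 2] >= 1 & nb[, 2] <= dims[2] &
           nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lin <- rep(NA_integer_, n)
    lin[inb] <- nb[inb, 1] + dims[1] * (nb[inb, 2] - 1) +
      dims[1] * dims[2] * (nb[inb, 3] - 1)
    in_mask <- inb & myocardium_mask[pmax(lin, 1)] & !is.na(lin)
    in_endo <- inb & endo_boundary[pmax(lin, 1)] & !is.na(lin) & !in_mask
    in_epi <- inb & epi_boundary[pmax(lin, 1)] & !is.na(lin) &
      !in_mask & !in_endo
    # Dirichlet values are imposed at the voxel face (half-spacing ghost),
    # weight 2; interior couplings weight 1; other faces reflect
    diagc <- diagc + as.numeric(in_mask) + 2 * as.numeric(in_endo | in_epi)
    rhs <- rhs + 2 * as.numeric(in_epi)
    n_dirichlet <- n_dirichlet + sum(in_endo | in_epi)
    w <- which(in_mask)
    ii <- c(ii, w)
    jj <- c(jj, id[lin[w]])
    xx <- c(xx, rep(-1, length(w)))
  }
  if (any(diagc == 0))
    stop("isolated myocardial voxels with no neighbours")
  if (n_dirichlet == 0)
    stop("Laplace system is singular: the wall touches no Dirichlet boundary")
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(xx, diagc), dims = c(n, n))
  phi_v <- tryCatch(
    as.numeric(Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(A)),
                             rhs)),
    error = function(e)
      stop("Laplace system is singular: a wall component touches no boundary"))
  phi <- array(NA_real_, dims)
  phi[idx] <- phi_v
  # gradient with Dirichlet values at voxel faces (half-spacing)
  grad <- array(0, c(dims, 3))
  for (ax in 1:3) {
    getv <- function(nb) {
      okb <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
             nb[, 2] >= 1 & nb[, 2] <= dims[2] &
             nb[, 3] >= 1 & nb[, 3] <= dims[3]
      v <- rep(NA_real_, n)
      d <- rep(NA_real_, n)
      lin <- nb[okb, 1] + dims[1] * (nb[okb, 2] - 1) +
        dims[1] * dims[2] * (nb[okb, 3] - 1)
      v[okb] <- ifelse(myocardium_mask[lin], phi[lin],
                       ifelse(endo_boundary[lin], 0,
                              ifelse(epi_boundary[lin], 1, NA_real_)))
      d[okb] <- ifelse(myocardium_mask[lin], 1, 0.5)
      list(v = v, d = d)
    }
    p <- getv(sweep(co, 2, offs[2 * ax, ], `+`))
    m <- getv(sweep(co, 2, offs[2 * ax - 1, ], `+`))
    g <- ifelse(!is.na(p$v) & !is.na(m$v), (p$v - m$v) / (p$d + m$d),
                ifelse(!is.na(p$v), (p$v - phi_v) / p$d,
                       ifelse(!is.na(m$v), (phi_v - m$v) / m$d, 0)))
    sl <- array(0, dims)
    sl[idx] <- g
    grad[, , , ax] <- sl
  }
  gn <- sqrt(grad[, , , 1]^2 + grad[, , , 2]^2 + grad[, , , 3]^2)
  r <- grad
  for (ax in 1:3) r[, , , ax] <- ifelse(gn > 0, grad[, , , ax] / gn, 0)
  out <- list(phi = phi, grad = grad, r = r, mask = myocardium_mask)
  class(out) <- "depth_field"
  out
}

#' Build local cardiac frames from the radial field
#'
#' c = (l_global x r) / |l_global x r| (circumferential) and l = r x c
#' (longitudinal). Voxels where the radial direction is nearly parallel to
#' the global long axis (|l_global x r| < 1e-3) are flagged degenerate.
#'
#' @param depth A `depth_field` (or an (x,y,z,3) radial unit field).
#' @param l_global Unit global long axis.
#' @param mask Logical volume when `depth` is a plain array.
#' @return Object of class `local_frame_field`: arrays `r`, `c`, `l`
#'   (x,y,z,3), `degenerate` flags, `l_global`, `mask`.
#' @export
build_local_frames <- function(depth, l_global, mask = NULL) {
  if (inherits(depth, "depth_field")) {
    r <- depth$r; mask <- depth$mask
  } else {
    r <- depth
    if (is.null(mask)) mask <- array(TRUE, dim(r)[1:3])
  }
  l_global <- unit(l_global)
  dims <- dim(r)[1:3]
  rx <- r[, , , 1]; ry <- r[, , , 2]; rz <- r[, , , 3]
  cx <- l_global[2] * rz - l_global[3] * ry
  cy <- l_global[3] * rx - l_global[1] * rz
  cz <- l_global[1] * ry - l_global[2] * rx
  cn <- sqrt(cx^2 + cy^2 + cz^2)
  degenerate <- mask & cn < 1e-3
  cn[cn == 0] <- 1
  cx <- cx / cn; cy <- cy / cn; cz <- cz / cn
  lx <- ry * cz - rz * cy
  ly <- rz * cx - rx * cz
  lz <- rx * cy - ry * cx
  pack <- function(a, b, d) { out <- array(0, c(dims, 3))
    out[, , , 1] <- a; out[, , , 2] <- b; out[, , , 3] <- d; out }
  out <- list(r = r, c = pack(cx, cy, cz), l = pack(lx, ly, lz),
              degenerate = degenerate, l_global = l_global, mask = mask)
  class(out) <- "local_frame_field"
  out
}

# angle maps from eigenvector and frame component matrices (n x 3), degrees.
# Axial sign: each vector is flipped so the denominator component is >= 0.
angles_from_vectors <- function(v1, v3, r, c, l, tol = 1e-9) {
  comp <- function(v, e) rowSums(v * e)
  ang <- function(num, den) {
    s <- ifelse(den < 0, -1, 1)
    num <- num * s
    den <- den * s
    a <- deg(atan2(num, den))
    a[abs(num) < tol & den < tol] <- NA_real_   # zero-length projection
    a[a <= -90] <- a[a <= -90] + 180            # fold to (-90, 90]
    a
  }
  vc1 <- comp(v1, c); vr1 <- comp(v1, r); vl1 <- comp(v1, l)
  vc3 <- comp(v3, c); vr3 <- comp(v3, r); vl3 <- comp(v3, l)
  list(HA = ang(vl1, vc1), TA = ang(vr1, vc1),
       SE = ang(vl3, vr3), SA = ang(vc3, vr3))
}

#' Helix, transverse, sheet-elevation and sheet-azimuth angle maps
#'
#' With components (vc, vr, vl) of an eigenvector in the local frame:
#' HA = atan(vl/vc) from the projection of v1 onto the tangential (c-l)
#' plane; TA = atan(vr/vc) from its short-axis (c-r) projection;
#' SE = atan(vl/vr) from the projection of v3 onto the radial (r-l) plane;
#' SA = atan(vc/vr) from its short-axis projection. The axial eigenvector
#' sign is resolved by flipping so the denominator component is
#' non-negative; angles lie in (-90, 90] degrees. Degenerate-frame voxels
#' and zero-length projections are NA and flagged.
#'
#' @param eigen An `eigen_system` (or a list with `v1`, `v3` (x,y,z,3)).
#' @param frames A `local_frame_field`.
#' @return Object of class `angle_maps`: volumes `HA`, `TA`, `SE`, `SA`
#'   (degrees), `flagged` logical volume, `mask`.
#' @export
compute_angle_maps <- function(eigen, frames) {
  stopifnot(inherits(frames, "local_frame_field"))
  dims <- dim(frames$r)[1:3]
  mask <- frames$mask & !frames$degenerate
  if (!is.null(eigen$mask)) mask <- mask & eigen$mask
  idx <- which(mask)
  take <- function(a) matrix(a, ncol = 3)[idx, , drop = FALSE]
  ang <- angles_from_vectors(take(eigen$v1), take(eigen$v3),
                             take(frames$r), take(frames$c), take(frames$l))
  put <- function(v) { a <- array(NA_real_, dims); a[idx] <- v; a }
  flagged <- array(FALSE, dims)
  flagged[idx] <- !is.finite(ang$HA) | !is.finite(ang$TA) |
    !is.finite(ang$SE) | !is.finite(ang$SA)
  flagged <- flagged | (frames$mask & frames$degenerate)
  out <- list(HA = put(ang$HA), TA = put(ang$TA), SE = put(ang$SE),
              SA = put(ang$SA), flagged = flagged, mask = mask)
  class(out) <- "angle_maps"
  out
}

#' @export
print.angle_maps <- function(x, ...) {
  ok <- x$mask & !x$flagged
  cat(sprintf(
    "angle maps over %d voxels (HA %.1f+/-%.1f, TA %.1f+/-%.1f, SE %.1f+/-%.1f, SA %.1f+/-%.1f deg)\n",
    sum(ok), mean(x$HA[ok]), sd(x$HA[ok]), mean(x$TA[ok]), sd(x$TA[ok]),
    mean(x$SE[ok]), sd(x$SE[ok]), mean(x$SA[ok]), sd(x$SA[ok])))
  invisible(x)
}

#' Render an angle map mid-slice with a cyclic colormap
#'
#' Writes a PNG of one axial slice, mapping the axial angle range
#' (-90, 90] onto the cyclic HSV hue wheel so that -90 and +90 (the same
#' physical axis) share a colour. Voxels outside the mask are black.
#'
#' @param angle_map Angle volume in degrees.
#' @param path Output PNG path.
#' @param slice Slice index (default: middle slice).
#' @param mask Optional logical volume.
#' @return `path`, invisibly.
#' @export
write_angle_png <- function(angle_map, path, slice = NULL, mask = NULL) {
  dims <- dim(angle_map)
  if (is.null(slice)) slice <- round(dims[3] / 2)
  a <- angle_map[, , slice]
  ok <- is.finite(a)
  if (!is.null(mask)) ok <- ok & mask[, , slice]
  hue <- (a + 90) / 180           # cyclic: -90 and +90 coincide mod 1
  hue[!ok] <- 0
  rgb <- grDevices::hsv(h = hue %% 1, s = 1, v = as.numeric(ok))
  col <- grDevices::col2rgb(rgb) / 255
  img <- array(0, c(dims[2], dims[1], 3))
  for (k in 1:3) img[, , k] <- t(matrix(col[k, ], dims[1], dims[2]))[dims[2]:1, ]
  png::writePNG(img, path)
  invisible(path)
}

#' Classify non-myocardial voxels into cavity and exterior
#'
#' Geometric helper for pipeline runs without ground-truth masks: per
#' short-axis slice containing wall voxels, non-mask voxels closer to the
#' slice centroid than the mean in-slice wall radius are assigned to the
#' cavity (endocardial boundary) and the remaining in-slice voxels to the
#' exterior (epicardial boundary). Slices without wall voxels belong to
#' neither boundary, so the wall's end faces are reflecting in the Laplace
#' solve. Suited to LV-annulus topologies.
#'
#' @param mask Logical myocardium volume.
#' @return List of logical volumes `endo_boundary`, `epi_boundary`.
#' @export
classify_lv_boundaries <- function(mask) {
  dims <- dim(mask)
  endo <- array(FALSE, dims)
  epi <- array(FALSE, dims)
  for (z in seq_len(dims[3])) {
    sl <- mask[, , z]
    if (!any(sl)) next
    w <- which(sl, arr.ind = TRUE)
    cen <- colMeans(w)
    rr <- sqrt((w[, 1] - cen[1])^2 + (w[, 2] - cen[2])^2)
    rmean <- mean(rr)
    nb <- which(!sl, arr.ind = TRUE)
    din <- sqrt((nb[, 1] - cen[1])^2 + (nb[, 2] - cen[2])^2) < rmean
    lin <- nb[, 1] + dims[1] * (nb[, 2] - 1) + dims[1] * dims[2] * (z - 1)
    endo[lin[din]] <- TRUE
    epi[lin[!din]] <- TRUE
  }
  list(endo_boundary = endo, epi_boundary = epi)
}
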