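# Sheetlet-domain segmentation: doubled-angle phase unwrapping, flat-kernel
# mean-shift, small-cluster merging and 3^3 mode filtering.

#' Unwrap an axial angle map into a spatially continuous feature
#'
#' Maps each angle A (degrees, axial: A and A+180 identified) to the
#' doubled-angle unit circle e^(2iA) and recovers a continuous scalar feature
#' by region-growing phase unwrapping of the doubled phase over the mask
#' (6-connectivity), halved back to angle units. Neighbouring voxels at +89
#' and -89 degrees thus differ by 2 degrees, not 178.
#'
#' @param angle_map Volume of angles in degrees, (-90, 90].
#' @param mask Logical volume.
#' @return Volume of unwrapped angles (degrees; NA outside the mask). Each
#'   connected component is anchored at its first voxel's raw value.
#' @export
unwrap_angle_features <- function(angle_map, mask) {
  dims <- dim(mask)
  out <- array(NA_real_, dims)
  if (!any(mask)) return(out)
  phase <- 2 * rad(angle_map)              # doubled-angle phase
  idx <- which(mask & is.finite(angle_map))
  remaining <- array(FALSE, dims)
  remaining[idx] <- TRUE
  strides <- c(1L, dims[1], dims[1] * dims[2])
  while (any(remaining)) {
    seed <- which(remaining)[1]
    out[seed] <- phase[seed]
    remaining[seed] <- FALSE
    queue <- seed
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      ci <- arrayInd(cur, dims)
      for (ax in 1:3) for (dr in c(-1L, 1L)) {
        ok <- ci[, ax] + dr >= 1 & ci[, ax] + dr <= dims[ax]
        if (!any(ok)) next
        nb <- cur[ok] + dr * strides[ax]
        new <- nb[remaining[nb]]
        if (!length(new)) next
        src <- cur[ok][remaining[nb]]
        # nearest 2*pi branch to the source's unwrapped value
        dphi <- (phase[new] - out[src] + pi) %% (2 * pi) - pi
        out[new] <- out[src] + dphi
        remaining[new] <- FALSE
        queue <- c(queue, new)
      }
      queue <- unique(queue)
    }
  }
  out / 2 * 180 / pi
}

#' Assemble the six-feature table for sheetlet clustering
#'
#' Per myocardial voxel: spatial location (x, y, z, mm), unwrapped sheet
#' elevation and azimuth features, and normalized transmural depth, each with
#' its kernel bandwidth. The angle bandwidth defaults to 0.3 radians on the
#' doubled-angle scale (about 8.6 degrees in angle units); the literal value
#' 0.3 degrees is selectable via `angle_bandwidth_unit = "deg"` but leaves
#' the angle features dominating all others.
#'
#' @param se_star,sa_star Unwrapped SE/SA feature volumes (degrees), from
#'   [unwrap_angle_features()].
#' @param depth Normalized transmural depth volume.
#' @param mask Logical volume of clustered voxels.
#' @param voxel_size Voxel size, mm.
#' @param spatial_bandwidth Spatial kernel bandwidth, mm (default 10).
#' @param angle_bandwidth Angle bandwidth (default 0.3).
#' @param angle_bandwidth_unit `"rad_doubled"` (default) or `"deg"`.
#' @param depth_bandwidth Transmural-depth bandwidth (default 0.1 = 10%).
#' @return Object of class `feature_table`: `features` (n x 6 matrix),
#'   `bandwidths` (length 6), `voxel_index`, `dims`, `voxel_size`.
#' @export
feature_table <- function(se_star, sa_star, depth, mask, voxel_size = 1,
                          spatial_bandwidth = 10, angle_bandwidth = 0.3,
                          angle_bandwidth_unit = c("rad_doubled", "deg"),
                          depth_bandwidth = 0.1) {
  angle_bandwidth_unit <- match.arg(angle_bandwidth_unit)
  if (spatial_bandwidth <= 0 || angle_bandwidth <= 0 || depth_bandwidth <= 0)
    stop("bandwidths must be positive")
  bw_angle <- if (angle_bandwidth_unit == "rad_doubled")
    deg(angle_bandwidth) / 2 else angle_bandwidth
  dims <- dim(mask)
  idx <- which(mask & is.finite(se_star) & is.finite(sa_star) &
                 is.finite(depth))
  co <- arrayInd(idx, dims)
  F <- cbind(co[, 1] * voxel_size, co[, 2] * voxel_size,
             co[, 3] * voxel_size, se_star[idx], sa_star[idx], depth[idx])
  colnames(F) <- c("x", "y", "z", "se", "sa", "depth")
  out <- list(features = F,
              bandwidths = c(rep(spatial_bandwidth, 3), rep(bw_angle, 2),
                             depth_bandwidth),
              voxel_index = idx, dims = dims, voxel_size = voxel_size)
  class(out) <- "feature_table"
  out
}

#' Flat-kernel mean-shift clustering of sheetlet features
#'
#' Mean-shift with a flat kernel on bandwidth-scaled features: each point is
#' iterated to the mean of all points within the unit ball of the scaled
#' feature space until the shift falls below `tol` bandwidths. Converged
#' modes closer than half a bandwidth are merged (deterministic point
#' order), and every voxel is labelled by its mode.
#'
#' @param features A [feature_table()].
#' @param max_iter Iteration cap per point (default 300).
#' @param tol Convergence threshold, in bandwidth units (default 1e-3).
#' @return Object of class `cluster_label_map`: `labels` integer volume (NA
#'   outside), `n_clusters`, `modes` (cluster centres in original feature
#'   units), `voxel_size`, `audit` log.
#' @export
flat_meanshift <- function(features, max_iter = 300, tol = 1e-3) {
  stopifnot(inherits(features, "feature_table"))
  Fs <- sweep(features$features, 2, features$bandwidths, `/`)
  ms <- cpp_meanshift(Fs, as.integer(max_iter), tol)
  M <- ms$modes
  n <- nrow(M)
  lab <- integer(n)
  centres <- matrix(0, 0, ncol(M))
  for (i in seq_len(n)) {
    if (nrow(centres)) {
      d2 <- colSums((t(centres) - M[i, ])^2)
      j <- which.min(d2)
      if (d2[j] < 0.25) { lab[i] <- j; next }   # within half a bandwidth
    }
    centres <- rbind(centres, M[i, ])
    lab[i] <- nrow(centres)
  }
  labels <- array(NA_integer_, features$dims)
  labels[features$voxel_index] <- lab
  modes <- sweep(centres, 2, features$bandwidths, `*`)
  colnames(modes) <- colnames(features$features)
  out <- list(labels = labels, n_clusters = nrow(centres), modes = modes,
              voxel_size = features$voxel_size,
              audit = sprintf("mean-shift: %d points, %d clusters, %d iterations",
                              n, nrow(centres), ms$iterations))
  class(out) <- "cluster_label_map"
  out
}

#' @export
print.cluster_label_map <- function(x, ...) {
  cat(sprintf("cluster label map: %d clusters over %d voxels\n",
              x$n_clusters, sum(!is.na(x$labels))))
  for (a in x$audit) cat(" ", a, "\n")
  invisible(x)
}

# 26-neighbourhood contact counts of cluster `id` with other clusters
cluster_contacts <- function(labels, id) {
  dims <- dim(labels)
  vox <- which(labels == id)
  ci <- arrayInd(vox, dims)
  contacts <- integer(0)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- ci
    nb[, 1] <- nb[, 1] + dx; nb[, 2] <- nb[, 2] + dy; nb[, 3] <- nb[, 3] + dz
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
      nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lin <- nb[ok, 1] + dims[1] * (nb[ok, 2] - 1) +
      dims[1] * dims[2] * (nb[ok, 3] - 1)
    lv <- labels[lin]
    lv <- lv[!is.na(lv) & lv != id]
    contacts <- c(contacts, lv)
  }
  contacts
}

#' Merge clusters below a minimum volume
#'
#' Iteratively merges every cluster smaller than `min_volume_mm3` into the
#' neighbouring cluster sharing the largest 26-connectivity contact surface
#' (ties broken toward the larger cluster), until none remain below the
#' threshold. Labels are relabelled to contiguous positive integers.
#'
#' @param label_map A `cluster_label_map`.
#' @param min_volume_mm3 Volume threshold (default 0.1 mm^3).
#' @return The merged `cluster_label_map` with an updated audit log.
#' @export
merge_small_clusters <- function(label_map, min_volume_mm3 = 0.1) {
  stopifnot(inherits(label_map, "cluster_label_map"))
  labels <- label_map$labels
  vvol <- label_map$voxel_size^3
  log <- character(0)
  repeat {
    tb <- table(labels)
    vols <- as.numeric(tb) * vvol
    small <- names(tb)[vols < min_volume_mm3]
    if (length(small) == 0 || length(tb) <= 1) break
    # smallest first
    id <- as.integer(small[order(vols[match(small, names(tb))])][1])
    contacts <- cluster_contacts(labels, id)
    if (length(contacts) == 0) {
      # isolated sub-threshold cluster: nothing to merge into
      if (length(small) == 1) break
      labels[labels == id] <- NA_integer_  # unreachable; drop
      log <- c(log, sprintf("dropped isolated cluster %d", id))
      next
    }
    ct <- table(contacts)
    best <- as.integer(names(ct)[ct == max(ct)])
    if (length(best) > 1) {
      sizes <- as.numeric(tb[as.character(best)])
      best <- best[which.max(sizes)]
    }
    labels[labels == id] <- best
    log <- c(log, sprintf("merged cluster %d (%.3f mm^3) into %d",
                          id, vols[match(as.character(id), names(tb))], best))
  }
  old <- sort(unique(labels[!is.na(labels)]))
  relab <- labels
  for (k in seq_along(old)) relab[labels == old[k]] <- k
  out <- label_map
  out$labels <- relab
  out$n_clusters <- length(old)
  out$audit <- c(label_map$audit, log,
                 sprintf("merge: %d clusters remain", length(old)))
  out
}

#' 3x3x3 mode filter on a label volume
#'
#' Replaces each labelled voxel by the modal label of its 3^3 neighbourhood
#' (restricted to labelled voxels); ties keep the centre label.
#'
#' @param label_map A `cluster_label_map` (or integer volume).
#' @return The filtered object of the same type.
#' @export
mode_filter_3cubed <- function(label_map) {
  labels <- if (inherits(label_map, "cluster_label_map"))
    label_map$labels else label_map
  dims <- dim(labels)
  idx <- which(!is.na(labels))
  ci <- arrayInd(idx, dims)
  K <- max(labels, na.rm = TRUE)
  counts <- matrix(0L, length(idx), K)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    nb <- ci
    nb[, 1] <- nb[, 1] + dx; nb[, 2] <- nb[, 2] + dy; nb[, 3] <- nb[, 3] + dz
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
      nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lin <- nb[ok, 1] + dims[1] * (nb[ok, 2] - 1) +
      dims[1] * dims[2] * (nb[ok, 3] - 1)
    lv <- labels[lin]
    fine <- !is.na(lv)
    rows <- which(ok)[fine]
    counts[cbind(rows, lv[fine])] <- counts[cbind(rows, lv[fine])] + 1L
  }
  centre <- labels[idx]
  best <- max.col(counts, ties.method = "first")
  bestn <- counts[cbind(seq_along(idx), best)]
  centn <- counts[cbind(seq_along(idx), centre)]
  new <- ifelse(bestn > centn, best, centre)  # ties keep the centre label
  outlab <- labels
  outlab[idx] <- new
  if (inherits(label_map, "cluster_label_map")) {
    out <- label_map
    out$labels <- outlab
    out$audit <- c(label_map$audit,
                   sprintf("mode filter: %d voxels relabelled",
                           sum(new != centre)))
    out
  } else outlab
}

#' Per-cluster summary statistics
#'
#' @param label_map A `cluster_label_map`.
#' @param se,sa Optional SE/SA volumes for per-cluster circular means.
#' @return data.frame: cluster, voxels, volume_mm3, centroid, mean SE/SA.
#' @export
cluster_stats <- function(label_map, se = NULL, sa = NULL) {
  stopifnot(inherits(label_map, "cluster_label_map"))
  labels <- label_map$labels
  dims <- dim(labels)
  ids <- sort(unique(labels[!is.na(labels)]))
  vvol <- label_map$voxel_size^3
  do.call(rbind, lapply(ids, function(id) {
    vox <- which(labels == id)
    ci <- arrayInd(vox, dims)
    data.frame(cluster = id, voxels = length(vox),
               volume_mm3 = length(vox) * vvol,
               cx = mean(ci[, 1]) * label_map$voxel_size,
               cy = mean(ci[, 2]) * label_map$voxel_size,
               cz = mean(ci[, 3]) * label_map$voxel_size,
               mean_se = if (is.null(se)) NA_real_ else
                 axial_mean_deg(se[vox][is.finite(se[vox])]),
               mean_sa = if (is.null(sa)) NA_real_ else
                 axial_mean_deg(sa[vox][is.finite(sa[vox])]))
  }))
}
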