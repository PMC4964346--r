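# Deterministic RK2 streamline tracking on axial eigenvector fields and
# TrackVis-compatible output.

#' RK2 streamline tracking of an axial vector field
#'
#' Midpoint (2nd-order Runge-Kutta) integration with trilinear interpolation
#' of the sign-aligned vector field. At every evaluation the interpolated
#' vector is aligned with the incoming direction, so fields that differ only
#' by per-voxel sign flips yield identical tracks. Growth is bidirectional
#' from each seed; a track terminates on mask exit, turning angle above the
#' threshold, a zero interpolated vector, or the step cap.
#'
#' @param vector_field (x,y,z,3) array of unit axial vectors.
#' @param mask Logical tracking mask.
#' @param seeds n x 3 matrix of 1-based voxel coordinates (may be fractional);
#'   default one seed per mask voxel.
#' @param step_mm Integration step (default half a voxel).
#' @param angle_threshold_deg Maximum turning angle per step (default 35).
#' @param min_length_mm Minimum track length kept (default 0.5).
#' @param voxel_size Voxel size, mm.
#' @param max_steps Per-direction step cap.
#' @return Object of class `track_set`: `tracks` (list of m x 3 matrices,
#'   world mm = (voxel index - 1) * voxel_size), `seed_id`, parameters.
#' @export
rk2_streamlines <- function(vector_field, mask, seeds = NULL,
                            step_mm = NULL, angle_threshold_deg = 35,
                            min_length_mm = 0.5, voxel_size = 1,
                            max_steps = 5000) {
  dims <- dim(vector_field)[1:3]
  stopifnot(all(dim(mask) == dims))
  if (is.null(step_mm)) step_mm <- 0.5 * voxel_size
  if (is.null(seeds)) seeds <- which(mask, arr.ind = TRUE)
  seeds <- matrix(as.numeric(seeds), ncol = 3)
  fld <- aperm(vector_field, c(1, 2, 3, 4))
  res <- cpp_streamlines(as.numeric(fld), as.integer(mask), as.integer(dims),
                         seeds - 1, step_mm / voxel_size,
                         angle_threshold_deg, as.integer(max_steps))
  lens <- vapply(res, nrow, integer(1))
  keep <- (lens - 1) * step_mm >= min_length_mm & lens >= 2
  tracks <- lapply(res[keep], function(m) m * voxel_size)
  out <- list(tracks = tracks, seed_id = which(keep),
              seeds = seeds[keep, , drop = FALSE],
              step_mm = step_mm, angle_threshold_deg = angle_threshold_deg,
              min_length_mm = min_length_mm, voxel_size = voxel_size,
              dims = dims)
  class(out) <- "track_set"
  out
}

#' @export
print.track_set <- function(x, ...) {
  n <- length(x$tracks)
  if (n == 0) { cat("track set: 0 tracks\n"); return(invisible(x)) }
  len <- vapply(x$tracks, function(m) (nrow(m) - 1) * x$step_mm, numeric(1))
  cat(sprintf("track set: %d tracks, length %.2f-%.2f mm (median %.2f)\n",
              n, min(len), max(len), median(len)))
  invisible(x)
}

#' Select tracks seeded in chosen sheetlet clusters
#'
#' @param tracks A `track_set` (e.g. v1 tracks).
#' @param cluster_labels A `cluster_label_map` (or integer label volume).
#' @param selected_clusters Integer cluster ids to keep.
#' @return A `track_set` restricted to tracks whose seed voxel carries one of
#'   the selected labels.
#' @export
cluster_seeded_tracks <- function(tracks, cluster_labels, selected_clusters) {
  stopifnot(inherits(tracks, "track_set"))
  lab <- if (inherits(cluster_labels, "cluster_label_map"))
    cluster_labels$labels else cluster_labels
  present <- unique(lab[!is.na(lab)])
  unknown <- setdiff(selected_clusters, present)
  if (length(unknown))
    stop("unknown cluster id(s): ", paste(unknown, collapse = ", "))
  if (length(tracks$tracks) == 0 || length(selected_clusters) == 0) {
    out <- tracks
    out$tracks <- list(); out$seed_id <- integer(0)
    out$seeds <- tracks$seeds[0, , drop = FALSE]
    return(out)
  }
  sv <- round(tracks$seeds)
  lin <- sv[, 1] + dim(lab)[1] * (sv[, 2] - 1) +
    dim(lab)[1] * dim(lab)[2] * (sv[, 3] - 1)
  keep <- lab[lin] %in% selected_clusters
  keep[is.na(keep)] <- FALSE
  out <- tracks
  out$tracks <- tracks$tracks[keep]
  out$seed_id <- tracks$seed_id[keep]
  out$seeds <- tracks$seeds[keep, , drop = FALSE]
  out
}

#' Write tracks in TrackVis .trk format
#'
#' Binary little-endian .trk (version 2) with the voxel-to-mm header taken
#' from the isotropic voxel size; point coordinates follow the TrackVis
#' voxel-mm convention (voxel index + 0.5, times voxel size).
#'
#' @param tracks A `track_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trk <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_set"))
  vs <- tracks$voxel_size
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s, n) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(n - length(raw))), con)
  }
  wchar("TRACK", 6)
  writeBin(as.integer(tracks$dims), con, size = 2, endian = "little")
  writeBin(rep(vs, 3), con, size = 4, endian = "little")
  writeBin(rep(0, 3), con, size = 4, endian = "little")      # origin
  writeBin(0L, con, size = 2, endian = "little")             # n_scalars
  wchar("", 200)                                             # scalar names
  writeBin(0L, con, size = 2, endian = "little")             # n_properties
  wchar("", 200)                                             # property names
  m <- diag(c(vs, vs, vs, 1))                                # vox to ras
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  wchar("", 444)                                             # reserved
  wchar("RAS", 4)                                            # voxel order
  wchar("", 4)                                               # pad2
  writeBin(rep(0, 6), con, size = 4, endian = "little")      # image orient
  wchar("", 2 + 6)                                           # pads
  writeBin(as.integer(c(length(tracks$tracks), 2L, 1000L)), con,
           size = 4, endian = "little")
  for (tr in tracks$tracks) {
    writeBin(nrow(tr), con, size = 4, endian = "little")
    pts <- (tr / vs + 0.5) * vs                              # voxel-mm
    writeBin(as.numeric(t(pts)), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Export tracks as a CSV polyline table
#'
#' @param tracks A `track_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_set"))
  df <- do.call(rbind, lapply(seq_along(tracks$tracks), function(i) {
    m <- tracks$tracks[[i]]
    data.frame(track = i, vertex = seq_len(nrow(m)),
               x = m[, 1], y = m[, 2], z = m[, 3])
  }))
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
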