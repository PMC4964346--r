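# AHA 17-segment labelling, transmural profiles and angle histograms.

#' AHA 17-segment labels for the LV myocardium
#'
#' Splits the long-axis extent of the LV wall (above the apical cap) into
#' basal, mid-cavity and apical thirds, with 6/6/4 circumferential sectors
#' measured from the anterior RV-insertion landmark: basal 1-6, mid 7-12,
#' apical 13-16. Segment 17 is the apical cap: wall voxels distal to the
#' apical extent of the LV cavity.
#'
#' @param mask Logical LV myocardium volume.
#' @param l_global Unit long axis (apex to base).
#' @param landmark RV-insertion landmark, world mm relative to the volume
#'   centre (as emitted by the phantom).
#' @param voxel_size Voxel size, mm.
#' @param cavity_mask Optional LV cavity mask defining the apical cap; when
#'   absent (or when the cavity spans the full wall) segment 17 is empty.
#' @return Object of class `aha_label_map`: `labels` integer volume (NA
#'   outside the mask), `landmark_angle`, `thirds` (long-axis cut points).
#' @export
aha17_labels <- function(mask, l_global, landmark, voxel_size = 1,
                         cavity_mask = NULL) {
  dims <- dim(mask)
  l_global <- unit(l_global)
  idx <- which(mask)
  if (length(idx) == 0) stop("empty LV mask")
  co <- which(mask, arr.ind = TRUE)
  centre <- (dims + 1) / 2
  P <- sweep(co, 2, centre) * voxel_size
  t_ax <- as.numeric(P %*% l_global)
  # in-plane angle from the landmark direction
  lm_perp <- landmark - sum(landmark * l_global) * l_global
  if (vnorm(lm_perp) < voxel_size / 2)
    stop("landmark lies on the long axis")
  e1 <- unit(lm_perp)
  e2 <- pracma_cross(l_global, e1)
  Pp <- P - outer(t_ax, l_global)
  theta <- atan2(Pp %*% e2, Pp %*% e1) %% (2 * pi)
  # apical cap: distal to the cavity's apical extent
  cap <- rep(FALSE, length(idx))
  if (!is.null(cavity_mask) && any(cavity_mask)) {
    cc <- which(cavity_mask, arr.ind = TRUE)
    t_cav_min <- min(sweep(cc, 2, centre) %*% l_global) * voxel_size
    cap <- t_ax < t_cav_min
  }
  lab <- integer(length(idx))
  lab[cap] <- 17L
  body <- !cap
  t_body <- t_ax[body]
  t0 <- min(t_body); t1 <- max(t_body)
  third <- findInterval(t_body, c(t0 + (t1 - t0) / 3, t0 + 2 * (t1 - t0) / 3))
  # third: 0 apical, 1 mid, 2 basal (long axis points to base)
  th_b <- theta[body]
  sec6 <- pmin(floor(th_b / (pi / 3)), 5)
  sec4 <- pmin(floor(th_b / (pi / 2)), 3)
  lab[body] <- ifelse(third == 2L, 1L + sec6,
                      ifelse(third == 1L, 7L + sec6, 13L + sec4))
  labels <- array(NA_integer_, dims)
  labels[idx] <- lab
  out <- list(labels = labels, landmark_angle = atan2(sum(lm_perp * e2),
                                                      sum(lm_perp * e1)),
              l_global = l_global,
              thirds = c(t0 + (t1 - t0) / 3, t0 + 2 * (t1 - t0) / 3))
  class(out) <- "aha_label_map"
  out
}

# minimal cross product (named to avoid masking base)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.aha_label_map <- function(x, ...) {
  tb <- table(x$labels)
  cat("AHA-17 labels:", paste(sprintf("%s:%d", names(tb), tb), collapse = " "),
      "\n")
  invisible(x)
}

#' Transmural profiles of the angle maps per AHA segment
#'
#' Bins each angle against normalized transmural depth within each segment,
#' takes circular (doubled-angle) means per bin, unwraps the bin sequence so
#' ranges beyond 90 degrees are representable, and fits an ordinary linear
#' model of angle against depth. Linearity is the fit R^2 and the transmural
#' range is the fitted-line endpoint difference over depth 0 to 1.
#'
#' @param angles An `angle_maps` object.
#' @param depth Transmural depth volume (0 endo to 1 epi), e.g. `phi` of
#'   [solve_laplace_depth()].
#' @param labels An `aha_label_map` (or integer volume).
#' @param n_bins Number of depth bins covering `[0, 1]` (default 10).
#' @param min_bins Minimum populated bins for a valid profile (default 5).
#' @return data.frame: `segment`, `angle`, `n_voxels`, `n_bins`,
#'   `r_squared`, `range_deg`, `flag`; bin-level means in
#'   `attr(, "bins")`.
#' @export
transmural_profiles <- function(angles, depth, labels, n_bins = 10,
                                min_bins = 5) {
  stopifnot(inherits(angles, "angle_maps"))
  lab <- if (inherits(labels, "aha_label_map")) labels$labels else labels
  ok <- angles$mask & !angles$flagged & !is.na(lab) & is.finite(depth)
  segs <- sort(unique(lab[ok]))
  edges <- seq(0, 1, length.out = n_bins + 1)
  centres <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  rows <- list()
  bins <- list()
  for (sg in segs) {
    insg <- ok & lab == sg
    d <- depth[insg]
    bin <- pmin(pmax(findInterval(d, edges, rightmost.closed = TRUE), 1),
                n_bins)
    for (an in c("HA", "TA", "SE", "SA")) {
      a <- angles[[an]][insg]
      keep <- is.finite(a)
      bm <- vapply(seq_len(n_bins), function(b) {
        v <- a[keep & bin == b]
        if (length(v) == 0) NA_real_ else axial_mean_deg(v)
      }, numeric(1))
      # regress against the within-bin mean depth, not the bin centre:
      # exact for ramps under nonuniform transmural sampling
      bd <- vapply(seq_len(n_bins), function(b) {
        v <- d[keep & bin == b]
        if (length(v) == 0) NA_real_ else mean(v)
      }, numeric(1))
      pop <- which(is.finite(bm))
      if (length(pop) < min_bins) {
        rows[[length(rows) + 1]] <- data.frame(
          segment = sg, angle = an, n_voxels = sum(keep),
          n_bins = length(pop), r_squared = NA_real_, range_deg = NA_real_,
          flag = "missing")
        next
      }
      # unwrap the bin sequence on the 180-degree axial circle
      bu <- bm[pop]
      if (length(bu) > 1) {
        dstep <- fold90(diff(bu))
        bu <- bu[1] + c(0, cumsum(dstep))
      }
      fit <- lm(bu ~ bd[pop])
      sl <- coef(fit)[2]
      ssr <- sum(residuals(fit)^2)
      sst <- sum((bu - mean(bu))^2)
      flag <- "ok"
      r2 <- if (sst < 1e-12) { flag <- "zero-variance"; 0 } else 1 - ssr / sst
      rows[[length(rows) + 1]] <- data.frame(
        segment = sg, angle = an, n_voxels = sum(keep),
        n_bins = length(pop), r_squared = r2, range_deg = unname(sl),
        flag = flag)
      bins[[length(bins) + 1]] <- data.frame(
        segment = sg, angle = an, bin_centre = centres[pop],
        depth = bd[pop], mean_deg = bu)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "bins") <- do.call(rbind, bins)
  out
}

#' Reshape transmural profiles to a per-segment summary table
#'
#' One row per AHA segment with linearity (R^2) and transmural range
#' (degrees) columns for each of HA, TA, SE and SA, suitable for CSV export.
#'
#' @param profiles Output of [transmural_profiles()].
#' @param path Optional CSV path to write.
#' @return A data.frame (invisibly when `path` is given).
#' @export
profile_summary_table <- function(profiles, path = NULL) {
  segs <- sort(unique(profiles$segment))
  out <- data.frame(segment = segs)
  for (an in c("HA", "TA", "SE", "SA")) {
    sub <- profiles[profiles$angle == an, ]
    out[[paste0(tolower(an), "_linearity")]] <-
      sub$r_squared[match(segs, sub$segment)]
    out[[paste0(tolower(an), "_range_deg")]] <-
      sub$range_deg[match(segs, sub$segment)]
  }
  if (!is.null(path)) {
    write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}

#' Per-segment angle histograms
#'
#' Normalized counts over (-90, 90] per AHA segment, with peak-bin location
#' and a circular skewness measure computed on the doubled angles.
#'
#' @param angles An `angle_maps` object.
#' @param labels An `aha_label_map` (or integer volume).
#' @param bin_width Bin width in degrees (default 5).
#' @return data.frame of `segment`, `angle`, `bin_centre`, `density`;
#'   per-segment `peak_deg` and `circ_skew` in `attr(, "summary")`.
#' @export
angle_histograms <- function(angles, labels, bin_width = 5) {
  stopifnot(inherits(angles, "angle_maps"))
  lab <- if (inherits(labels, "aha_label_map")) labels$labels else labels
  ok <- angles$mask & !angles$flagged & !is.na(lab)
  edges <- seq(-90, 90, by = bin_width)
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  rows <- list(); summ <- list()
  for (sg in sort(unique(lab[ok]))) {
    for (an in c("HA", "TA", "SE", "SA")) {
      a <- angles[[an]][ok & lab == sg]
      a <- a[is.finite(a)]
      if (length(a) == 0) next
      # (-90, 90]: left-open bins
      cnt <- tabulate(pmin(pmax(ceiling((a + 90) / bin_width), 1),
                           length(centres)), nbins = length(centres))
      dens <- cnt / sum(cnt)
      rows[[length(rows) + 1]] <- data.frame(
        segment = sg, angle = an, bin_centre = centres, density = dens)
      t2 <- rad(2 * a)
      m1 <- atan2(mean(sin(t2)), mean(cos(t2)))
      r1 <- sqrt(mean(sin(t2))^2 + mean(cos(t2))^2)
      skew <- mean(sin(2 * (t2 - m1))) / max(1 - r1, 1e-12)^1.5
      summ[[length(summ) + 1]] <- data.frame(
        segment = sg, angle = an, peak_deg = centres[which.max(dens)],
        circ_skew = skew, n = length(a))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- do.call(rbind, summ)
  out
}
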