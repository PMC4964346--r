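# Acquisition-physics model: PGSE + crusher waveforms, effective b-matrix with
# cross-terms, prospective gradient adjustment, calibration.

#' Pulsed-gradient spin-echo sequence timing
#'
#' Describes one diffusion-weighted acquisition: a rectangular PGSE diffusion
#' gradient pair (duration `delta`, separation `Delta`, amplitude
#' `g_amplitude` along `direction`) placed symmetrically about the refocusing
#' pulse, plus an optional symmetric rectangular crusher pair flanking the
#' refocusing pulse. Times are in ms, amplitudes in T/m. Time zero is the
#' centre of the refocusing pulse; the effective gradient polarity is inverted
#' after it.
#'
#' @param delta Diffusion gradient duration, ms.
#' @param Delta Diffusion time (lobe start-to-start separation), ms.
#' @param g_amplitude Diffusion gradient amplitude, T/m.
#' @param direction Unit 3-vector of the diffusion gradient.
#' @param crusher_amplitude Crusher amplitude, T/m (0 disables crushers).
#' @param crusher_duration Crusher lobe duration, ms.
#' @param crusher_gap Gap between refocusing pulse centre and each crusher
#'   lobe, ms.
#' @param crusher_axis Unit 3-vector of the crusher gradient (default +z).
#' @param gyromagnetic_ratio rad/(s T); default is that of 1H.
#' @return An object of class `sequence_timing`.
#' @export
sequence_timing <- function(delta = 2, Delta = 5.5, g_amplitude = 0,
                            direction = c(1, 0, 0),
                            crusher_amplitude = 0, crusher_duration = 1.5,
                            crusher_gap = 0.2, crusher_axis = c(0, 0, 1),
                            gyromagnetic_ratio = GAMMA_1H) {
  stopifnot(delta > 0, delta <= Delta, g_amplitude >= 0,
            crusher_amplitude >= 0, crusher_duration > 0, crusher_gap >= 0)
  obj <- list(delta = delta, Delta = Delta, g_amplitude = g_amplitude,
              direction = unit(direction),
              crusher_amplitude = crusher_amplitude,
              crusher_duration = crusher_duration,
              crusher_gap = crusher_gap,
              crusher_axis = unit(crusher_axis),
              gyromagnetic_ratio = gyromagnetic_ratio)
  class(obj) <- "sequence_timing"
  obj
}

#' @export
print.sequence_timing <- function(x, ...) {
  cat(sprintf("PGSE sequence: delta=%g ms, Delta=%g ms, G=%g T/m\n",
              x$delta, x$Delta, x$g_amplitude))
  if (x$crusher_amplitude > 0)
    cat(sprintf("  crushers: %g T/m x %g ms (gap %g ms) along [%s]\n",
                x$crusher_amplitude, x$crusher_duration, x$crusher_gap,
                paste(signif(x$crusher_axis, 3), collapse = ", ")))
  invisible(x)
}

# effective-gradient lobe table: times ms relative to the refocusing pulse,
# amplitudes T/m with the post-refocus sign inversion already applied
effective_lobes <- function(seq) {
  d2 <- seq$Delta / 2
  h2 <- seq$delta / 2
  lob <- list(
    list(t0 = -d2 - h2, t1 = -d2 + h2,
         g = seq$g_amplitude * seq$direction, source = "diffusion"),
    list(t0 = d2 - h2, t1 = d2 + h2,
         g = -seq$g_amplitude * seq$direction, source = "diffusion"))
  if (seq$crusher_amplitude > 0) {
    cd <- seq$crusher_duration
    gp <- seq$crusher_gap
    lob <- c(lob, list(
      list(t0 = -gp - cd, t1 = -gp,
           g = seq$crusher_amplitude * seq$crusher_axis, source = "imaging"),
      list(t0 = gp, t1 = gp + cd,
           g = -seq$crusher_amplitude * seq$crusher_axis, source = "imaging")))
  }
  # reject temporally overlapping lobes: the lobe table would be ambiguous
  n <- length(lob)
  if (n > 1) {
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      if (lob[[a]]$t0 < lob[[b]]$t1 - 1e-12 && lob[[b]]$t0 < lob[[a]]$t1 - 1e-12)
        stop("overlapping gradient lobes: waveform is ambiguous")
    }
  }
  lob
}

#' Effective b-matrix components of a sequence
#'
#' Integrates q(t) = gamma * integral of the effective gradient and decomposes
#' b = integral of q q^T dt by waveform source: diffusion lobes, imaging
#' (crusher) lobes, and their interaction. The piecewise-polynomial integration
#' is exact for piecewise-constant gradients. Scalar components are traces of
#' the corresponding 3x3 b-matrices, in s/mm^2, and satisfy
#' `b_effective = b_diffusion + b_imaging + b_cross` to rounding error.
#'
#' @param seq A [sequence_timing()] object.
#' @return An object of class `b_components` with scalar fields `b_diffusion`,
#'   `b_imaging`, `b_cross`, `b_effective` and 3x3 matrices `B_diffusion`,
#'   `B_imaging`, `B_cross`, `B_effective` (s/mm^2).
#' @export
compute_b_components <- function(seq) {
  stopifnot(inherits(seq, "sequence_timing"))
  lob <- effective_lobes(seq)
  brk <- sort(unique(c(sapply(lob, `[[`, "t0"), sapply(lob, `[[`, "t1"))))
  gam <- seq$gyromagnetic_ratio
  qd <- qi <- c(0, 0, 0)              # rad/m
  Bdd <- Bii <- Bdi <- matrix(0, 3, 3)
  seg_int <- function(a, ga, b, gb, h) {
    # int_0^h (a + ga t)(b + gb t)^T dt
    tcrossprod(a, b) * h +
      (tcrossprod(a, gb) + tcrossprod(ga, b)) * h^2 / 2 +
      tcrossprod(ga, gb) * h^3 / 3
  }
  for (k in seq_len(length(brk) - 1)) {
    t0 <- brk[k]; t1 <- brk[k + 1]
    h <- (t1 - t0) * 1e-3             # s
    gd <- gi <- c(0, 0, 0)
    for (l in lob) {
      if (l$t0 <= t0 + 1e-12 && l$t1 >= t1 - 1e-12) {
        if (l$source == "diffusion") gd <- gd + l$g else gi <- gi + l$g
      }
    }
    sd_ <- gam * gd                    # dq/dt, rad/(m s)
    si_ <- gam * gi
    Bdd <- Bdd + seg_int(qd, sd_, qd, sd_, h)
    Bii <- Bii + seg_int(qi, si_, qi, si_, h)
    Bdi <- Bdi + seg_int(qd, sd_, qi, si_, h) + seg_int(qi, si_, qd, sd_, h)
    qd <- qd + sd_ * h
    qi <- qi + si_ * h
  }
  # s/m^2 -> s/mm^2
  Bdd <- Bdd / 1e6; Bii <- Bii / 1e6; Bdi <- Bdi / 1e6
  out <- list(B_diffusion = Bdd, B_imaging = Bii, B_cross = Bdi,
              B_effective = Bdd + Bii + Bdi,
              b_diffusion = sum(diag(Bdd)), b_imaging = sum(diag(Bii)),
              b_cross = sum(diag(Bdi)),
              b_effective = sum(diag(Bdd + Bii + Bdi)))
  class(out) <- "b_components"
  out
}

#' @export
print.b_components <- function(x, ...) {
  cat(sprintf(
    "b components (s/mm^2): diffusion %.3f + imaging %.3f + cross %.3f = %.3f\n",
    x$b_diffusion, x$b_imaging, x$b_cross, x$b_effective))
  invisible(x)
}

#' Diffusion gradient amplitude giving a target Stejskal-Tanner b-value
#'
#' Closed form G = sqrt(b / (gamma^2 delta^2 (Delta - delta/3))) for the
#' rectangular PGSE pair, ignoring crushers and cross-terms.
#'
#' @param seq A [sequence_timing()] template.
#' @param b_target Target b_diffusion, s/mm^2.
#' @return Gradient amplitude in T/m.
#' @export
stejskal_tanner_amplitude <- function(seq, b_target) {
  stopifnot(b_target >= 0)
  gam <- seq$gyromagnetic_ratio
  dl <- seq$delta * 1e-3
  DL <- seq$Delta * 1e-3
  sqrt(b_target * 1e6 / (gam^2 * dl^2 * (DL - dl / 3)))
}

#' Crusher amplitude giving a target b_imaging
#'
#' Solves the quadratic dependence of the crusher self-term on amplitude.
#'
#' @param seq A [sequence_timing()] template.
#' @param b_imaging_target Target crusher contribution, s/mm^2 (e.g. 61 for
#'   the strong-crusher protocol or 12 for the minimized-crusher one).
#' @return The `sequence_timing` with `crusher_amplitude` set.
#' @export
calibrate_crusher <- function(seq, b_imaging_target) {
  stopifnot(b_imaging_target >= 0)
  probe <- seq
  probe$crusher_amplitude <- 1
  probe$g_amplitude <- 0
  b1 <- compute_b_components(probe)$b_imaging
  seq$crusher_amplitude <- sqrt(b_imaging_target / b1)
  seq
}

#' Diffusion gradient scheme
#'
#' Non-diffusion-weighted (b0) volume count, unit DW directions and the nominal
#' b-value. The default 61-direction set is an electrostatic-repulsion table
#' shipped with the package.
#'
#' @param n_b0 Number of b=0 volumes (default 8).
#' @param directions n x 3 matrix of unit DW directions.
#' @param b_nominal Nominal b-value, s/mm^2 (default 1000).
#' @return Object of class `gradient_scheme`.
#' @export
gradient_scheme <- function(n_b0 = 8, directions = default_directions61(),
                            b_nominal = 1000) {
  directions <- as.matrix(directions)
  stopifnot(ncol(directions) == 3, n_b0 >= 1, b_nominal > 0)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("gradient directions must be unit vectors")
  directions <- directions / nrm
  obj <- list(n_b0 = as.integer(n_b0), directions = directions,
              b_nominal = b_nominal)
  class(obj) <- "gradient_scheme"
  obj
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("gradient scheme: %d b0 + %d DW directions at b=%g s/mm^2\n",
              x$n_b0, nrow(x$directions), x$b_nominal))
  invisible(x)
}

#' @rdname gradient_scheme
#' @export
default_directions61 <- function() {
  f <- system.file("extdata", "dwdirs61.txt", package = "cardiacdti",
                   mustWork = TRUE)
  as.matrix(read.table(f))
}

n_volumes <- function(scheme) scheme$n_b0 + nrow(scheme$directions)

#' Prospectively adjust the diffusion gradient amplitude per direction
#'
#' For each DW direction the diffusion gradient strength G is updated by Newton
#' iteration on the effective b-value (a quadratic in G: the diffusion
#' self-term scales as G^2 and the cross-term with the fixed crushers as G)
#' until `|b_effective - b_nominal| < tolerance_frac * b_nominal`, mirroring
#' the on-scanner adjustment.
#'
#' @param scheme A [gradient_scheme()].
#' @param seq_template A [sequence_timing()] carrying timing and crushers; its
#'   `g_amplitude`/`direction` are replaced per direction.
#' @param tolerance_frac Convergence tolerance as a fraction of `b_nominal`
#'   (default 0.001).
#' @return A list with `table` (data.frame per direction: g_unadjusted,
#'   g_adjusted, b_diffusion, b_imaging, b_cross, b_effective, iterations) and
#'   `sequences`, the adjusted per-direction `sequence_timing` objects.
#' @export
prospective_adjust <- function(scheme, seq_template, tolerance_frac = 0.001) {
  stopifnot(inherits(scheme, "gradient_scheme"),
            inherits(seq_template, "sequence_timing"), tolerance_frac > 0)
  bi <- {
    s0 <- seq_template; s0$g_amplitude <- 0
    compute_b_components(s0)$b_imaging
  }
  if (scheme$b_nominal <= bi)
    stop("b_nominal does not exceed b_imaging: target unreachable")
  g0 <- stejskal_tanner_amplitude(seq_template, scheme$b_nominal)
  n <- nrow(scheme$directions)
  tab <- data.frame(g_unadjusted = rep(g0, n), g_adjusted = NA_real_,
                    b_diffusion = NA_real_, b_imaging = NA_real_,
                    b_cross = NA_real_, b_effective = NA_real_,
                    iterations = NA_integer_)
  seqs <- vector("list", n)
  for (i in seq_len(n)) {
    sq <- seq_template
    sq$direction <- scheme$directions[i, ]
    # coefficients of the exact quadratic b_eff(G) = alpha G^2 + beta G + bi
    sq$g_amplitude <- 1
    b1 <- compute_b_components(sq)
    alpha <- b1$b_diffusion
    beta <- b1$b_cross
    disc <- beta^2 + 4 * alpha * (scheme$b_nominal - bi)
    if (disc < 0)
      stop(sprintf("adjustment target unreachable for direction %d", i))
    g <- (-beta + sqrt(disc)) / (2 * alpha)
    it <- 0L
    repeat {
      it <- it + 1L
      sq$g_amplitude <- g
      bc <- compute_b_components(sq)
      err <- bc$b_effective - scheme$b_nominal
      if (abs(err) < tolerance_frac * scheme$b_nominal || it >= 50L) break
      g <- g - err / (2 * alpha * g + beta)   # Newton, analytic derivative
    }
    if (abs(bc$b_effective - scheme$b_nominal) >=
        tolerance_frac * scheme$b_nominal)
      stop(sprintf("adjustment failed to converge for direction %d", i))
    tab$g_adjusted[i] <- g
    tab$b_diffusion[i] <- bc$b_diffusion
    tab$b_imaging[i] <- bc$b_imaging
    tab$b_cross[i] <- bc$b_cross
    tab$b_effective[i] <- bc$b_effective
    tab$iterations[i] <- it
    seqs[[i]] <- sq
  }
  list(table = tab, sequences = seqs)
}

#' Combine reversed-polarity acquisitions
#'
#' Voxelwise geometric mean of two DWI stacks acquired with opposite diffusion
#' gradient polarity. Under the monoexponential signal model the
#' imaging-diffusion cross-term enters with opposite sign in the two scans, so
#' sqrt(exp(-(b+c)D) * exp(-(b-c)D)) = exp(-bD) cancels it exactly.
#'
#' @param signal_plus,signal_minus `dwi_stack` objects whose schemes agree up
#'   to the sign of the DW directions.
#' @return A `dwi_stack` with the combined signal; voxels that are zero in
#'   either input are zero in the output and counted in `attr(,"n_zero")`.
#' @export
combine_reversed_polarity <- function(signal_plus, signal_minus) {
  stopifnot(inherits(signal_plus, "dwi_stack"),
            inherits(signal_minus, "dwi_stack"))
  if (!all(dim(signal_plus$data) == dim(signal_minus$data)))
    stop("reversed-polarity stacks have mismatched dimensions")
  dp <- signal_plus$scheme$directions
  dm <- signal_minus$scheme$directions
  if (nrow(dp) != nrow(dm) || max(abs(dp + dm)) > 1e-6)
    stop("schemes are not related by direction sign reversal")
  out <- signal_plus
  zero <- signal_plus$data == 0 | signal_minus$data == 0
  out$data <- sqrt(pmax(signal_plus$data, 0) * pmax(signal_minus$data, 0))
  out$data[zero] <- 0
  attr(out, "n_zero") <- sum(zero)
  out
}

#' Gradient scaling calibration factors from a reference phantom
#'
#' The apparent diffusivity measured along one gradient axis scales with the
#' square of the actual gradient amplitude, so the actual per-axis scaling is
#' s_i = sqrt(D_measured,i / D_reference) and the multiplicative correction to
#' the commanded amplitude is 1/s_i.
#'
#' @param measured_adc_xyz Length-3 vector of diffusivities measured along the
#'   x, y, z gradient axes.
#' @param reference_adc Reference diffusivity of the phantom liquid at the
#'   measured temperature (same units).
#' @return Object of class `calibration_factors`: list with `scale` (length-3
#'   correction factors) and `actual_scale` (the inferred per-axis gradient
#'   scaling).
#' @export
gradient_calibration_factors <- function(measured_adc_xyz, reference_adc) {
  stopifnot(length(measured_adc_xyz) == 3)
  if (any(measured_adc_xyz <= 0) || reference_adc <= 0)
    stop("diffusivities must be positive")
  s <- sqrt(measured_adc_xyz / reference_adc)
  out <- list(scale = setNames(1 / s, c("x", "y", "z")),
              actual_scale = setNames(s, c("x", "y", "z")))
  class(out) <- "calibration_factors"
  out
}

#' @export
print.calibration_factors <- function(x, ...) {
  cat(sprintf("gradient calibration factors: x %.4f, y %.4f, z %.4f\n",
              x$scale[1], x$scale[2], x$scale[3]))
  invisible(x)
}

#' Reference diffusivity of the calibration liquid at a given temperature
#'
#' Linear interpolation of the cyclooctane reference table shipped with the
#' package. The shipped table is a synthetic stand-in of plausible magnitude
#' and slope; substitute laboratory reference data for real calibration.
#'
#' @param temperature_C Temperature in degrees Celsius.
#' @param table Optional two-column data.frame (temperature_C,
#'   diffusivity_1e3mm2s) overriding the shipped fixture.
#' @return Diffusivity in 10^-3 mm^2/s.
#' @export
reference_diffusivity <- function(temperature_C, table = NULL) {
  if (is.null(table)) {
    f <- system.file("extdata", "cyclooctane_diffusivity_synthetic.tsv",
                     package = "cardiacdti", mustWork = TRUE)
    table <- read.table(f, header = TRUE)
  }
  stats::approx(table[[1]], table[[2]], xout = temperature_C, rule = 2)$y
}
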