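# DW signal synthesis, receiver gain chain and temperature-drift models.

#' Synthesize a diffusion-weighted image stack from phantom truth
#'
#' Evaluates the monoexponential tensor model S = S0 exp(-B:D) per voxel and
#' volume. The actual gradient vectors are `diag(gradient_scale) %*% u`, so a
#' miscalibrated scanner is simulated by scaling the gradients while the
#' *nominal* b-matrices (from the unscaled scheme) are reported in the output
#' stack — exactly the situation of fitting poorly calibrated data. Rician
#' noise adds independent complex Gaussian channels and takes the magnitude;
#' the channel sigma is set so that mean myocardial S0 divided by the
#' standard deviation of the paired noise-only *magnitude* volume equals
#' `snr_b0` — i.e. SNR is defined exactly as it is measured, against
#' magnitude noise data (for Rician noise the magnitude sd is
#' sigma * sqrt(2 - pi/2)). `snr_dw` optionally sets a separate (smaller)
#' sigma for the DW volumes relative to the mean myocardial DW signal,
#' emulating a higher DW receiver gain.
#'
#' @param truth A [generate_lv_phantom()] result.
#' @param scheme A [gradient_scheme()].
#' @param snr_b0 SNR of the non-DW volumes against mean myocardial S0
#'   (ignored when `noise_model = "none"`).
#' @param noise_model `"none"`, `"rician"` or `"gaussian"`.
#' @param gradient_scale Per-axis actual gradient scaling (default exact
#'   calibration `c(1,1,1)`; the offset scan uses `c(1, 0.9, 0.9)`).
#' @param seed Integer seed for the noise stream.
#' @param snr_dw Optional SNR of the DW volumes against the mean myocardial DW
#'   signal; `NULL` reuses the b0 noise sigma.
#' @param b_per_direction Optional per-direction effective b-values replacing
#'   `scheme$b_nominal` (e.g. an unadjusted scan's variable b).
#' @param volume_scale Optional per-volume multiplicative diffusivity scale
#'   (e.g. a temperature schedule); length = number of volumes.
#' @return Object of class `dwi_stack`: `data` (x,y,z,volume), `scheme`,
#'   `b_matrices` (volumes x 6: xx,yy,zz,xy,xz,yz in s/mm^2, nominal),
#'   `voxel_size`, `noise_volume` (b0 gain), `noise_volume_dw` (DW gain),
#'   `noise_sd` (per volume), `myocardium_mask`.
#' @export
synthesize_dwi <- function(truth, scheme, snr_b0 = NULL,
                           noise_model = c("none", "rician", "gaussian"),
                           gradient_scale = c(1, 1, 1), seed = 1L,
                           snr_dw = NULL, b_per_direction = NULL,
                           volume_scale = NULL) {
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(truth, "phantom_truth"), inherits(scheme, "gradient_scheme"))
  if (any(gradient_scale <= 0)) stop("gradient_scale components must be > 0")
  if (noise_model != "none" && (is.null(snr_b0) || snr_b0 <= 0))
    stop("snr_b0 must be positive for a noisy synthesis")
  nv <- n_volumes(scheme)
  ndir <- nrow(scheme$directions)
  bvals <- if (is.null(b_per_direction)) rep(scheme$b_nominal, ndir)
           else rep_len(b_per_direction, ndir)
  if (is.null(volume_scale)) volume_scale <- rep(1, nv)
  stopifnot(length(volume_scale) == nv)

  bmat_of <- function(dirs, b) {
    t(vapply(seq_len(nrow(dirs)), function(i) {
      u <- dirs[i, ]
      B <- b[i] * tcrossprod(u)
      c(B[1, 1], B[2, 2], B[3, 3], B[1, 2], B[1, 3], B[2, 3])
    }, numeric(6)))
  }
  # nominal b-matrices, reported with the stack
  b_nom <- rbind(matrix(0, scheme$n_b0, 6), bmat_of(scheme$directions, bvals))
  # actual b-matrices: gradients scaled before the b-matrix evaluation
  dirs_act <- sweep(scheme$directions, 2, gradient_scale, `*`)
  b_act <- rbind(matrix(0, scheme$n_b0, 6), bmat_of(dirs_act, bvals))

  dims <- truth$dims
  nvox <- prod(dims)
  D6 <- matrix(truth$tensors, nrow = nvox)          # nvox x 6
  W <- t(b_act * rep(c(1, 1, 1, 2, 2, 2), each = nv)) # 6 x nv, double off-diag
  s0 <- as.vector(truth$s0)
  if (noise_model == "rician" && all(s0 == 0)) stop("zero S0 with rician noise")
  data <- array(0, c(dims, nv))
  # exponent: -1e-3 * B:D (D in 1e-3 mm^2/s, b in s/mm^2)
  E <- D6 %*% W                                      # nvox x nv
  signal <- s0 * exp(-1e-3 * sweep(E, 2, volume_scale, `*`))

  myo <- truth$myocardium_mask
  dwv <- c(rep(FALSE, scheme$n_b0), rep(TRUE, ndir))
  noise_sd <- rep(0, nv)
  noise_volume <- NULL
  if (noise_model != "none") {
    set.seed(derive_seed(seed, "dwi_noise"))
    # channel sigma such that mean signal / sd(noise magnitude) = snr
    kmag <- if (noise_model == "rician") sqrt(2 - pi / 2) else 1
    sig0 <- mean(s0[as.vector(myo)]) / (snr_b0 * kmag)
    noise_sd[!dwv] <- sig0
    noise_sd[dwv] <- if (is.null(snr_dw)) sig0 else
      mean(signal[as.vector(myo), dwv]) / (snr_dw * kmag)
    n1 <- matrix(rnorm(nvox * nv), nvox, nv)
    n1 <- sweep(n1, 2, noise_sd, `*`)
    if (noise_model == "rician") {
      n2 <- matrix(rnorm(nvox * nv), nvox, nv)
      n2 <- sweep(n2, 2, noise_sd, `*`)
      signal <- sqrt((signal + n1)^2 + n2^2)
    } else {
      signal <- signal + n1
    }
    m1 <- rnorm(nvox) * noise_sd[1]
    m2 <- rnorm(nvox) * noise_sd[1]
    noise_volume <- array(if (noise_model == "rician") sqrt(m1^2 + m2^2)
                          else m1, dims)
    # noise data at the DW receiver gain (separate acquisition in practice)
    sd_dw <- noise_sd[which(dwv)[1]]
    d1 <- rnorm(nvox) * sd_dw
    d2 <- rnorm(nvox) * sd_dw
    noise_volume_dw <- array(if (noise_model == "rician") sqrt(d1^2 + d2^2)
                             else d1, dims)
  } else noise_volume_dw <- NULL
  data <- array(signal, c(dims, nv))
  out <- list(data = data, scheme = scheme, b_matrices = b_nom,
              b_matrices_actual = b_act, voxel_size = truth$voxel_size,
              noise_volume = noise_volume, noise_volume_dw = noise_volume_dw,
              noise_sd = noise_sd,
              myocardium_mask = myo, gradient_scale = gradient_scale,
              noise_model = noise_model)
  class(out) <- "dwi_stack"
  out
}

#' @export
print.dwi_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("DWI stack: %dx%dx%d, %d volumes (%d b0 + %d DW), %s noise\n",
              d[1], d[2], d[3], d[4], x$scheme$n_b0,
              nrow(x$scheme$directions), x$noise_model))
  invisible(x)
}

#' Receiver gain chain specification
#'
#' @param gain_db Receiver gain in dB (amplitude factor `10^(gain_db/20)`).
#' @param pre_adc_noise_sd,post_adc_noise_sd Noise added before/after the
#'   analogue-to-digital converter, in output signal units.
#' @param adc_bits ADC resolution in bits.
#' @param full_scale ADC full-scale value in output signal units.
#' @return Object of class `gain_chain_spec`.
#' @export
gain_chain_spec <- function(gain_db = 0, pre_adc_noise_sd = 0,
                            post_adc_noise_sd = 0, adc_bits = 16,
                            full_scale = 1) {
  stopifnot(adc_bits >= 1, full_scale > 0,
            pre_adc_noise_sd >= 0, post_adc_noise_sd >= 0)
  obj <- as.list(environment())
  class(obj) <- "gain_chain_spec"
  obj
}

#' Apply the receiver gain chain to a signal volume
#'
#' y = quantize(g * signal + pre-ADC noise) + post-ADC noise with
#' g = 10^(gain_db/20). Values beyond the ADC full scale are clipped and
#' counted. A higher gain makes the fixed ADC quantization and post-ADC noise
#' relatively smaller — the rationale for the dynamic (per-b-value) receiver
#' gain setting.
#'
#' @param signal Non-negative numeric array.
#' @param chain A [gain_chain_spec()].
#' @param seed Integer seed for the noise draws.
#' @param renormalize If `TRUE`, also return the output divided by g.
#' @return List: `signal`, `clipped_count`, `clipped_fraction`, `gain_factor`,
#'   and `signal_renormalized` when requested.
#' @export
apply_gain_chain <- function(signal, chain, seed = 1L, renormalize = TRUE) {
  stopifnot(inherits(chain, "gain_chain_spec"), all(is.finite(signal)),
            all(signal >= 0))
  set.seed(derive_seed(seed, "gain_chain"))
  g <- 10^(chain$gain_db / 20)
  y <- g * signal
  if (chain$pre_adc_noise_sd > 0)
    y <- y + rnorm(length(signal), sd = chain$pre_adc_noise_sd)
  step <- chain$full_scale / 2^chain$adc_bits
  clipped <- sum(y > chain$full_scale)
  y <- pmin(pmax(y, 0), chain$full_scale)
  y <- round(y / step) * step
  if (chain$post_adc_noise_sd > 0)
    y <- y + rnorm(length(signal), sd = chain$post_adc_noise_sd)
  if (!is.null(dim(signal))) y <- array(y, dim = dim(signal))
  out <- list(signal = y, clipped_count = clipped,
              clipped_fraction = clipped / length(signal), gain_factor = g)
  if (renormalize) out$signal_renormalized <- y / g
  out
}

#' Temperature schedule specification
#'
#' First-order exponential heating of the sample toward `t_steady` while
#' diffusion gradients run (DW scans) and cooling toward `t_ambient` during
#' non-DW scans and pauses. The default heating time constant is calibrated so
#' that 6 consecutive warm-up DW scans bring the sample just beyond 99% of
#' the steady-state temperature rise (tau = 17.4 min at 13.5 min per scan).
#'
#' @param t_ambient,t_steady Ambient and steady-state temperatures, deg C.
#' @param warmup_count Number of consecutive warm-up DW scans.
#' @param heat_time_constant,cool_time_constant Exponential time constants,
#'   minutes.
#' @param scan_duration Duration of one volume acquisition, minutes.
#' @param diffusivity_coeff Fractional diffusivity change per deg C
#'   (default 0.024, i.e. 2.4% per deg C).
#' @param t_ref Reference temperature for the diffusivity scale factors
#'   (default `t_ambient`).
#' @return Object of class `temperature_schedule`.
#' @export
temperature_schedule <- function(t_ambient = 20.2, t_steady = 23.8,
                                 warmup_count = 6,
                                 heat_time_constant = 17.4,
                                 cool_time_constant = 30,
                                 scan_duration = 13.5,
                                 diffusivity_coeff = 0.024,
                                 t_ref = t_ambient) {
  stopifnot(t_steady >= t_ambient, diffusivity_coeff >= 0, warmup_count >= 0)
  if (scan_duration < 0 || heat_time_constant <= 0 || cool_time_constant <= 0)
    stop("durations and time constants must be positive")
  obj <- as.list(environment())
  class(obj) <- "temperature_schedule"
  obj
}

#' Simulate sample temperature over an acquisition
#'
#' Runs `warmup_count` consecutive warm-up DW scans followed by the main
#' acquisition of `n_b0 + n_dw` volumes in the given ordering. DW volumes heat
#' the sample toward `t_steady`, non-DW volumes cool it toward `t_ambient`.
#' The per-volume diffusivity scale is `1 + diffusivity_coeff * (T - t_ref)`.
#'
#' @param sched A [temperature_schedule()].
#' @param n_b0,n_dw Number of non-DW / DW volumes of the main acquisition.
#' @param interleave If `TRUE` (default) b0 volumes are spread evenly among
#'   the DW volumes so both sample matched temperatures; otherwise all b0
#'   volumes precede the DW volumes.
#' @return data.frame with one row per volume (warm-ups first): `volume`,
#'   `phase` ("warmup", "b0", "dw"), `time_end` (minutes), `temperature`
#'   (deg C at mid-volume, the representative sample temperature of the
#'   scan), `temperature_end`, and `scale` (diffusivity factor; NA for
#'   warm-ups).
#'   Attribute `steady_volume` is the first warm-up volume reaching 99% of the
#'   steady-state rise.
#' @export
simulate_temperature_schedule <- function(sched, n_b0 = 8, n_dw = 61,
                                          interleave = TRUE) {
  stopifnot(inherits(sched, "temperature_schedule"))
  phases <- rep("warmup", sched$warmup_count)
  if (interleave && n_b0 > 0) {
    ord <- character(n_b0 + n_dw)
    pos <- round(seq(1, n_b0 + n_dw, length.out = max(n_b0, 1)))
    ord[pos] <- "b0"
    ord[ord == ""] <- "dw"
  } else {
    ord <- c(rep("b0", n_b0), rep("dw", n_dw))
  }
  phases <- c(phases, ord)
  n <- length(phases)
  temp_mid <- temp_end <- numeric(n)
  t_now <- sched$t_ambient
  for (i in seq_len(n)) {
    heating <- phases[i] %in% c("warmup", "dw")
    target <- if (heating) sched$t_steady else sched$t_ambient
    tau <- if (heating) sched$heat_time_constant else sched$cool_time_constant
    temp_mid[i] <- target + (t_now - target) *
      exp(-sched$scan_duration / (2 * tau))
    t_now <- target + (t_now - target) * exp(-sched$scan_duration / tau)
    temp_end[i] <- t_now
  }
  # mid-volume temperature is the representative sample temperature of a scan
  scale <- 1 + sched$diffusivity_coeff * (temp_mid - sched$t_ref)
  scale[phases == "warmup"] <- NA_real_
  out <- data.frame(volume = seq_len(n), phase = phases,
                    time_end = seq_len(n) * sched$scan_duration,
                    temperature = temp_mid, temperature_end = temp_end,
                    scale = scale)
  rise <- sched$t_steady - sched$t_ambient
  steady <- which(phases == "warmup" &
                    temp_end >= sched$t_ambient + 0.99 * rise)
  attr(out, "steady_volume") <- if (length(steady)) steady[1] else NA_integer_
  out
}
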