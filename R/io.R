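# File formats (NIfTI + FSL bval/bvec, YAML config) and the pipeline driver.

#' Read a DWI stack from NIfTI + FSL bval/bvec
#'
#' Gradient directions are reoriented to world space with the rotation part
#' of the NIfTI affine when it is not the identity (FSL bvecs are stored in
#' image space). Zero direction rows are accepted for b = 0 volumes.
#'
#' @param path_nifti 4D NIfTI file.
#' @param path_bval,path_bvec FSL-style b-value / b-vector text files.
#' @return A `dwi_stack` (nominal b-matrices built as b * u u^T).
#' @export
read_dwi <- function(path_nifti, path_bval, path_bvec) {
  for (f in c(path_nifti, path_bval, path_bvec))
    if (!file.exists(f)) stop("missing input file: ", f)
  img <- RNifti::readNifti(path_nifti)
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) != 4) stop("expected a 4D NIfTI volume")
  nv <- dim(data)[4]
  bvals <- scan(path_bval, quiet = TRUE)
  bvecs <- as.matrix(read.table(path_bvec))
  if (nrow(bvecs) == 3 && ncol(bvecs) != 3) bvecs <- t(bvecs)
  if (length(bvals) != nv || nrow(bvecs) != nv)
    stop(sprintf("scheme/volume count mismatch: %d volumes, %d bvals, %d bvecs",
                 nv, length(bvals), nrow(bvecs)))
  nrm <- sqrt(rowSums(bvecs^2))
  isb0 <- bvals == 0 | nrm == 0
  if (any(abs(nrm[!isb0] - 1) > 1e-3))
    stop("non-unit b-vectors beyond tolerance")
  bvecs[!isb0, ] <- bvecs[!isb0, ] / nrm[!isb0]
  aff <- tryCatch(structure(RNifti::xform(img), class = NULL),
                  error = function(e) NULL)
  notes <- character(0)
  if (!is.null(aff)) {
    R <- aff[1:3, 1:3]
    R <- sweep(R, 2, sqrt(colSums(R^2)), `/`)
    if (max(abs(R - diag(3))) > 1e-6) {
      bvecs <- bvecs %*% t(R)
      notes <- c(notes, "bvecs rotated to world space by the affine")
    }
  }
  vs <- tryCatch(RNifti::pixdim(img)[1], error = function(e) 1)
  b6 <- t(vapply(seq_len(nv), function(i) {
    B <- bvals[i] * tcrossprod(bvecs[i, ])
    c(B[1, 1], B[2, 2], B[3, 3], B[1, 2], B[1, 3], B[2, 3])
  }, numeric(6)))
  scheme <- gradient_scheme(n_b0 = max(sum(isb0), 1),
                            directions = bvecs[!isb0, , drop = FALSE],
                            b_nominal = max(bvals))
  out <- list(data = data, scheme = scheme, b_matrices = b6,
              b_matrices_actual = b6, voxel_size = vs, noise_volume = NULL,
              noise_sd = NULL, myocardium_mask = NULL,
              gradient_scale = c(1, 1, 1), noise_model = "unknown",
              volume_bvals = bvals, volume_bvecs = bvecs, io_notes = notes)
  class(out) <- "dwi_stack"
  out
}

#' Write a DWI stack as NIfTI + FSL bval/bvec
#'
#' @param dwi A `dwi_stack`.
#' @param prefix Output path prefix (writes `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec`).
#' @return The NIfTI path, invisibly.
#' @export
write_dwi <- function(dwi, prefix) {
  stopifnot(inherits(dwi, "dwi_stack"))
  img <- RNifti::asNifti(dwi$data)
  img <- RNifti::`pixdim<-`(img, c(rep(dwi$voxel_size, 3), 1))
  nii <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(img, nii)
  nb0 <- dwi$scheme$n_b0
  bvals <- c(rep(0, nb0), rep(dwi$scheme$b_nominal,
                              nrow(dwi$scheme$directions)))
  bvecs <- rbind(matrix(0, nb0, 3), dwi$scheme$directions)
  cat(paste(format(bvals, trim = TRUE), collapse = " "), "\n",
      file = paste0(prefix, ".bval"), sep = "")
  write.table(t(bvecs), paste0(prefix, ".bvec"), row.names = FALSE,
              col.names = FALSE)
  invisible(nii)
}

#' Write a named list of volumes as NIfTI maps
#'
#' @param maps Named list of 3D/4D arrays.
#' @param dir Output directory.
#' @param voxel_size Voxel size, mm.
#' @return Character vector of written paths, invisibly.
#' @export
write_nifti_maps <- function(maps, dir, voxel_size = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(maps), function(nm) {
    img <- RNifti::asNifti(maps[[nm]])
    img <- RNifti::`pixdim<-`(img, c(rep(voxel_size, 3),
                                     1)[seq_along(dim(maps[[nm]]))])
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(img, p)
    p
  }, character(1))
  invisible(paths)
}

#' Pipeline configuration
#'
#' Collects every stage toggle and parameter of the phantom-to-statistics
#' pipeline. Round-trips losslessly through YAML via [read_pipeline_config()]
#' / [write_pipeline_config()].
#'
#' @param seed Global seed; each stage derives a substream via
#'   [derive_seed()].
#' @param phantom Named list of [phantom_spec()] arguments.
#' @param snr_b0,snr_dw Acquisition SNR (non-DW / DW volumes).
#' @param noise_model `"rician"`, `"gaussian"` or `"none"`.
#' @param gradient_scale Actual per-axis gradient scaling.
#' @param b_imaging Crusher contribution for the prospective-adjustment
#'   stage, s/mm^2.
#' @param stages Character vector of stages to run, any of
#'   `c("adjust", "bootstrap", "track", "cluster")` in addition to the always
#'   run core (phantom, synthesize, fit, mask, frames, angles, aha,
#'   profiles).
#' @param bootstrap_n Bootstrap replicates.
#' @param bootstrap_max_voxels Cap on bootstrapped voxels (random subsample).
#' @param track_max_seeds Cap on streamline seeds.
#' @param cluster_max_voxels Cap on clustered voxels.
#' @param output_dir Optional directory for NIfTI/CSV/JSON outputs (NULL:
#'   nothing written).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, phantom = list(), snr_b0 = 47,
                            snr_dw = 24, noise_model = "rician",
                            gradient_scale = c(1, 1, 1), b_imaging = 61,
                            stages = c("adjust", "bootstrap"),
                            bootstrap_n = 200, bootstrap_max_voxels = 2000,
                            track_max_seeds = 500, cluster_max_voxels = 6000,
                            output_dir = NULL) {
  obj <- as.list(environment())
  class(obj) <- "pipeline_config"
  obj
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251 + 1)) %%
            .Machine$integer.max)
}

#' Run the phantom-to-statistics pipeline
#'
#' Executes phantom generation, (optional) prospective b adjustment, DWI
#' synthesis, tensor fitting, masking and SNR, (optional) wild bootstrap +
#' COU, Laplace frames, angle maps, AHA-17 labelling, transmural profiles and
#' histograms, and (optional) tracking and sheetlet clustering, as toggled by
#' the config. Summary metrics are collected into a JSON-serializable report
#' with provenance (config hash, seed, package version).
#'
#' @param config A [pipeline_config()].
#' @param verbose Log stage progress to stderr.
#' @return A list report; written to `output_dir/report.json` when
#'   `output_dir` is set.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  log <- function(...) if (verbose) message(sprintf(...))
  report <- list(provenance = list(
    package = "cardiacdti",
    version = as.character(utils::packageVersion("cardiacdti")),
    seed = config$seed, config_hash = config_hash(config),
    timestamp = format(t_start)))

  log("[phantom] generating LV phantom")
  spec <- do.call(phantom_spec, c(config$phantom,
                                  list(seed = derive_seed(config$seed,
                                                          "phantom"))))
  truth <- generate_lv_phantom(spec)
  report$phantom <- list(
    dims = truth$dims, voxel_size = truth$voxel_size,
    myocardial_voxels = sum(truth$myocardium_mask),
    eigenvalues = truth$eigenvalues_myocardium,
    fa_true = fa_from_eigenvalues(truth$eigenvalues_myocardium))

  scheme <- gradient_scheme()
  if ("adjust" %in% config$stages) {
    log("[adjust] prospective diffusion gradient adjustment")
    seq_t <- calibrate_crusher(sequence_timing(), config$b_imaging)
    adj <- prospective_adjust(scheme, seq_t)
    report$adjust <- list(
      b_imaging = config$b_imaging,
      b_effective_range = range(adj$table$b_effective),
      max_iterations = max(adj$table$iterations))
  }

  log("[synthesize] DW signal synthesis (SNR %s/%s, %s noise)",
      config$snr_b0, config$snr_dw, config$noise_model)
  dwi <- synthesize_dwi(truth, scheme, snr_b0 = config$snr_b0,
                        noise_model = config$noise_model,
                        gradient_scale = config$gradient_scale,
                        seed = derive_seed(config$seed, "synthesize"),
                        snr_dw = config$snr_dw)

  log("[fit] tensor NLLS over %d voxels", prod(truth$dims))
  fit <- fit_tensor_nlls(dwi)
  eig <- eigen_metrics(fit)
  seg <- segment_myocardium(fit$s0, eig$mean_adc, eig$fa, eigen = eig)
  myo <- seg$mask
  report$fit <- list(
    converged_fraction = mean(fit$converged),
    mask_voxels = sum(myo),
    mask_dice_vs_truth = {
      tm <- truth$myocardium_mask
      2 * sum(myo & tm) / (sum(myo) + sum(tm))
    },
    sheetlet_excluded_fraction = seg$excluded_fraction,
    fa_myocardium = mean(eig$fa[myo], na.rm = TRUE),
    adc_myocardium = mean(eig$mean_adc[myo], na.rm = TRUE))
  if (!is.null(dwi$noise_volume)) {
    nb0 <- scheme$n_b0
    snr0 <- compute_snr(dwi$data, myo, dwi$noise_volume)
    snrd <- compute_snr(dwi$data, myo, dwi$noise_volume_dw)
    report$snr <- list(b0 = mean(snr0[seq_len(nb0)]),
                       dw = mean(snrd[-seq_len(nb0)]))
  }

  if ("bootstrap" %in% config$stages) {
    log("[bootstrap] wild bootstrap (%d replicates)", config$bootstrap_n)
    bm <- myo
    idx <- which(bm)
    if (length(idx) > config$bootstrap_max_voxels) {
      set.seed(derive_seed(config$seed, "bootstrap_subsample"))
      keep <- sample(idx, config$bootstrap_max_voxels)
      bm <- array(FALSE, dim(bm)); bm[keep] <- TRUE
    }
    ens <- wild_bootstrap(fit, n = config$bootstrap_n,
                          seed = derive_seed(config$seed, "bootstrap"),
                          mask = bm)
    cou <- cone_of_uncertainty(ens)
    report$cou <- as.list(setNames(cou$summary, c("v1", "v2", "v3")))
  }

  log("[frames] Laplace depth + local frames + angle maps")
  bnd <- classify_lv_boundaries(myo)
  depth <- solve_laplace_depth(myo, bnd$endo_boundary, bnd$epi_boundary)
  lax <- global_long_axis(bnd$endo_boundary, voxel_size = truth$voxel_size)
  frames <- build_local_frames(depth, lax)
  amaps <- compute_angle_maps(eig, frames)
  okv <- amaps$mask & !amaps$flagged
  report$angles <- list(
    degenerate_voxels = sum(frames$degenerate),
    ha_mean = axial_mean_deg(amaps$HA[okv]), ha_sd = sd(amaps$HA[okv]),
    ta_mean = axial_mean_deg(amaps$TA[okv]), ta_sd = sd(amaps$TA[okv]))

  log("[aha] 17-segment labelling + transmural profiles")
  aha <- aha17_labels(myo, lax, truth$landmark,
                      voxel_size = truth$voxel_size,
                      cavity_mask = truth$lv_cavity_mask)
  prof <- transmural_profiles(amaps, depth$phi, aha)
  ha16 <- prof[prof$angle == "HA" & prof$segment <= 16 & prof$flag == "ok", ]
  report$profiles <- list(
    segments = sort(unique(prof$segment)),
    ha_r2_min_aha1_16 = min(ha16$r_squared),
    ha_range_mean = mean(abs(ha16$range_deg)))
  hist <- angle_histograms(amaps, aha)
  report$histograms <- list(rows = nrow(hist))

  if ("track" %in% config$stages) {
    log("[track] RK2 streamlines along v1")
    idx <- which(okv)
    set.seed(derive_seed(config$seed, "track"))
    if (length(idx) > config$track_max_seeds)
      idx <- sort(sample(idx, config$track_max_seeds))
    seeds <- arrayInd(idx, truth$dims)
    tr <- rk2_streamlines(eig$v1, okv, seeds = seeds,
                          voxel_size = truth$voxel_size)
    report$track <- list(n_tracks = length(tr$tracks),
                         median_length_mm = if (length(tr$tracks))
                           median(vapply(tr$tracks, function(m)
                             (nrow(m) - 1) * tr$step_mm, numeric(1)))
                         else NA_real_)
  } else tr <- NULL

  if ("cluster" %in% config$stages) {
    log("[cluster] sheetlet-domain mean-shift")
    cm <- if (!is.null(seg$sheetlet_mask)) seg$sheetlet_mask & okv else okv
    idx <- which(cm)
    if (length(idx) > config$cluster_max_voxels) {
      set.seed(derive_seed(config$seed, "cluster_subsample"))
      keep <- sort(sample(idx, config$cluster_max_voxels))
      cm <- array(FALSE, dim(cm)); cm[keep] <- TRUE
    }
    se_u <- unwrap_angle_features(amaps$SE, cm)
    sa_u <- unwrap_angle_features(amaps$SA, cm)
    ft <- feature_table(se_u, sa_u, depth$phi, cm,
                        voxel_size = truth$voxel_size)
    cl <- flat_meanshift(ft)
    cl <- merge_small_clusters(cl)
    cl <- mode_filter_3cubed(cl)
    report$cluster <- list(n_clusters = cl$n_clusters,
                           voxels = sum(!is.na(cl$labels)))
  } else cl <- NULL

  report$elapsed_s <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_nifti_maps(list(s0 = fit$s0, fa = eig$fa, adc = eig$mean_adc,
                          ha = amaps$HA, ta = amaps$TA, se = amaps$SE,
                          sa = amaps$SA, depth = depth$phi),
                     config$output_dir, truth$voxel_size)
    write.table(prof, file.path(config$output_dir, "transmural_profiles.csv"),
                sep = ",", row.names = FALSE)
    jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
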