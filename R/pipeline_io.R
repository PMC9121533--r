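#' Pipeline configuration
#'
#' Collects every tunable of the simulate -> preprocess -> quantify ->
#' extract -> stats chain in one serialisable object. `write_config()` /
#' `read_config()` round-trip it as YAML, and every [run_pipeline()] call
#' writes the resolved configuration beside its outputs.
#'
#' @param cohort A [cohort_spec()].
#' @param n_imaging_subjects How many subjects get full image simulation
#'   and voxel-wise fitting (the cohort table itself covers all subjects;
#'   image-level processing is the expensive part).
#' @param matrix_size Phantom grid.
#' @param noise_sd Image noise SD, signal units.
#' @param background_width Ghost-free corner width, voxels.
#' @param erode_width ROI erosion box width, voxels.
#' @param sinus_percentile High-signal sinus percentile.
#' @param reliable_multiplier Background-SD multiplier of the reliable-voxel
#'   threshold.
#' @param cbf_max Upper bound of the multi-TI CBF fit.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            n_imaging_subjects = 2,
                            matrix_size = c(32, 32, 12),
                            noise_sd = 1.5, background_width = 5,
                            erode_width = 2, sinus_percentile = 90,
                            reliable_multiplier = 1, cbf_max = 3000,
                            seed = 1L) {
  structure(list(
    cohort = cohort, n_imaging_subjects = n_imaging_subjects,
    matrix_size = as.integer(matrix_size), noise_sd = noise_sd,
    background_width = background_width, erode_width = erode_width,
    sinus_percentile = sinus_percentile,
    reliable_multiplier = reliable_multiplier, cbf_max = cbf_max,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path File path for the YAML serialisation.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  x$cohort$features <- as.data.frame(x$cohort$features)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  feat <- tibble::as_tibble(as.data.frame(x$cohort$features))
  ch <- x$cohort
  cohort <- cohort_spec(
    n_sca = ch$n_sca, n_control = ch$n_control, features = feat,
    cao2_slope_frac = ch$cao2_slope_frac,
    iq_sinus_slope = ch$iq_sinus_slope, wm_psi_slope = ch$wm_psi_slope,
    p_hydroxycarbamide = ch$p_hydroxycarbamide,
    p_transfusion = ch$p_transfusion, p_sci_sca = ch$p_sci_sca,
    p_sci_control = ch$p_sci_control, cognition_sd = ch$cognition_sd,
    seed = ch$seed)
  pipeline_config(
    cohort = cohort, n_imaging_subjects = x$n_imaging_subjects,
    matrix_size = x$matrix_size, noise_sd = x$noise_sd,
    background_width = x$background_width, erode_width = x$erode_width,
    sinus_percentile = x$sinus_percentile,
    reliable_multiplier = x$reliable_multiplier, cbf_max = x$cbf_max,
    seed = x$seed)
}

#' Write a 3D/4D map as NIfTI
#'
#' @param map Numeric array.
#' @param path Output `.nii` path.
#' @param voxel_size Voxel edge lengths, mm.
#' @return The path, invisibly.
#' @export
write_nifti_map <- function(map, path, voxel_size = c(3.4, 3.4, 4)) {
  img <- RNifti::asNifti(map)
  RNifti::pixdim(img) <- voxel_size[seq_len(min(3, length(dim(map))))]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI map as a plain array
#'
#' @param path `.nii` / `.nii.gz` path.
#' @param like Optional reference array or NIfTI whose grid the map must
#'   match; a mismatch raises an error naming the file.
#' @return Numeric array with the NIfTI attributes stripped.
#' @export
read_nifti_map <- function(path, like = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (!is.null(like) && !identical(dim(arr)[1:3], dim(like)[1:3])) {
    stop(sprintf(
      "read_nifti_map: grid of '%s' (%s) does not match the reference (%s)",
      path, paste(dim(arr)[1:3], collapse = "x"),
      paste(dim(like)[1:3], collapse = "x")), call. = FALSE)
  }
  arr
}

#' Read a simulated/exported ASL series from disk
#'
#' Reconstructs an `asl_series` from a 4D difference NIfTI, an M0 NIfTI and
#' an acquisition spec.
#'
#' @param data_path 4D difference-series NIfTI.
#' @param m0_path 3D M0 NIfTI.
#' @param acq An [acquisition_spec()].
#' @return An `asl_series`.
#' @export
read_asl_series <- function(data_path, m0_path, acq) {
  dat <- read_nifti_map(data_path)
  m0 <- read_nifti_map(m0_path, like = dat)
  if (dim(dat)[4] != acq$n_volumes) {
    stop(sprintf(
      "read_asl_series: '%s' has %d volumes but the acquisition expects %d",
      data_path, dim(dat)[4], acq$n_volumes), call. = FALSE)
  }
  structure(list(data = dat, m0 = m0, acq = acq, params = NULL,
                 noise_sd = NA_real_), class = "asl_series")
}

# process one simulated subject end to end; returns the feature row
.process_subject <- function(row, config) {
  physio <- subject_physiology(
    subject_id = row$subject_id, group = row$group, age = row$age,
    sex = row$sex, hemoglobin = row$hemoglobin,
    hematocrit = row$hematocrit, spo2 = row$spo2)
  # the two sequences plant their own truth values (single- and multi-TI
  # apparent CBF genuinely differ); geometry and M0 are shared
  truth_s <- make_phantom(
    matrix_size = config$matrix_size,
    cbf = c(gm = row$gm_cbf_sti, wm = row$wm_cbf_sti,
            sinus = row$sinus_cbf_sti),
    bat = c(gm = row$gm_bat_mti, wm = row$wm_bat_mti,
            sinus = row$sinus_bat_mti))
  truth_m <- make_phantom(
    matrix_size = config$matrix_size,
    cbf = c(gm = row$gm_cbf_mti, wm = row$wm_cbf_mti,
            sinus = row$sinus_cbf_mti),
    bat = c(gm = row$gm_bat_mti, wm = row$wm_bat_mti,
            sinus = row$sinus_bat_mti))
  acq_s <- acquisition_spec("singleTI_pCASL", matrix_size = config$matrix_size,
                            background_corner_width = config$background_width)
  acq_m <- acquisition_spec("multiTI_PASL", matrix_size = config$matrix_size,
                            background_corner_width = config$background_width)
  ser_s <- simulate_series(truth_s, acq_s, physio, noise_sd = config$noise_sd,
                           seed = row$subject_seed)
  ser_m <- simulate_series(truth_m, acq_m, physio, noise_sd = config$noise_sd,
                           seed = row$subject_seed + 1L)

  md <- mean_difference(ser_s)
  p_s <- pcasl_params(t1_blood = physio$t1_blood)
  seg <- truth_s$segmentation
  tissue <- seg > 0L
  map_s <- quantify_singleti(md, truth_s$m0, p_s, mask = tissue)

  bg <- background_stats(ser_m, width = config$background_width)
  rel <- reliable_voxel_mask(ser_m, bg, config$reliable_multiplier)
  p_m <- pasl_params(t1_blood = physio$t1_blood)
  map_m <- fit_multiti(ser_m, truth_m$m0, p_m, mask = tissue & rel,
                       stats = bg, cbf_max = config$cbf_max)

  rois <- build_roi_set(seg == 1L, seg == 2L, seg == 3L, map_s$cbf,
                        erode_width = config$erode_width,
                        percentile = config$sinus_percentile,
                        subject_id = row$subject_id)
  extract_features(list(singleti = map_s, multiti = map_m), rois,
                   subject_id = row$subject_id)
}

#' Run the full synthetic pipeline
#'
#' Simulates a cohort table, runs the image-level chain (phantom ->
#' difference series -> preprocessing -> voxel-wise quantification -> ROI
#' features) for the first `n_imaging_subjects` subjects, runs the
#' statistical stage on the full cohort table, and writes the feature
#' table, statistics tables, a provenance manifest (with file checksums)
#' and the resolved configuration into `out_dir`. Per-subject failures are
#' quarantined with their error message; the run is deterministic given
#' the configuration seeds.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param cohort Optional pre-built cohort table; by default the cohort is
#'   simulated from `config$cohort`.
#' @param max_fail_frac Abort if more than this fraction of imaging
#'   subjects fail.
#' @return List: `cohort`, `imaging_features`, `group_stats`, `cao2_stats`,
#'   `quarantine`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile(),
                         cohort = NULL, max_fail_frac = 0.5) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cohort)) cohort <- simulate_cohort(config$cohort)

  n_img <- min(config$n_imaging_subjects, nrow(cohort))
  quarantine <- list()
  feats <- list()
  for (i in seq_len(n_img)) {
    row <- cohort[i, ]
    res <- tryCatch(.process_subject(row, config), error = function(e) e)
    if (inherits(res, "error")) {
      quarantine[[row$subject_id]] <- conditionMessage(res)
    } else {
      feats[[row$subject_id]] <- res
    }
  }
  if (n_img > 0 && length(quarantine) / n_img > max_fail_frac) {
    stop(sprintf("run_pipeline: %d of %d imaging subjects failed",
                 length(quarantine), n_img), call. = FALSE)
  }
  imaging_features <- if (length(feats)) dplyr::bind_rows(feats)
                      else tibble::tibble()

  gstats <- group_comparison_table(cohort)
  cstats <- cao2_correlation_table(cohort)

  paths <- c(cohort = file.path(out_dir, "cohort.csv"),
             features = file.path(out_dir, "imaging_features.csv"),
             group_stats = file.path(out_dir, "group_stats.csv"),
             cao2_stats = file.path(out_dir, "cao2_stats.csv"),
             config = file.path(out_dir, "config.yaml"))
  utils::write.csv(cohort, paths["cohort"], row.names = FALSE, na = "")
  utils::write.csv(imaging_features, paths["features"], row.names = FALSE,
                   na = "")
  utils::write.csv(gstats, paths["group_stats"], row.names = FALSE, na = "")
  utils::write.csv(cstats, paths["cao2_stats"], row.names = FALSE, na = "")
  write_config(config, paths["config"])

  manifest <- tibble::tibble(
    file = basename(unname(paths)),
    md5 = vapply(unname(paths), function(p) unname(tools::md5sum(p)),
                 character(1)),
    n_quarantined = length(quarantine))
  jsonlite::write_json(
    list(files = manifest, quarantine = quarantine,
         package_version = as.character(utils::packageVersion("venoasl"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)

  list(cohort = cohort, imaging_features = imaging_features,
       group_stats = gstats, cao2_stats = cstats,
       quarantine = quarantine, manifest = manifest, out_dir = out_dir)
}
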