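#' Inflow-time grid
#'
#' Builds the inclusive arithmetic grid of inflow times, specified in
#' milliseconds and returned in seconds. The default acquisition samples
#' 10 TIs from 350 to 2600 ms in 250 ms steps.
#'
#' @param start_ms,stop_ms First and last inflow time, ms.
#' @param step_ms Grid step, ms (> 0).
#' @return Numeric vector of inflow times in seconds.
#' @examples
#' make_ti_grid()               # 10 values, 0.35 .. 2.60 s
#' make_ti_grid(350, 2600, 750) # 0.35 1.10 1.85 2.60
#' @export
make_ti_grid <- function(start_ms = 350, stop_ms = 2600, step_ms = 250) {
  if (!is.finite(step_ms) || step_ms <= 0) {
    stop("make_ti_grid: 'step_ms' must be > 0", call. = FALSE)
  }
  if (start_ms > stop_ms) {
    stop("make_ti_grid: 'start_ms' must be <= 'stop_ms'", call. = FALSE)
  }
  seq(start_ms, stop_ms, by = step_ms) / 1000
}

#' Acquisition specification
#'
#' Describes one simulated ASL acquisition: a single-TI pCASL series of
#' repeated difference volumes at one post-labeling delay, or a multi-TI
#' PASL series with one difference volume per inflow time. In-plane corner
#' squares of `background_corner_width` voxels are kept ghost-free
#' (pure background) by the phantom.
#'
#' @param kind `"singleTI_pCASL"` or `"multiTI_PASL"`.
#' @param inflow_times Inflow times in seconds (multi-TI only); defaults to
#'   [make_ti_grid()].
#' @param repeats Number of repeated difference volumes (single-TI only).
#' @param matrix_size Integer vector of 3 voxel counts.
#' @param voxel_size Voxel edge lengths, mm.
#' @param background_corner_width Width of the ghost-free corner squares,
#'   voxels.
#' @return List of class `acquisition_spec`.
#' @export
acquisition_spec <- function(kind = c("singleTI_pCASL", "multiTI_PASL"),
                             inflow_times = NULL, repeats = 10,
                             matrix_size = c(32, 32, 24),
                             voxel_size = c(3.4, 3.4, 4),
                             background_corner_width = 5) {
  kind <- match.arg(kind)
  if (kind == "multiTI_PASL") {
    if (is.null(inflow_times)) inflow_times <- make_ti_grid()
    if (any(diff(inflow_times) <= 0)) {
      stop("acquisition_spec: 'inflow_times' must be strictly increasing",
           call. = FALSE)
    }
    n_vol <- length(inflow_times)
  } else {
    if (repeats < 1) stop("acquisition_spec: 'repeats' must be >= 1",
                          call. = FALSE)
    n_vol <- repeats
  }
  structure(list(kind = kind, inflow_times = inflow_times,
                 repeats = repeats, matrix_size = as.integer(matrix_size),
                 voxel_size = voxel_size, n_volumes = n_vol,
                 background_corner_width = background_corner_width),
            class = "acquisition_spec")
}

# voxel-centre membership rules for the phantom compartments; shared by
# make_phantom() and kept analytic so tests can re-derive counts
.phantom_geometry <- function(dim) {
  cx <- (dim[1] + 1) / 2; cy <- (dim[2] + 1) / 2
  rx <- 0.40 * dim[1]; ry <- 0.40 * dim[2]
  list(
    cx = cx, cy = cy, rx = rx, ry = ry,
    wm_frac = 0.55,                       # WM core = inner 55% of the shell
    sinus_y = cy + 0.88 * ry,             # posterior midline tube
    sinus_r = 1.8
  )
}

#' Digital perfusion phantom
#'
#' Builds a three-compartment phantom on a 3D grid: a gray-matter elliptic
#' annulus around a white-matter core (constant across slices, so every
#' compartment is a tube along z), plus a small posterior midline cylinder
#' standing in for the sagittal sinus. The four in-plane corner squares
#' remain background on every slice, so ghost-free background statistics can
#' be measured. Background voxels carry zero CBF and zero M0.
#'
#' Labels: 0 background, 1 gray matter, 2 white matter, 3 sinus.
#'
#' @param matrix_size Integer vector of 3 voxel counts (in-plane at least
#'   three corner widths; default 32 x 32 x 24).
#' @param cbf Named vector of true CBF (mL/100g/min) for `gm`, `wm`, `sinus`.
#' @param bat Named vector of true bolus arrival times, s.
#' @param m0 Named vector of proton-density signal per compartment.
#' @param jitter_sd Optional within-compartment multiplicative variation
#'   (lognormal sd on the CBF map); 0 disables it.
#' @param corner_width Ghost-free corner width used for the validity check.
#' @param seed Integer seed (only consulted when `jitter_sd > 0`).
#' @return List of class `phantom_truth` with `segmentation`, `cbf_true`,
#'   `bat_true`, `m0` arrays.
#' @export
make_phantom <- function(matrix_size = c(32, 32, 24),
                         cbf = c(gm = 54, wm = 31, sinus = 105),
                         bat = c(gm = 0.7, wm = 0.95, sinus = 1.2),
                         m0 = c(gm = 1000, wm = 800, sinus = 900),
                         jitter_sd = 0, corner_width = 5, seed = 1L) {
  dim <- as.integer(matrix_size)
  if (length(dim) != 3 || any(dim[1:2] < 3 * corner_width) || dim[3] < 4) {
    stop("make_phantom: matrix too small to host corner ROIs and compartments",
         call. = FALSE)
  }
  g <- .phantom_geometry(dim)
  x <- seq_len(dim[1]); y <- seq_len(dim[2])
  ex <- outer((x - g$cx) / g$rx, rep(1, dim[2]))
  ey <- outer(rep(1, dim[1]), (y - g$cy) / g$ry)
  r2 <- ex^2 + ey^2
  slice <- matrix(0L, dim[1], dim[2])
  slice[r2 <= 1] <- 1L                                    # GM shell
  slice[r2 <= g$wm_frac^2] <- 2L                          # WM core
  sx <- outer(x - g$cx, rep(1, dim[2]))
  sy <- outer(rep(1, dim[1]), y - g$sinus_y)
  slice[sx^2 + sy^2 <= g$sinus_r^2] <- 3L                 # sinus tube
  seg <- array(rep(slice, dim[3]), dim = dim)

  # corner squares must be background on every slice
  w <- corner_width
  if (any(slice[1:w, 1:w] != 0L) ||
      any(slice[1:w, (dim[2] - w + 1):dim[2]] != 0L) ||
      any(slice[(dim[1] - w + 1):dim[1], 1:w] != 0L) ||
      any(slice[(dim[1] - w + 1):dim[1], (dim[2] - w + 1):dim[2]] != 0L)) {
    stop("make_phantom: compartments intrude into the corner background",
         call. = FALSE)
  }

  lut <- function(vals) {
    out <- array(0, dim = dim)
    out[seg == 1L] <- vals[["gm"]]
    out[seg == 2L] <- vals[["wm"]]
    out[seg == 3L] <- vals[["sinus"]]
    out
  }
  cbf_true <- lut(cbf); bat_true <- lut(bat); m0_map <- lut(m0)
  if (jitter_sd > 0) {
    set.seed(seed)
    jit <- array(exp(stats::rnorm(prod(dim), 0, jitter_sd)), dim = dim)
    cbf_true <- cbf_true * jit
  }
  structure(list(segmentation = seg, cbf_true = cbf_true,
                 bat_true = bat_true, m0 = m0_map,
                 labels = c(background = 0L, gm = 1L, wm = 2L, sinus = 3L)),
            class = "phantom_truth")
}

#' Simulate an ASL difference-image series from a phantom
#'
#' Forward-simulates pre-aligned difference volumes for one subject:
#' single-TI pCASL series are `repeats` copies of the [pcasl_forward()]
#' signal, multi-TI PASL series one volume per inflow time from
#' [pasl_kinetic_signal()], each plus i.i.d. Gaussian noise. The subject's
#' blood T1 enters the forward model; blood magnetization is
#' `m0 * p$m0_scale` (default `m0 / lam`). Background voxels are pure
#' noise. Control/label pairs and background suppression are not modelled;
#' the difference signal is simulated directly.
#'
#' @param truth A [make_phantom()] object.
#' @param acq An [acquisition_spec()].
#' @param physio A [subject_physiology()] (supplies `t1_blood`).
#' @param noise_sd Gaussian noise sd in signal units (the default 1.5 gives
#'   single-repeat peak SNR of roughly 5-10 with M0 near 1000).
#' @param seed Integer seed.
#' @param pcasl,pasl Optional parameter sets; defaults use the subject's
#'   blood T1 with standard constants.
#' @return List of class `asl_series`: 4D `data`, 3D `m0`, acquisition
#'   metadata.
#' @export
simulate_series <- function(truth, acq, physio, noise_sd = 1.5, seed = 1L,
                            pcasl = NULL, pasl = NULL) {
  stopifnot(inherits(truth, "phantom_truth"),
            inherits(acq, "acquisition_spec"))
  if (!all(dim(truth$cbf_true) == acq$matrix_size)) {
    stop("simulate_series: phantom and acquisition grids differ",
         call. = FALSE)
  }
  dim3 <- dim(truth$cbf_true)
  set.seed(seed)
  if (acq$kind == "singleTI_pCASL") {
    p <- if (is.null(pcasl)) pcasl_params(t1_blood = physio$t1_blood)
         else pcasl
    clean <- pcasl_forward(truth$cbf_true, truth$m0, p)
    dat <- array(0, dim = c(dim3, acq$repeats))
    for (r in seq_len(acq$repeats)) {
      dat[, , , r] <- clean +
        array(stats::rnorm(prod(dim3), 0, noise_sd), dim = dim3)
    }
    params <- p
  } else {
    p <- if (is.null(pasl)) pasl_params(t1_blood = physio$t1_blood)
         else pasl
    m0b <- truth$m0 * p$m0_scale
    dat <- array(0, dim = c(dim3, length(acq$inflow_times)))
    for (i in seq_along(acq$inflow_times)) {
      clean <- array(
        pasl_kinetic_signal(acq$inflow_times[i], as.vector(truth$cbf_true),
                            as.vector(truth$bat_true), as.vector(m0b), p),
        dim = dim3)
      dat[, , , i] <- clean +
        array(stats::rnorm(prod(dim3), 0, noise_sd), dim = dim3)
    }
    params <- p
  }
  structure(list(data = dat, m0 = truth$m0, acq = acq, params = params,
                 noise_sd = noise_sd),
            class = "asl_series")
}

#' Cohort simulation settings
#'
#' Defines the synthetic-cohort generator: group sizes, per-group
#' means/SDs of the nine ROI-level hemodynamic features, the negative
#' CaO2-CBF coupling inside the patient group, the cognition couplings, and
#' treatment prevalences. Defaults plant a patient (SCA) group with higher
#' CBF everywhere, shorter tissue BAT, longer and more variable venous
#' (sinus) BAT, and cognition linked to venous CBF. Skewed features (the
#' three sinus CBF variables, SCI burden) are lognormal, parameterised by
#' meanlog/sdlog back-computed from medians and interquartile ranges;
#' normal features by mean/SD.
#'
#' @param n_sca,n_control Group sizes.
#' @param features Data frame of feature distributions (one row per
#'   feature x group) with columns `feature`, `group`, `mean`, `sd`,
#'   `log` (logical: parameters on the log scale).
#' @param cao2_slope_frac Planted correlation (as a fraction of feature SD
#'   per CaO2 SD, i.e. the target Pearson r, negated) between CaO2 and each
#'   CBF feature within the SCA group.
#' @param iq_sinus_slope IQ points per log-unit of sinus multi-TI CBF
#'   (planted regression slope; negative means higher venous CBF, lower IQ).
#' @param wm_psi_slope PSI points per mL/100g/min of WM multi-TI CBF.
#' @param p_hydroxycarbamide,p_transfusion,p_sci_sca,p_sci_control
#'   Treatment / lesion prevalences.
#' @param cognition_sd Residual SD of the cognitive scores.
#' @param seed Integer seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_sca = 90, n_control = 40,
                        features = default_feature_table(),
                        cao2_slope_frac = 0.45,
                        iq_sinus_slope = -3.94,
                        wm_psi_slope = -0.29,
                        p_hydroxycarbamide = 0.36, p_transfusion = 0.07,
                        p_sci_sca = 0.41, p_sci_control = 0.10,
                        cognition_sd = 12.5, seed = 20220101L) {
  stopifnot(n_sca >= 2, n_control >= 2, all(features$sd >= 0),
            all(c(p_hydroxycarbamide, p_transfusion, p_sci_sca,
                  p_sci_control) >= 0),
            all(c(p_hydroxycarbamide, p_transfusion, p_sci_sca,
                  p_sci_control) <= 1))
  structure(list(
    n_sca = n_sca, n_control = n_control, features = features,
    cao2_slope_frac = cao2_slope_frac, iq_sinus_slope = iq_sinus_slope,
    wm_psi_slope = wm_psi_slope,
    p_hydroxycarbamide = p_hydroxycarbamide, p_transfusion = p_transfusion,
    p_sci_sca = p_sci_sca, p_sci_control = p_sci_control,
    cognition_sd = cognition_sd, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Default feature distribution table
#'
#' Per-group distributions of the nine ROI-level hemodynamic features:
#' gray-matter, white-matter and high-signal sagittal-sinus CBF from the
#' single-TI sequence; CBF and BAT for the same regions from the multi-TI
#' sequence. Sinus CBF features are lognormal (`log = TRUE`, `mean`/`sd`
#' are meanlog/sdlog); all others are normal. Values follow the group
#' summary statistics of a pediatric/young-adult sickle-cell cohort with
#' healthy controls.
#'
#' @return A tibble with columns `feature`, `family`, `group`, `mean`,
#'   `sd`, `log`.
#' @export
default_feature_table <- function() {
  tribble_row <- function(feature, family, group, mean, sd, log) {
    tibble::tibble(feature = feature, family = family, group = group,
                   mean = mean, sd = sd, log = log)
  }
  iqr_sdlog <- function(lo, hi) (log(hi) - log(lo)) / (2 * stats::qnorm(0.75))
  iqr_sd <- function(lo, hi) (hi - lo) / (2 * stats::qnorm(0.75))
  dplyr::bind_rows(
    tribble_row("gm_cbf_sti", "singleTI_CBF", "SCA", 54.06, 7.78, FALSE),
    tribble_row("gm_cbf_sti", "singleTI_CBF", "control", 42.52, 7.13, FALSE),
    tribble_row("wm_cbf_sti", "singleTI_CBF", "SCA", 31.25, 4.82, FALSE),
    tribble_row("wm_cbf_sti", "singleTI_CBF", "control", 22.91, 4.49, FALSE),
    tribble_row("sinus_cbf_sti", "singleTI_CBF", "SCA",
                log(104.66), iqr_sdlog(80.06, 145.60), TRUE),
    tribble_row("sinus_cbf_sti", "singleTI_CBF", "control",
                log(66.18), iqr_sdlog(57.03, 78.93), TRUE),
    tribble_row("gm_cbf_mti", "multiTI_CBF", "SCA", 129.02, 22.26, FALSE),
    tribble_row("gm_cbf_mti", "multiTI_CBF", "control", 89.62, 11.83, FALSE),
    tribble_row("wm_cbf_mti", "multiTI_CBF", "SCA", 69.52, 11.99, FALSE),
    tribble_row("wm_cbf_mti", "multiTI_CBF", "control", 51.83, 7.46, FALSE),
    tribble_row("sinus_cbf_mti", "multiTI_CBF", "SCA",
                log(253.77), iqr_sdlog(157.73, 467.67), TRUE),
    tribble_row("sinus_cbf_mti", "multiTI_CBF", "control",
                log(145.83), iqr_sdlog(113.95, 202.52), TRUE),
    tribble_row("gm_bat_mti", "multiTI_BAT", "SCA",
                0.72, iqr_sd(0.66, 0.75), FALSE),
    tribble_row("gm_bat_mti", "multiTI_BAT", "control",
                0.82, iqr_sd(0.77, 0.89), FALSE),
    tribble_row("wm_bat_mti", "multiTI_BAT", "SCA",
                0.96, iqr_sd(0.91, 1.05), FALSE),
    tribble_row("wm_bat_mti", "multiTI_BAT", "control",
                1.15, iqr_sd(1.08, 1.26), FALSE),
    tribble_row("sinus_bat_mti", "multiTI_BAT", "SCA",
                1.17, iqr_sd(0.98, 1.45), FALSE),
    tribble_row("sinus_bat_mti", "multiTI_BAT", "control",
                1.01, iqr_sd(0.87, 1.10), FALSE)
  )
}

#' Map feature names to parameter-map families
#'
#' The FDR stratification groups comparisons by parameter-map family:
#' single-TI CBF, multi-TI CBF, multi-TI BAT.
#'
#' @param feature Character vector of feature names.
#' @return Character vector of family labels.
#' @export
feature_family <- function(feature) {
  dplyr::case_when(
    grepl("_cbf_sti$", feature) ~ "singleTI_CBF",
    grepl("_cbf_mti$", feature) ~ "multiTI_CBF",
    grepl("_bat_mti$", feature) ~ "multiTI_BAT",
    TRUE ~ NA_character_
  )
}

#' Simulate a study cohort table
#'
#' Generates the per-subject table the statistical stage consumes:
#' demographics, hematology (with CaO2 via [compute_cao2()] and blood T1
#' via [estimate_t1_blood()]), treatments, SCI burden, intracranial volume,
#' education decile, the nine ROI-level hemodynamic features, and cognitive
#' scores. Within the patient group, CBF features are drawn with a negative
#' linear dependence on CaO2 (residual SD shrunk so the marginal SD matches
#' the configured value); IQ depends on log sinus multi-TI CBF and PSI on WM
#' multi-TI CBF through the planted slopes. The draw is deterministic given
#' `spec$seed`, and each subject also receives a derived `subject_seed` (for
#' reproducible image simulation downstream).
#'
#' @param spec A [cohort_spec()].
#' @return A tibble, one row per subject, with the generating spec attached
#'   as attribute `"spec"`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_sca + spec$n_control
  if (spec$n_sca < 10 || spec$n_control < 10) {
    warning("simulate_cohort: very small groups; downstream analyses may be",
            " unstable")
  }
  group <- rep(c("SCA", "control"), c(spec$n_sca, spec$n_control))
  sca <- group == "SCA"

  age <- stats::runif(n, 8, 28)
  sex <- ifelse(stats::runif(n) < ifelse(sca, 0.49, 0.38), "male", "female")
  hemoglobin <- ifelse(sca,
                       pmin(pmax(stats::rnorm(n, 8.6, 1.2), 5.5), 12),
                       pmin(pmax(stats::rnorm(n, 13.2, 1.0), 11), 16.5))
  hematocrit <- pmin(pmax(hemoglobin * 0.03 +
                            stats::rnorm(n, 0, 0.005), 0.15), 0.55)
  spo2 <- ifelse(sca,
                 pmin(stats::rnorm(n, 0.97, 0.015), 1),
                 pmin(stats::rnorm(n, 0.99, 0.006), 1))
  spo2 <- pmax(spo2, 0.85)
  cao2 <- compute_cao2(hemoglobin, spo2)
  t1_blood <- estimate_t1_blood(hematocrit, spo2)

  hydroxycarbamide <- sca & stats::runif(n) < spec$p_hydroxycarbamide
  transfusion <- sca & stats::runif(n) < spec$p_transfusion
  sci <- stats::runif(n) < ifelse(sca, spec$p_sci_sca, spec$p_sci_control)
  sci_burden <- ifelse(
    sci,
    round(exp(stats::rnorm(n, ifelse(sca, log(59), log(19)),
                           ifelse(sca, 1.11, 0.6)))),
    0)
  etiv <- stats::rnorm(n, 1.45e6, 1.4e5)
  education_decile <- sample(1:10, n, replace = TRUE)

  # hemodynamic features: group mean/SD, CaO2-coupled CBF within SCA
  feat <- spec$features
  out <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)), group = group, age = age,
    sex = sex, hemoglobin = hemoglobin, hematocrit = hematocrit,
    spo2 = spo2, cao2 = cao2, t1_blood = t1_blood,
    hydroxycarbamide = hydroxycarbamide, transfusion = transfusion,
    sci = sci, sci_burden = sci_burden, etiv = etiv,
    education_decile = education_decile
  )
  cao2_c <- cao2 - ifelse(sca, mean(cao2[sca]), mean(cao2[!sca]))
  sd_cao2_sca <- stats::sd(cao2[sca])
  for (fn in unique(feat$feature)) {
    vals <- numeric(n)
    for (gr in c("SCA", "control")) {
      row <- feat[feat$feature == fn & feat$group == gr, ]
      idx <- group == gr
      is_cbf <- grepl("_cbf_", fn)
      if (gr == "SCA" && is_cbf) {
        # plant CaO2 coupling with target |r| = cao2_slope_frac, keeping
        # the marginal SD at the configured value
        r <- spec$cao2_slope_frac
        slope <- -r * row$sd / sd_cao2_sca
        resid_sd <- row$sd * sqrt(max(0, 1 - r^2))
        draw <- row$mean + slope * cao2_c[idx] +
          stats::rnorm(sum(idx), 0, resid_sd)
      } else {
        draw <- stats::rnorm(sum(idx), row$mean, row$sd)
      }
      vals[idx] <- if (row$log) exp(draw) else draw
    }
    out[[fn]] <- vals
  }

  # cognition: IQ coupled to log venous CBF, PSI to WM CBF; WMI and the
  # executive (Tower) scores carry group shifts only
  resid <- function(sd) stats::rnorm(n, 0, sd)
  log_sinus <- log(out$sinus_cbf_mti)
  iq_base <- ifelse(sca, 92.63, 98.10)
  out$iq <- iq_base + spec$iq_sinus_slope *
    (log_sinus - ave(log_sinus, group)) + resid(spec$cognition_sd)
  out$wmi <- ifelse(sca, 91.73, 99.24) + resid(13.5)
  psi_base <- ifelse(sca, 89.49, 97.55)
  out$psi <- psi_base + spec$wm_psi_slope *
    (out$wm_cbf_mti - ave(out$wm_cbf_mti, group)) + resid(spec$cognition_sd)
  out$tower_achievement <- pmax(1, pmin(19, round(
    ifelse(sca, 9, 9.5) + resid(2.2))))
  out$tower_time <- ifelse(sca, 559.44, 561.17) + resid(149)

  out$subject_seed <- (spec$seed %% 1000003L) * 1000L + seq_len(n)
  attr(out, "spec") <- spec
  out
}
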