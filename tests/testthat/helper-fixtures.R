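# shared fixtures: tiny phantoms and series, built in code at test time

tiny_physio <- function(group = "SCA") {
  if (group == "SCA") {
    subject_physiology("T01", "SCA", age = 15, sex = "male",
                       hemoglobin = 8.5, hematocrit = 0.24, spo2 = 0.97)
  } else {
    subject_physiology("T02", "control", age = 16, sex = "female",
                       hemoglobin = 13.2, hematocrit = 0.41, spo2 = 0.99)
  }
}

tiny_phantom <- function(matrix_size = c(24, 24, 4), ...) {
  make_phantom(matrix_size = matrix_size, ...)
}

tiny_series <- function(kind = "singleTI_pCASL", noise_sd = 0, seed = 7,
                        matrix_size = c(24, 24, 4), truth = NULL,
                        physio = tiny_physio()) {
  if (is.null(truth)) truth <- tiny_phantom(matrix_size)
  acq <- acquisition_spec(kind, matrix_size = matrix_size)
  simulate_series(truth, acq, physio, noise_sd = noise_sd, seed = seed)
}

# a curve-only multi-TI "series": n voxels along x, one voxel y/z
curve_series <- function(curves, m0_val = 900) {
  n <- nrow(curves)
  acq <- acquisition_spec("multiTI_PASL", matrix_size = c(n, 1, 1))
  dat <- array(curves, dim = c(n, 1, 1, ncol(curves)))
  structure(list(data = dat, m0 = array(m0_val, c(n, 1, 1)), acq = acq,
                 params = NULL, noise_sd = NA_real_),
            class = "asl_series")
}

# independent brute-force BH step-up oracle (definition, not p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(ord == i)  # rank of p[i]
    cand <- vapply(r:m, function(j) min(1, m * p[ord[j]] / j), numeric(1))
    adj[i] <- min(cand)
  }
  adj
}

# null cohort spec: identical feature distributions in both groups, no
# planted couplings
null_cohort_spec <- function(seed, n_sca = 90, n_control = 40) {
  feat <- default_feature_table()
  ctrl <- feat[feat$group == "control", ]
  both <- rbind(transform(ctrl, group = "SCA"), ctrl)
  cohort_spec(n_sca = n_sca, n_control = n_control,
              features = tibble::as_tibble(both),
              cao2_slope_frac = 0, iq_sinus_slope = 0, wm_psi_slope = 0,
              seed = seed)
}
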