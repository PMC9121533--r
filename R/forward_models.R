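#' Single-TI pCASL quantification parameters
#'
#' Parameter set for the single post-labeling-delay pCASL quantification
#' (Alsop consensus form): blood-brain partition coefficient `lam` (mL/g),
#' labeling efficiency `alpha`, label duration `tau` (s), post-labeling
#' delay `pld` (s) and subject-specific blood T1 (s).
#'
#' @param t1_blood Blood T1 in seconds (subject specific; see
#'   [estimate_t1_blood()]).
#' @param lam Partition coefficient, mL/g.
#' @param alpha Labeling efficiency in (0, 1].
#' @param tau Label duration, s.
#' @param pld Post-labeling delay, s.
#' @return List of class `pcasl_params`.
#' @export
pcasl_params <- function(t1_blood, lam = 0.9, alpha = 0.85, tau = 1.8,
                         pld = 1.5) {
  p <- list(lam = lam, alpha = alpha, tau = tau, pld = pld,
            t1_blood = t1_blood)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1 &&
                    is.finite(x) && x > 0, logical(1)))) {
    stop("pcasl_params: all parameters must be finite, positive scalars",
         call. = FALSE)
  }
  if (alpha > 1) stop("pcasl_params: alpha must be <= 1", call. = FALSE)
  structure(p, class = "pcasl_params")
}

#' Multi-TI PASL kinetic-model parameters
#'
#' Parameter set for the pulsed-label Buxton general kinetic model:
#' partition coefficient `lam`, labeling efficiency `alpha`, bolus temporal
#' width `tau` (s; the QUIPSS-II/Q2TIPS saturation delay), blood T1 and a
#' single fixed tissue T1. The default `t1_tissue` of 1.9 s is intermediate
#' between anemic and normal blood T1, a choice aimed at venous (blood-pool)
#' signal rather than tissue accuracy.
#'
#' @param t1_blood Blood T1, s (subject specific).
#' @param lam Partition coefficient, mL/g.
#' @param alpha Labeling efficiency in (0, 1].
#' @param tau Bolus temporal width, s.
#' @param t1_tissue Tissue T1, s.
#' @param m0_scale Blood equilibrium magnetization convention:
#'   `m0_blood = m0_tissue / lam` when deriving M0b from a proton-density
#'   image (the default); kept here so the convention is configurable.
#' @return List of class `pasl_params`.
#' @export
pasl_params <- function(t1_blood = 1.88, lam = 0.9, alpha = 0.98, tau = 0.7,
                        t1_tissue = 1.9, m0_scale = NULL) {
  p <- list(lam = lam, alpha = alpha, tau = tau, t1_blood = t1_blood,
            t1_tissue = t1_tissue)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1 &&
                    is.finite(x) && x > 0, logical(1)))) {
    stop("pasl_params: all parameters must be finite, positive scalars",
         call. = FALSE)
  }
  if (alpha > 1) stop("pasl_params: alpha must be <= 1", call. = FALSE)
  p$m0_scale <- if (is.null(m0_scale)) 1 / lam else m0_scale
  structure(p, class = "pasl_params")
}

#' Forward single-TI pCASL difference signal
#'
#' Exact algebraic inverse of [pcasl_quantify()]; used to simulate
#' difference images from a known CBF map:
#' \deqn{\Delta M = \frac{CBF \cdot 2\alpha T_{1b} M_0
#'   (1 - e^{-\tau/T_{1b}}) e^{-PLD/T_{1b}}}{6000 \lambda}}
#'
#' @param cbf CBF in mL/100g/min (>= 0); vectorised.
#' @param m0 Proton-density signal (> 0); vectorised.
#' @param p A [pcasl_params()] set.
#' @return Difference signal in the units of `m0`; 0 iff `cbf` is 0.
#' @export
pcasl_forward <- function(cbf, m0, p) {
  stopifnot(inherits(p, "pcasl_params"))
  if (any(!is.finite(cbf)) || any(cbf < 0, na.rm = TRUE)) {
    stop("pcasl_forward: 'cbf' must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(m0))) {
    stop("pcasl_forward: 'm0' must be finite", call. = FALSE)
  }
  cbf * 2 * p$alpha * p$t1_blood * m0 *
    (1 - exp(-p$tau / p$t1_blood)) * exp(-p$pld / p$t1_blood) /
    (6000 * p$lam)
}

#' Quantify CBF from a single-TI pCASL difference signal
#'
#' Single-delay quantification:
#' \deqn{CBF = \frac{6000 \lambda \, \Delta M \, e^{PLD/T_{1b}}}
#'   {2\alpha T_{1b} M_0 (1 - e^{-\tau/T_{1b}})}}
#' Negative difference signal yields negative CBF — no clipping is applied
#' here; masking is a downstream concern. Voxels whose `m0` falls below
#' `m0_floor` are flagged invalid by returning `NaN` rather than raising an
#' error, so that map-level quantification can proceed.
#'
#' @param delta_m Difference signal; vectorised.
#' @param m0 Proton-density signal; vectorised.
#' @param p A [pcasl_params()] set.
#' @param m0_floor Positive floor below which `m0` is considered unusable.
#' @return CBF in mL/100g/min (`NaN` where `m0 <= m0_floor`).
#' @export
pcasl_quantify <- function(delta_m, m0, p, m0_floor = 1e-6) {
  stopifnot(inherits(p, "pcasl_params"), m0_floor > 0)
  cbf <- 6000 * p$lam * delta_m * exp(p$pld / p$t1_blood) /
    (2 * p$alpha * p$t1_blood * m0 * (1 - exp(-p$tau / p$t1_blood)))
  cbf[!is.finite(m0) | m0 <= m0_floor] <- NaN
  cbf
}

# Decayed delivery integral (exp(-k*u1) - exp(-k*u2)) / k, with its
# analytic k -> 0 limit (u2 - u1). Written via expm1 for small-k stability.
.delivered <- function(k, u1, u2) {
  du <- u2 - u1
  small <- abs(k * du) < 1e-8 & abs(k) < 1e-8
  out <- ifelse(small, du, exp(-k * u1) * (-expm1(-k * du)) / k)
  out
}

#' Buxton pulsed-label kinetic signal (closed form)
#'
#' Evaluates the general kinetic model for a pulsed label: a box-car
#' arterial bolus of temporal width `tau` arriving at `bat`, decaying with
#' blood T1 before arrival and with the apparent tissue T1 after exchange,
#' where \eqn{1/T_{1,app} = 1/T_{1,tissue} + f/\lambda} and
#' \eqn{k = 1/T_{1b} - 1/T_{1,app}}. The three regimes (pre-arrival, bolus
#' in transit, bolus complete) are continuous at both breakpoints, and the
#' degenerate \eqn{k \to 0} case is handled by its analytic limit.
#'
#' Flow enters internally as \eqn{f = CBF/6000} (mL/g/s).
#'
#' @param t Time(s) after labeling, s; vectorised.
#' @param cbf CBF in mL/100g/min (scalar or vector recycled against `t`).
#' @param bat Bolus arrival time, s.
#' @param m0_blood Equilibrium blood magnetization (signal units).
#' @param p A [pasl_params()] set.
#' @return Difference signal \eqn{\Delta M(t)}.
#' @export
pasl_kinetic_signal <- function(t, cbf, bat, m0_blood, p) {
  stopifnot(inherits(p, "pasl_params"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("pasl_kinetic_signal: 't' must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(cbf)) || any(cbf < 0)) {
    stop("pasl_kinetic_signal: 'cbf' must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(bat)) || any(bat < 0)) {
    stop("pasl_kinetic_signal: 'bat' must be finite and >= 0", call. = FALSE)
  }
  n <- max(length(t), length(cbf), length(bat), length(m0_blood))
  t <- rep_len(t, n); cbf <- rep_len(cbf, n)
  bat <- rep_len(bat, n); m0b <- rep_len(m0_blood, n)

  f <- cbf / 6000                                   # mL/g/s
  inv_t1app <- 1 / p$t1_tissue + f / p$lam
  k <- 1 / p$t1_blood - inv_t1app
  amp <- 2 * m0b * f * p$alpha * exp(-t * inv_t1app)

  upper <- pmin(t, bat + p$tau)
  dm <- ifelse(t <= bat, 0, amp * .delivered(k, bat, upper))
  dm
}

#' Buxton kinetic signal by numerical convolution (oracle)
#'
#' Independent evaluation of the pulsed-label kinetic signal as the
#' delivery-residue-decay convolution
#' \deqn{\Delta M(t) = 2 M_{0b} \int_0^t f\, c(s)\, r(t-s)\, m(t-s)\, ds}
#' with box-car arterial input \eqn{c(s) = \alpha e^{-s/T_{1b}}} on
#' \eqn{[bat, bat+\tau)}, residue \eqn{r(u) = e^{-f u / \lambda}} and decay
#' \eqn{m(u) = e^{-u/T_{1,tissue}}}, by adaptive quadrature. Slower than
#' [pasl_kinetic_signal()] but shares none of its algebra; used as the
#' cross-check in tests.
#'
#' @inheritParams pasl_kinetic_signal
#' @param rel_tol Quadrature relative tolerance.
#' @return Difference signal \eqn{\Delta M(t)}.
#' @export
pasl_kinetic_numeric <- function(t, cbf, bat, m0_blood, p,
                                 rel_tol = 1e-9) {
  stopifnot(inherits(p, "pasl_params"))
  f <- cbf / 6000
  vapply(t, function(ti) {
    if (ti <= bat || f == 0) return(0)
    up <- min(ti, bat + p$tau)
    integrand <- function(s) {
      f * p$alpha * exp(-s / p$t1_blood) *
        exp(-(f / p$lam) * (ti - s)) * exp(-(ti - s) / p$t1_tissue)
    }
    q <- stats::integrate(integrand, lower = bat, upper = up,
                          rel.tol = rel_tol, abs.tol = 1e-13)
    if (q$message != "OK") {
      stop("pasl_kinetic_numeric: quadrature did not converge",
           call. = FALSE)
    }
    2 * m0_blood * q$value
  }, numeric(1))
}
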