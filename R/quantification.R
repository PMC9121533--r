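#' Perfusion map container
#'
#' @param cbf,bat,rss,converged,degenerate 3D arrays (BAT/RSS/convergence
#'   only for multi-TI fits).
#' @param params The parameter set used.
#' @param sequence `"singleTI"` or `"multiTI"`.
#' @return List of class `perfusion_maps` with a provenance record.
#' @keywords internal
new_perfusion_maps <- function(cbf, bat = NULL, rss = NULL,
                               converged = NULL, degenerate = NULL,
                               params, sequence) {
  structure(list(
    cbf = cbf, bat = bat, rss = rss, converged = converged,
    degenerate = degenerate, params = params, sequence = sequence,
    provenance = list(
      package = "venoasl",
      version = as.character(utils::packageVersion("venoasl")),
      params = unclass(params), sequence = sequence,
      optimizer = if (sequence == "multiTI")
        "L-BFGS-B, multi-start over the TI grid in BAT" else NA_character_
    )
  ), class = "perfusion_maps")
}

#' Single-TI CBF map
#'
#' Applies [pcasl_quantify()] voxel-wise inside a mask; voxels outside the
#' mask are `NA`.
#'
#' @param mean_diff 3D mean difference image (see [mean_difference()]).
#' @param m0 3D proton-density image on the same grid.
#' @param p A [pcasl_params()] set.
#' @param mask 3D logical array.
#' @param m0_floor Positive floor on usable `m0`.
#' @return A `perfusion_maps` object with the `cbf` map.
#' @export
quantify_singleti <- function(mean_diff, m0, p, mask,
                              m0_floor = 1e-6) {
  stopifnot(all(dim(mean_diff) == dim(m0)), all(dim(mean_diff) == dim(mask)))
  cbf <- array(NA_real_, dim = dim(mean_diff))
  idx <- which(mask)
  cbf[idx] <- pcasl_quantify(mean_diff[idx], m0[idx], p, m0_floor = m0_floor)
  new_perfusion_maps(cbf = cbf, params = p, sequence = "singleTI")
}

# residual sum of squares of the kinetic model against one voxel's curve
.rss_voxel <- function(par, ti, obs, m0b, params) {
  pred <- pasl_kinetic_signal(ti, par[1], par[2], m0b, params)
  sum((obs - pred)^2)
}

# fit one voxel: bounded least squares, multi-start over a BAT grid with
# initial-RSS screening, tie-break toward the smallest BAT
.fit_voxel <- function(ti, obs, m0b, p, cbf_max, bat_grid, n_starts = 4) {
  bat_max <- max(ti)
  # unit-amplitude curves per start give a cheap linear CBF initialiser;
  # starts are then ranked by their initial RSS and only the most promising
  # n_starts are polished (BAT aliasing shows up in the initial RSS)
  inits <- t(vapply(bat_grid, function(bat0) {
    s1 <- pasl_kinetic_signal(ti, 1, bat0, m0b, p)
    peak <- max(s1)
    cbf0 <- if (peak > 0) min(max(max(obs) / peak, 1), cbf_max) else 60
    c(cbf0 = cbf0, bat0 = bat0,
      rss0 = .rss_voxel(c(cbf0, bat0), ti, obs, m0b, p))
  }, numeric(3)))
  ord <- order(inits[, "rss0"], inits[, "bat0"])
  keep <- ord[seq_len(min(n_starts, nrow(inits)))]
  fits <- list()
  for (i in keep) {
    cbf0 <- inits[i, "cbf0"]; bat0 <- inits[i, "bat0"]
    fit <- try(stats::optim(
      c(cbf0, bat0), .rss_voxel, ti = ti, obs = obs, m0b = m0b,
      params = p, method = "L-BFGS-B", lower = c(0, 0), upper = c(cbf_max, bat_max),
      control = list(factr = 1e1, maxit = 300,
                     parscale = c(max(cbf0, 10), 1),
                     ndeps = c(1e-6, 1e-6))), silent = TRUE)
    if (!inherits(fit, "try-error")) fits[[length(fits) + 1]] <- fit
  }
  if (length(fits) == 0) return(NULL)
  pick <- function(cands) {
    best <- cands[[1]]
    for (fit in cands[-1]) {
      tol <- 1e-12 * max(abs(best$value), 1e-12)
      if (fit$value < best$value - tol ||
          (abs(fit$value - best$value) <= tol && fit$par[2] < best$par[2])) {
        best <- fit
      }
    }
    best
  }
  best <- pick(fits)
  # an L-BFGS-B line-search stall (code 52) at an already-converged optimum
  # should not displace a cleanly converged equal-RSS fit
  if (best$convergence != 0) {
    clean <- Filter(function(f) f$convergence == 0, fits)
    if (length(clean)) {
      alt <- pick(clean)
      if (alt$value <= best$value + 1e-9 * max(sum(obs^2), 1e-12)) best <- alt
    }
  }
  # at factr = 1e1 the stopping rule sits at machine precision, where the
  # finite-difference line search can stall (code 52) on an already-optimal
  # point; that is convergence for our purposes, unlike iteration overflow
  if (best$convergence == 52) best$convergence <- 0
  # a fitted arrival at/after the last TI predicts zero signal everywhere:
  # CBF is unidentified, so report zero delivered flow and flag degenerate
  if (best$par[2] >= bat_max - 1e-9) {
    best$par[1] <- 0
    best$degenerate <- TRUE
  }
  best
}

#' Multi-TI joint CBF/BAT fitting
#'
#' Per masked voxel, minimises the residual sum of squares between the
#' observed multi-TI difference signal and [pasl_kinetic_signal()] over
#' `(cbf, bat)` with bounds `cbf` in `[0, cbf_max]` and `bat` in
#' `[0, max(TI)]`, by bounded quasi-Newton (L-BFGS-B) least squares with a
#' multi-start over a BAT grid (default: every TI; the objective is
#' multi-modal in BAT at low SNR). Among equal-RSS starts the smallest BAT
#' wins (earliest physically plausible arrival). Voxels with fewer than
#' `min_points` above-noise TI points are not fitted, and optimizer failure
#' at a voxel flags it unconverged without stopping the map.
#'
#' The default `cbf_max` of 3000 mL/100g/min deliberately accommodates the
#' extreme apparent values (~2500) seen in venous voxels, where labelled
#' water transits without tissue exchange and the fitted CBF is relative.
#'
#' @param series A multi-TI `asl_series`.
#' @param m0 3D proton-density image.
#' @param p A [pasl_params()] set.
#' @param mask 3D logical array; should lie inside the reliable-voxel mask
#'   (checked when `stats` is given).
#' @param stats Optional [background_stats()] for the above-noise count and
#'   the reliable-mask containment check.
#' @param cbf_max Upper CBF bound, mL/100g/min.
#' @param bat_grid Multi-start BAT values, s (default: the TI grid).
#' @param n_starts Number of screened starts polished per voxel.
#' @param min_points Minimum above-noise TI points needed to fit a voxel.
#' @return A `perfusion_maps` object with `cbf`, `bat`, `rss`, `converged`
#'   and `degenerate` (fit pinned at a CBF bound) maps.
#' @export
fit_multiti <- function(series, m0, p, mask, stats = NULL,
                        cbf_max = 3000, bat_grid = NULL, n_starts = 4,
                        min_points = 3) {
  stopifnot(inherits(series, "asl_series"))
  if (series$acq$kind != "multiTI_PASL") {
    stop("fit_multiti: expected a multiTI_PASL series", call. = FALSE)
  }
  ti <- series$acq$inflow_times
  d <- dim(series$data)
  stopifnot(all(d[1:3] == dim(mask)), all(d[1:3] == dim(m0)))
  if (is.null(bat_grid)) bat_grid <- ti
  if (!is.null(stats)) {
    rel <- reliable_voxel_mask(series, stats)
    if (any(mask & !rel)) {
      warning("fit_multiti: mask contains voxels outside the reliable-voxel",
              " mask")
    }
  }
  nvox <- prod(d[1:3])
  dat <- matrix(series$data, nvox, d[4])
  cbf <- array(NA_real_, d[1:3]); bat <- array(NA_real_, d[1:3])
  rss <- array(NA_real_, d[1:3])
  conv <- array(FALSE, d[1:3]); degen <- array(FALSE, d[1:3])
  noise_floor <- if (is.null(stats)) -Inf else stats$mean + stats$sd
  m0b_all <- m0 * p$m0_scale
  for (v in which(mask)) {
    obs <- dat[v, ]
    if (sum(obs > noise_floor) < min_points) next
    fit <- .fit_voxel(ti, obs, m0b_all[v], p, cbf_max, bat_grid, n_starts)
    if (is.null(fit)) next
    ok <- fit$convergence == 0
    conv[v] <- ok
    if (ok) {
      cbf[v] <- fit$par[1]; bat[v] <- fit$par[2]; rss[v] <- fit$value
      degen[v] <- isTRUE(fit$degenerate) || fit$par[1] <= 1e-9 ||
        fit$par[1] >= cbf_max - 1e-9
    }
  }
  new_perfusion_maps(cbf = cbf, bat = bat, rss = rss, converged = conv,
                     degenerate = degen, params = p, sequence = "multiTI")
}

#' @export
print.perfusion_maps <- function(x, ...) {
  cat(sprintf("<perfusion_maps: %s, %s voxels fitted>\n", x$sequence,
              sum(is.finite(x$cbf))))
  invisible(x)
}

#' Summarise a perfusion map fit
#'
#' @param x A `perfusion_maps` object.
#' @param ... Unused.
#' @return One-row tibble: voxels fitted, convergence and degeneracy
#'   fractions, CBF/BAT medians.
#' @method glance perfusion_maps
#' @export
glance.perfusion_maps <- function(x, ...) {
  n_fit <- sum(is.finite(x$cbf))
  tibble::tibble(
    sequence = x$sequence, n_fitted = n_fit,
    frac_converged = if (is.null(x$converged)) NA_real_
      else sum(x$converged) / max(1, n_fit),
    frac_degenerate = if (is.null(x$degenerate)) NA_real_
      else sum(x$degenerate) / max(1, n_fit),
    median_cbf = stats::median(x$cbf[is.finite(x$cbf)]),
    median_bat = if (is.null(x$bat)) NA_real_
      else stats::median(x$bat[is.finite(x$bat)])
  )
}

#' Per-voxel tidy view of a perfusion map
#'
#' @param x A `perfusion_maps` object.
#' @param ... Unused.
#' @return Tibble with voxel indices and fitted values (finite-CBF voxels).
#' @method tidy perfusion_maps
#' @export
tidy.perfusion_maps <- function(x, ...) {
  idx <- which(is.finite(x$cbf), arr.ind = TRUE)
  li <- which(is.finite(x$cbf))
  cbf <- x$cbf[li]
  bat <- if (is.null(x$bat)) rep(NA_real_, length(li)) else x$bat[li]
  rss <- if (is.null(x$rss)) rep(NA_real_, length(li)) else x$rss[li]
  conv <- if (is.null(x$converged)) rep(NA, length(li)) else x$converged[li]
  tibble::tibble(x = idx[, 1], y = idx[, 2], z = idx[, 3],
                 cbf = cbf, bat = bat, rss = rss, converged = conv)
}

#' Plot an axial slice of a perfusion map
#'
#' @param object A `perfusion_maps` object.
#' @param map `"cbf"` or `"bat"`.
#' @param slice Axial slice index (default: middle).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot perfusion_maps
#' @export
autoplot.perfusion_maps <- function(object, map = c("cbf", "bat"),
                                    slice = NULL, ...) {
  map <- match.arg(map)
  arr <- object[[map]]
  if (is.null(arr)) stop("autoplot: map not present", call. = FALSE)
  if (is.null(slice)) slice <- ceiling(dim(arr)[3] / 2)
  df <- tidyr::expand_grid(x = seq_len(dim(arr)[1]),
                           y = seq_len(dim(arr)[2]))
  df$value <- arr[cbind(df$x, df$y, slice)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = if (map == "cbf") "CBF\n(mL/100g/min)"
                  else "BAT (s)",
                  title = sprintf("%s map, slice %d", toupper(map), slice))
}
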