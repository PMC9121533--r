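#' Mean difference image of a single-TI series
#'
#' Voxel-wise arithmetic mean of the repeated single-TI pCASL difference
#' volumes.
#'
#' @param series An `asl_series` from [simulate_series()] or
#'   [read_asl_series()], of kind `singleTI_pCASL`.
#' @return A 3D array.
#' @export
mean_difference <- function(series) {
  stopifnot(inherits(series, "asl_series"))
  if (series$acq$kind != "singleTI_pCASL") {
    stop("mean_difference: expected a singleTI_pCASL series", call. = FALSE)
  }
  d <- dim(series$data)
  array(rowMeans(matrix(series$data, prod(d[1:3]), d[4])), dim = d[1:3])
}

#' Ghost-free background statistics
#'
#' Places four square background ROIs of the given width in the in-plane
#' corners of the field of view and pools the difference signal over all
#' slices and all volumes of the series, returning its mean and standard
#' deviation. The pooled voxel count is `4 * width^2 * n_slices *
#' n_volumes`. Per-volume statistics are available via `per_volume`.
#'
#' @param series An `asl_series`.
#' @param width Corner square width, voxels (default 5).
#' @param per_volume If `TRUE`, also return a per-volume mean/sd table.
#' @param tissue_mask Optional 3D logical array; a warning is raised if any
#'   corner box overlaps it.
#' @return List of class `background_stats`: `mean`, `sd`, `n_voxels`,
#'   `corner_boxes` (index ranges), optionally `per_volume`.
#' @export
background_stats <- function(series, width = 5, per_volume = FALSE,
                             tissue_mask = NULL) {
  stopifnot(inherits(series, "asl_series"))
  d <- dim(series$data)
  nx <- d[1]; ny <- d[2]; nz <- d[3]; nv <- d[4]
  if (nx < 3 * width || ny < 3 * width) {
    stop("background_stats: in-plane matrix must be at least 3x the corner",
         " width", call. = FALSE)
  }
  xr <- list(1:width, (nx - width + 1):nx)
  yr <- list(1:width, (ny - width + 1):ny)
  boxes <- list(
    list(x = xr[[1]], y = yr[[1]]), list(x = xr[[1]], y = yr[[2]]),
    list(x = xr[[2]], y = yr[[1]]), list(x = xr[[2]], y = yr[[2]]))
  in_box <- matrix(FALSE, nx, ny)
  for (b in boxes) in_box[b$x, b$y] <- TRUE
  if (!is.null(tissue_mask) &&
      any(tissue_mask & array(in_box, dim = c(nx, ny, nz)))) {
    warning("background_stats: corner boxes overlap the tissue mask")
  }
  sel <- array(in_box, dim = c(nx, ny, nz, nv))
  vals <- series$data[sel]
  out <- structure(list(
    mean = mean(vals), sd = stats::sd(vals), n_voxels = length(vals),
    corner_boxes = boxes, width = width
  ), class = "background_stats")
  if (per_volume) {
    pv <- t(vapply(seq_len(nv), function(v) {
      x <- series$data[, , , v][array(in_box, dim = c(nx, ny, nz))]
      c(mean = mean(x), sd = stats::sd(x))
    }, numeric(2)))
    out$per_volume <- tibble::tibble(volume = seq_len(nv),
                                     mean = pv[, 1], sd = pv[, 2])
  }
  out
}

#' Reliable-voxel mask
#'
#' A voxel is reliable when its difference signal exceeds the ghost-free
#' background mean plus `multiplier` standard deviations on at least one
#' volume of the series. The comparison is strict (`>`).
#'
#' @param series An `asl_series`.
#' @param stats A [background_stats()] result from the same series.
#' @param multiplier Threshold multiplier on the background SD (default 1).
#' @return A 3D logical array.
#' @export
reliable_voxel_mask <- function(series, stats, multiplier = 1) {
  stopifnot(inherits(series, "asl_series"),
            inherits(stats, "background_stats"))
  d <- dim(series$data)
  mx <- apply(series$data, 1:3, max)
  array(mx > stats$mean + multiplier * stats$sd, dim = d[1:3])
}

#' Volume-to-volume drift QC
#'
#' Flags series whose volume-to-volume center-of-mass drift (of absolute
#' signal) exceeds a limit, mirroring a motion-exclusion policy without
#' re-implementing registration. Inputs are assumed pre-aligned; this is a
#' guard, not a correction.
#'
#' @param series An `asl_series`.
#' @param limit_voxels Maximum allowed drift of the signal center of mass
#'   between consecutive volumes, voxels.
#' @return A one-row tibble with `max_drift` and logical `pass`.
#' @export
qc_series_drift <- function(series, limit_voxels = 1) {
  stopifnot(inherits(series, "asl_series"))
  d <- dim(series$data)
  idx <- list(slice.index(array(0, d[1:3]), 1),
              slice.index(array(0, d[1:3]), 2),
              slice.index(array(0, d[1:3]), 3))
  com <- t(vapply(seq_len(d[4]), function(v) {
    w <- abs(series$data[, , , v]); tw <- sum(w)
    vapply(idx, function(ix) sum(ix * w) / tw, numeric(1))
  }, numeric(3)))
  drift <- if (d[4] < 2) 0 else max(sqrt(rowSums(diff(com)^2)))
  tibble::tibble(max_drift = drift, pass = drift <= limit_voxels)
}
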