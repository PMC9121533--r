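#' Morphological box erosion of a 3D mask
#'
#' Erodes a logical mask with a cubic box structuring element of the given
#' width: a voxel survives iff every voxel of the box placed at it lies in
#' the mask. For even widths the box has no central voxel; the origin is
#' taken at the lower-corner voxel (offsets `0 .. width-1` along each
#' axis), so eroding a solid cube of side n with width 2 leaves a cube of
#' side n-1. Used to trim partial-volume rims from tissue and vein masks.
#'
#' @param mask 3D logical array.
#' @param width Box width, voxels (default 2).
#' @return Eroded 3D logical array (may be empty, with a warning).
#' @export
erode_mask <- function(mask, width = 2) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3, width >= 1)
  if (!any(mask)) stop("erode_mask: mask is empty", call. = FALSE)
  d <- dim(mask)
  out <- mask
  offs <- as.matrix(expand.grid(dx = 0:(width - 1), dy = 0:(width - 1),
                                dz = 0:(width - 1)))
  shift_and <- function(acc, o) {
    sh <- array(FALSE, d)
    xs <- seq_len(d[1] - o[1]); ys <- seq_len(d[2] - o[2])
    zs <- seq_len(d[3] - o[3])
    sh[xs, ys, zs] <- mask[xs + o[1], ys + o[2], zs + o[3]]
    acc & sh
  }
  for (i in seq_len(nrow(offs))) out <- shift_and(out, offs[i, ])
  if (!any(out)) warning("erode_mask: erosion emptied the mask")
  out
}

#' High-signal sagittal-sinus ROI
#'
#' Restricts a sinus mask to its highest-signal part: the threshold is the
#' given percentile (linear-interpolation definition) of the finite
#' single-TI CBF values inside the mask, and voxels at or above it are
#' retained. With distinct values and the default 90th percentile this
#' keeps the top 10% of in-mask voxels. The ROI is defined once from the
#' single-TI CBF map and then applied to every map family.
#'
#' @param cbf_singleti 3D single-TI CBF map.
#' @param sinus_mask 3D logical sinus mask (needs >= 10 finite-valued
#'   voxels).
#' @param percentile Percentile cutoff in (0, 100); default 90.
#' @param subject_id Optional label used in error messages.
#' @return 3D logical array, a subset of `sinus_mask`.
#' @export
high_signal_roi <- function(cbf_singleti, sinus_mask, percentile = 90,
                            subject_id = NULL) {
  stopifnot(all(dim(cbf_singleti) == dim(sinus_mask)))
  ok <- sinus_mask & is.finite(cbf_singleti)
  if (sum(ok) < 10) {
    stop(sprintf(
      "high_signal_roi: fewer than 10 finite sinus voxels%s",
      if (is.null(subject_id)) "" else paste0(" for subject ", subject_id)),
      call. = FALSE)
  }
  thr <- stats::quantile(cbf_singleti[ok], percentile / 100, names = FALSE,
                         type = 7)
  ok & cbf_singleti >= thr
}

#' Mean of a map over an ROI
#'
#' Mean over the finite map values inside the ROI, with the voxel count and
#' the coverage fraction (finite-valued in-ROI voxels / ROI size); partial
#' FOV coverage of the sinus is the norm in real acquisitions, so coverage
#' is always reported.
#'
#' @param map 3D numeric array.
#' @param roi 3D logical array on the same grid.
#' @return One-row tibble: `mean`, `n_voxels`, `coverage`.
#' @export
roi_mean <- function(map, roi) {
  stopifnot(all(dim(map) == dim(roi)))
  n_roi <- sum(roi)
  vals <- map[roi & is.finite(map)]
  tibble::tibble(
    mean = if (length(vals)) mean(vals) else NaN,
    n_voxels = length(vals),
    coverage = if (n_roi > 0) length(vals) / n_roi else 0
  )
}

#' Build the ROI set for one subject
#'
#' Erodes the gray-matter, white-matter and sinus masks with a box of the
#' given width (partial-volume control) and derives the high-signal sinus
#' ROI from the single-TI CBF map.
#'
#' @param gm,wm,sinus 3D logical input masks (externally produced
#'   segmentations or phantom labels).
#' @param cbf_singleti 3D single-TI CBF map used to define the high-signal
#'   sinus ROI.
#' @param erode_width Box width for erosion; 0 skips erosion.
#' @param percentile Sinus percentile cutoff.
#' @param subject_id Optional label for error messages.
#' @return List of class `roi_set`: `gm`, `wm`, `sinus_full`, `sinus_high`.
#' @export
build_roi_set <- function(gm, wm, sinus, cbf_singleti, erode_width = 2,
                          percentile = 90, subject_id = NULL) {
  er <- function(m) if (erode_width >= 1) erode_mask(m, erode_width) else m
  gm_e <- er(gm); wm_e <- er(wm); sinus_e <- er(sinus)
  structure(list(
    gm = gm_e, wm = wm_e, sinus_full = sinus_e,
    sinus_high = high_signal_roi(cbf_singleti, sinus_e, percentile,
                                 subject_id = subject_id),
    percentile = percentile
  ), class = "roi_set")
}

#' Extract per-subject ROI features
#'
#' Assembles one feature row per subject: ROI-mean single-TI CBF, multi-TI
#' CBF and multi-TI BAT over gray matter, white matter and the high-signal
#' sinus ROI, with coverage columns. A missing sequence leaves its features
#' missing but keeps the row.
#'
#' @param maps Named list with elements `singleti` and/or `multiti`, each a
#'   `perfusion_maps` object (or `NULL`).
#' @param rois A [build_roi_set()] result.
#' @param subject_id Optional identifier column value.
#' @return One-row tibble of features and coverages.
#' @export
extract_features <- function(maps, rois, subject_id = NA_character_) {
  stopifnot(inherits(rois, "roi_set"))
  grab <- function(map, roi) {
    if (is.null(map)) return(c(NA_real_, NA_real_))
    r <- roi_mean(map, roi)
    c(r$mean, r$coverage)
  }
  sti <- maps$singleti; mti <- maps$multiti
  regions <- list(gm = rois$gm, wm = rois$wm, sinus = rois$sinus_high)
  out <- tibble::tibble(subject_id = as.character(subject_id))
  for (rg in names(regions)) {
    v <- grab(if (is.null(sti)) NULL else sti$cbf, regions[[rg]])
    out[[paste0(rg, "_cbf_sti")]] <- v[1]
    out[[paste0(rg, "_cbf_sti_coverage")]] <- v[2]
  }
  for (rg in names(regions)) {
    v <- grab(if (is.null(mti)) NULL else mti$cbf, regions[[rg]])
    out[[paste0(rg, "_cbf_mti")]] <- v[1]
    out[[paste0(rg, "_cbf_mti_coverage")]] <- v[2]
    b <- grab(if (is.null(mti)) NULL else mti$bat, regions[[rg]])
    out[[paste0(rg, "_bat_mti")]] <- b[1]
  }
  out
}
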