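# brute-force erosion oracle: voxel kept iff the whole w-box fits in mask
erode_oracle <- function(mask, width) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!mask[i, j, z]) next
    ok <- i + width - 1 <= d[1] && j + width - 1 <= d[2] &&
      z + width - 1 <= d[3]
    if (ok) ok <- all(mask[i:(i + width - 1), j:(j + width - 1),
                           z:(z + width - 1)])
    out[i, j, z] <- ok
  }
  out
}

test_that("box erosion shrinks a solid cube by width - 1 per axis", {
  m <- array(FALSE, c(14, 14, 14))
  m[3:12, 3:12, 3:12] <- TRUE                      # solid 10^3 cube
  e <- erode_mask(m, width = 2)
  expect_equal(sum(e), 9^3)
  expect_identical(e, erode_oracle(m, 2))
})

test_that("erosion matches the brute-force oracle on random masks", {
  set.seed(42)
  for (w in c(2, 3)) {
    m <- array(runif(12^3) < 0.7, c(12, 12, 12))
    m[1, 1, 1] <- TRUE                              # keep non-empty
    expect_identical(suppressWarnings(erode_mask(m, w)), erode_oracle(m, w))
  }
})

test_that("erosion is anti-extensive and warns when it empties the mask", {
  m <- array(FALSE, c(8, 8, 8)); m[4, 4, 4] <- TRUE
  expect_warning(e <- erode_mask(m, 2), "emptied")
  expect_false(any(e))
  m2 <- array(runif(10^3) < 0.8, c(10, 10, 10)); m2[5, 5, 5] <- TRUE
  e1 <- suppressWarnings(erode_mask(m2, 2))
  if (any(e1)) {
    e2 <- suppressWarnings(erode_mask(e1, 2))
    expect_true(all(m2[e1]))   # e1 subset of m2
    expect_true(all(e1[e2]))   # e2 subset of e1
  }
  expect_error(erode_mask(array(FALSE, c(4, 4, 4))), "empty")
})

test_that("the high-signal ROI keeps exactly the top decile of distinct values", {
  set.seed(9)
  d <- c(10, 10, 10)
  map <- array(sample(seq_len(1000)), d)            # 1000 distinct values
  mask <- array(TRUE, d)
  roi <- high_signal_roi(map, mask, percentile = 90)
  expect_equal(sum(roi), 100)
  # equals the brute-force sort-and-cut oracle
  cut <- sort(as.vector(map), decreasing = TRUE)[100]
  expect_identical(roi, mask & (map >= cut))
})

test_that("high-signal ROI handles degenerate and invalid inputs", {
  d <- c(5, 5, 4)
  const <- array(7, d)
  roi <- high_signal_roi(const, array(TRUE, d))
  expect_true(all(roi))                             # ties at the threshold
  small <- array(TRUE, d); small[] <- FALSE; small[1:5] <- TRUE
  expect_error(high_signal_roi(const, small, subject_id = "S9"), "S9")
  # retained fraction near 10% for distinct values, never below
  set.seed(10)
  map <- array(rnorm(prod(d)), d)
  roi2 <- high_signal_roi(map, array(TRUE, d))
  frac <- sum(roi2) / prod(d)
  expect_gte(frac, 0.10 - 1e-12)
  expect_lte(frac, 0.10 + 1 / prod(d))
})

test_that("ROI means handle constants, small ROIs, and partial coverage", {
  d <- c(6, 6, 3)
  expect_equal(roi_mean(array(3.3, d), array(TRUE, d))$mean, 3.3)
  m <- array(0, d); m[1] <- 10; m[2] <- 20
  roi <- array(FALSE, d); roi[1:2] <- TRUE
  r <- roi_mean(m, roi)
  expect_equal(r$mean, 15)
  expect_equal(r$n_voxels, 2)
  # non-finite voxels shrink coverage but not the mean of what remains
  m[2] <- NaN
  r2 <- roi_mean(m, roi)
  expect_equal(r2$mean, 10)
  expect_equal(r2$coverage, 0.5)
  r3 <- roi_mean(m, array(FALSE, d))
  expect_true(is.nan(r3$mean))
  expect_equal(r3$coverage, 0)
})

test_that("the high-signal sinus mean dominates the full-sinus mean", {
  set.seed(12)
  d <- c(12, 12, 6)
  map <- array(rlnorm(prod(d), 4, 0.5), d)
  sinus <- array(runif(prod(d)) < 0.4, d)
  sinus[1:20] <- TRUE
  high <- high_signal_roi(map, sinus)
  expect_true(all(high[!sinus] == FALSE))           # containment
  expect_gte(roi_mean(map, high)$mean, roi_mean(map, sinus)$mean)
})

test_that("feature extraction recovers planted values on a noiseless phantom", {
  ph <- tiny_phantom()
  ser_s <- tiny_series("singleTI_pCASL", noise_sd = 0)
  ser_m <- tiny_series("multiTI_PASL", noise_sd = 0)
  tis <- ph$segmentation > 0
  map_s <- quantify_singleti(mean_difference(ser_s), ph$m0, ser_s$params,
                             mask = tis)
  map_m <- fit_multiti(ser_m, ph$m0, ser_m$params, mask = tis)
  rois <- build_roi_set(ph$segmentation == 1L, ph$segmentation == 2L,
                        ph$segmentation == 3L, map_s$cbf, erode_width = 0)
  row <- extract_features(list(singleti = map_s, multiti = map_m), rois,
                          subject_id = "P1")
  expect_equal(row$gm_cbf_sti, 54, tolerance = 1e-8)
  expect_equal(row$wm_cbf_sti, 31, tolerance = 1e-8)
  expect_equal(row$sinus_cbf_sti, 105, tolerance = 1e-8)
  expect_equal(row$gm_bat_mti, 0.7, tolerance = 1e-4)
  expect_equal(row$sinus_bat_mti, 1.2, tolerance = 1e-4)
  expect_equal(row$gm_cbf_sti_coverage, 1)
  # a subject missing the multi-TI sequence keeps a row with NA features
  row2 <- extract_features(list(singleti = map_s, multiti = NULL), rois,
                           subject_id = "P2")
  expect_true(is.finite(row2$gm_cbf_sti))
  expect_true(is.na(row2$gm_cbf_mti) && is.na(row2$gm_bat_mti))
})

test_that("a three-subject feature table matches hand assembly", {
  d <- c(8, 8, 3)
  rois <- structure(list(
    gm = array(rep(c(TRUE, FALSE), c(32, prod(d) - 32)), d),
    wm = array(rep(c(FALSE, TRUE, FALSE), c(32, 32, prod(d) - 64)), d),
    sinus_full = array(rep(c(FALSE, TRUE), c(prod(d) - 20, 20)), d),
    sinus_high = array(rep(c(FALSE, TRUE), c(prod(d) - 10, 10)), d),
    percentile = 90), class = "roi_set")
  rows <- lapply(1:3, function(s) {
    cbf <- array(s * 10, d)
    maps <- list(
      singleti = structure(list(cbf = cbf, bat = NULL),
                           class = "perfusion_maps"),
      multiti = structure(list(cbf = cbf * 2, bat = array(s / 10, d)),
                          class = "perfusion_maps"))
    extract_features(maps, rois, subject_id = sprintf("S%d", s))
  })
  tab <- dplyr::bind_rows(rows)
  expect_equal(tab$gm_cbf_sti, c(10, 20, 30))
  expect_equal(tab$sinus_cbf_mti, c(20, 40, 60))
  expect_equal(tab$wm_bat_mti, c(0.1, 0.2, 0.3))
})
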