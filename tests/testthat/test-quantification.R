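test_that("single-TI quantification recovers the noiseless phantom exactly", {
  ph <- tiny_phantom()
  ser <- tiny_series("singleTI_pCASL", noise_sd = 0)
  md <- mean_difference(ser)
  tis <- ph$segmentation > 0
  maps <- quantify_singleti(md, ph$m0, ser$params, mask = tis)
  expect_equal(maps$cbf[tis], ph$cbf_true[tis], tolerance = 1e-12)
  expect_true(all(is.na(maps$cbf[!tis])))
  empty <- quantify_singleti(md, ph$m0, ser$params,
                             mask = array(FALSE, dim(md)))
  expect_true(all(!is.finite(empty$cbf)))
})

test_that("noisy single-TI ROI means stay within sampling error of truth", {
  ph <- tiny_phantom()
  ser <- tiny_series("singleTI_pCASL", noise_sd = 1.5, seed = 21)
  md <- mean_difference(ser)
  tis <- ph$segmentation > 0
  maps <- quantify_singleti(md, ph$m0, ser$params, mask = tis)
  gm <- ph$segmentation == 1L
  # voxel-level sd of the quantified noise: sd(md)/m0 * scale
  scale <- 6000 * 0.9 * exp(1.5 / ser$params$t1_blood) /
    (2 * 0.85 * ser$params$t1_blood * 1000 *
       (1 - exp(-1.8 / ser$params$t1_blood)))
  vox_sd <- 1.5 / sqrt(10) * scale
  se <- vox_sd / sqrt(sum(gm))
  expect_lt(abs(mean(maps$cbf[gm]) - 54), 3 * se)
})

test_that("multi-TI fitting recovers noiseless voxels to high precision", {
  p <- pasl_params(t1_blood = 1.88)
  ti <- make_ti_grid()
  cases <- expand.grid(cbf = c(25, 60, 300), bat = c(0.5, 1.0, 1.6))
  curves <- t(apply(cases, 1, function(cs) {
    pasl_kinetic_signal(ti, cs["cbf"], cs["bat"], 900 / 0.9, p)
  }))
  ser <- curve_series(curves)
  maps <- fit_multiti(ser, array(900, c(nrow(cases), 1, 1)), p,
                      mask = array(TRUE, c(nrow(cases), 1, 1)))
  expect_true(all(maps$converged[, 1, 1]))
  expect_equal(maps$cbf[, 1, 1], cases$cbf, tolerance = 1e-5)
  expect_equal(maps$bat[, 1, 1], cases$bat, tolerance = 1e-5)
  # BAT is finite only where converged; CBF only inside the mask
  expect_true(all(is.finite(maps$bat[maps$converged])))
  expect_true(all(!is.finite(maps$bat[!maps$converged])))
})

test_that("a zero-flow voxel pins at the lower bound and is flagged degenerate", {
  p <- pasl_params(t1_blood = 1.88)
  ti <- make_ti_grid()
  ser <- curve_series(matrix(0, 1, length(ti)))
  maps <- fit_multiti(ser, array(900, c(1, 1, 1)), p,
                      mask = array(TRUE, c(1, 1, 1)))
  expect_equal(maps$cbf[1, 1, 1], 0, tolerance = 1e-9)
  expect_true(maps$degenerate[1, 1, 1])
})

test_that("the winning fit beats every multi-start initialization", {
  p <- pasl_params(t1_blood = 1.88)
  ti <- make_ti_grid()
  set.seed(5)
  truth <- pasl_kinetic_signal(ti, 80, 0.9, 900 / 0.9, p)
  obs <- truth + rnorm(length(ti), 0, max(truth) / 8)
  fit <- venoasl:::.fit_voxel(ti, obs, 900 / 0.9, p, 3000, ti, n_starts = 10)
  for (bat0 in ti) {
    s1 <- pasl_kinetic_signal(ti, 1, bat0, 900 / 0.9, p)
    cbf0 <- if (max(s1) > 0) min(max(max(obs) / max(s1), 1), 3000) else 60
    rss0 <- sum((obs - pasl_kinetic_signal(ti, cbf0, bat0, 900 / 0.9, p))^2)
    expect_lte(fit$value, rss0 + 1e-9)
  }
})

test_that("map estimation is voxel-independent (permutation commutes)", {
  p <- pasl_params(t1_blood = 1.88)
  ti <- make_ti_grid()
  set.seed(8)
  cases <- data.frame(cbf = c(40, 120, 600), bat = c(0.6, 1.1, 1.7))
  curves <- t(apply(cases, 1, function(cs) {
    pasl_kinetic_signal(ti, cs[1], cs[2], 900 / 0.9, p) +
      rnorm(length(ti), 0, 0.5)
  }))
  perm <- c(3, 1, 2)
  m_a <- fit_multiti(curve_series(curves), array(900, c(3, 1, 1)), p,
                     mask = array(TRUE, c(3, 1, 1)))
  m_b <- fit_multiti(curve_series(curves[perm, ]), array(900, c(3, 1, 1)), p,
                     mask = array(TRUE, c(3, 1, 1)))
  expect_equal(m_b$cbf[, 1, 1], m_a$cbf[perm, 1, 1], tolerance = 1e-10)
  expect_equal(m_b$bat[, 1, 1], m_a$bat[perm, 1, 1], tolerance = 1e-10)
})

test_that("voxels with too few above-noise points are left unfitted", {
  p <- pasl_params(t1_blood = 1.88)
  ti <- make_ti_grid()
  curves <- matrix(0, 2, length(ti))
  curves[2, 5:6] <- 10                # only two points above noise
  ser <- curve_series(curves)
  bg <- structure(list(mean = 0, sd = 1, n_voxels = 1000,
                       corner_boxes = list(), width = 5),
                  class = "background_stats")
  # voxel 1 is pure background yet inside the mask: containment warning
  expect_warning(
    maps <- fit_multiti(ser, array(900, c(2, 1, 1)), p,
                        mask = array(TRUE, c(2, 1, 1)), stats = bg),
    "reliable")
  expect_false(is.finite(maps$cbf[2, 1, 1]))   # < 3 above-noise points
  expect_false(maps$converged[2, 1, 1])
})

test_that("fit summaries expose provenance and tidy per-voxel rows", {
  p <- pasl_params(t1_blood = 1.88)
  ti <- make_ti_grid()
  curves <- rbind(pasl_kinetic_signal(ti, 60, 0.7, 1000, p))
  maps <- fit_multiti(curve_series(curves), array(900, c(1, 1, 1)), p,
                      mask = array(TRUE, c(1, 1, 1)))
  g <- glance(maps)
  expect_equal(g$n_fitted, 1)
  expect_equal(g$frac_converged, 1)
  td <- tidy(maps)
  expect_equal(nrow(td), 1)
  expect_true(all(c("cbf", "bat", "rss", "converged") %in% names(td)))
  expect_match(maps$provenance$optimizer, "L-BFGS-B")
})
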