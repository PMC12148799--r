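test_that("rendering is deterministic under a fixed seed", {
  cfg <- sim_config("thorax", seed = 9)
  v1 <- render_aed(cfg, n_slices = 2)
  v2 <- render_aed(cfg, n_slices = 2)
  expect_identical(v1$voxels, v2$voxels)
})

test_that("seeds change only the noise", {
  base <- render_aed(sim_config("thorax", noise_sd_hu = 0, seed = 1),
                     n_slices = 2)
  va <- render_aed(sim_config("thorax", noise_sd_hu = 12, seed = 1),
                   n_slices = 2)
  vb <- render_aed(sim_config("thorax", noise_sd_hu = 12, seed = 2),
                   n_slices = 2)
  expect_false(identical(va$voxels, vb$voxels))
  for (v in list(va, vb)) {
    resid <- v$voxels - base$voxels
    expect_equal(mean(resid), 0, tolerance = 0.1)
    expect_equal(sd(resid), 12, tolerance = 0.02 * 12)
  }
})

test_that("noiseless unblurred rod centers hit the HU model exactly", {
  cfg <- sim_config("head", noise_sd_hu = 0, psf_sigma_mm = 0, seed = 1)
  v <- render_aed(cfg, n_slices = 1)
  m <- red_hu_model("head")
  lay <- default_aed_layout()
  for (i in seq_len(nrow(lay$rods))) {
    s <- circular_roi_stats(v, 1, c(lay$rods$x_mm[i], lay$rods$y_mm[i]), 10)
    expect_equal(s$mean_hu, red_to_hu(m, lay$rods$red[i]))
    expect_equal(s$sd_hu, 0)
  }
})

test_that("a large uniform ROI recovers the generator noise sd", {
  cfg <- sim_config("thorax", noise_sd_hu = 10, psf_sigma_mm = 0, seed = 4)
  v <- render_catphan(cfg, sections = 1)
  idx <- section_slice_index(v, 1, default_catphan_layout())
  s <- circular_roi_stats(v, idx, c(0, 0), 30)
  expect_gt(s$n_voxels, 2000)
  expect_equal(s$sd_hu, 10, tolerance = 0.05)
})

test_that("the tilted-wire trace advances by slice_thickness / tan(23) per slice", {
  cfg <- sim_config("thorax", noise_sd_hu = 0, psf_sigma_mm = 0, seed = 1)
  v <- render_catphan(cfg, sections = 3)
  lay <- default_catphan_layout()
  idx <- section_slice_index(v, 3, lay)
  centroid_u <- function(k) {
    pr <- line_profile(v, k, c(-20, 38), c(20, 38), 0.1)
    w <- pmax(pr$values - 10, 0)
    sum(pr$positions_mm * w) / sum(w) - 20
  }
  step <- centroid_u(idx + 1) - centroid_u(idx)
  expect_equal(step, 2 / tanpi(23 / 180), tolerance = 0.02)
  expect_equal(step, 4.712, tolerance = 0.01)
})

test_that("the 1 lp/cm bar set renders as a square wave with 5 mm half-period", {
  cfg <- sim_config("thorax", noise_sd_hu = 0, psf_sigma_mm = 0, seed = 1)
  v <- render_catphan(cfg, sections = 4)
  lay <- default_catphan_layout()
  idx <- section_slice_index(v, 4, lay)
  lp1 <- lay$line_pairs[1, ]
  w <- (2 * lp1$n_bars - 1) * lp1$gap_mm
  pr <- line_profile(v, idx, c(lp1$center_x_mm - w / 2 - 3, 0),
                     c(lp1$center_x_mm + w / 2 + 3, 0), 0.1)
  pk <- pracma::findpeaks(pr$values, minpeakdistance = 60, zero = "+",
                          minpeakheight = 400)
  expect_equal(nrow(pk), 4L)
  # peak-to-peak spacing is one full period = 2 gaps = 10 mm (peak positions
  # on the flat bar tops are only defined to about a pixel)
  expect_lt(max(abs(diff(sort(pk[, 2])) * 0.1 - 10)), 1.1)
  # bar width at half maximum equals the 5 mm gap
  above <- pr$values > (max(pr$values) + 10) / 2
  runs <- rle(above)
  expect_equal(mean(runs$lengths[runs$values]) * 0.1, 5, tolerance = 0.1)
})

test_that("contrast rods sit at their nominal offsets over the background", {
  cfg <- sim_config("thorax", noise_sd_hu = 0, psf_sigma_mm = 0, seed = 1)
  v <- render_catphan(cfg, sections = 2)
  lay <- default_catphan_layout()
  idx <- section_slice_index(v, 2, lay)
  cr <- lay$contrast_rods
  for (i in 1:3) {
    s <- circular_roi_stats(v, idx, c(cr$x_mm[i], cr$y_mm[i]), 5)
    expect_equal(s$mean_hu, lay$uniformity_hu + cr$nominal_hu[i],
                 tolerance = 1e-9)
  }
})

test_that("rods placed outside the body are refused", {
  lay <- default_aed_layout()
  lay$rods$x_mm[1] <- 190  # rod rim would cross the 200 mm semi-axis
  expect_error(render_aed(sim_config("thorax"), layout = lay, n_slices = 1),
               "outside the phantom body")
})

test_that("phantom offset and roll move the rendered structures accordingly", {
  cfg <- sim_config("thorax", noise_sd_hu = 0, psf_sigma_mm = 0, seed = 1,
                    offset_mm = c(6, -4), roll_deg = 90)
  v <- render_aed(cfg, n_slices = 1)
  expect_equal(locate_phantom_center(v, 1), c(6, -4), tolerance = 0.5)
  lay <- default_aed_layout()
  m <- red_hu_model("thorax")
  i <- which(lay$rods$red == 0.28)
  # roll 90 deg maps (x, y) -> (-y, x)
  pos <- c(-lay$rods$y_mm[i] + 6, lay$rods$x_mm[i] - 4)
  s <- circular_roi_stats(v, 1, pos, 10)
  expect_equal(s$mean_hu, red_to_hu(m, 0.28))
})
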