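test_that("CNR follows its defining formula on a constructed section", {
  lay <- default_catphan_layout()
  # +10 HU rod over 0 background, checkerboard sd 5 -> CNR = 10 / 5 = 2
  v <- section2_volume(rod_hu = 10, texture_sd = 5)
  r <- cnr(v, lay, contrast_pct = 1)
  expect_equal(r$cnr, 2, tolerance = 0.02)
  expect_equal(r$rod_diameter_mm, 15)

  # zero contrast gives zero CNR; sign flips with the contrast
  v0 <- section2_volume(rod_hu = 0)
  expect_equal(cnr(v0, lay, 1)$cnr, 0, tolerance = 0.02)
  vn <- section2_volume(rod_hu = -10)
  expect_equal(cnr(vn, lay, 1)$cnr, -cnr(v, lay, 1)$cnr, tolerance = 0.02)

  # doubling both sds halves the CNR (up to the checkerboard imbalance)
  v2 <- section2_volume(rod_hu = 10, texture_sd = 10)
  expect_equal(cnr(v2, lay, 1)$cnr, r$cnr / 2, tolerance = 0.05)

  # noiseless input has an undefined CNR
  vz <- section2_volume(rod_hu = 10, texture_sd = 0)
  expect_error(cnr(vz, lay, 1), "undefined")
})

test_that("rendered CNR tracks the nominal contrast over noise ratio", {
  lay <- default_catphan_layout()
  v <- render_catphan(sim_config("thorax", seed = 3), sections = 2)
  r1 <- cnr(v, lay, 1)
  # +10 HU rod, noise sd 10: expect CNR near 1
  expect_equal(r1$cnr, 1, tolerance = 0.15)
  r05 <- cnr(v, lay, 0.5)
  expect_lt(r05$cnr, r1$cnr)
})

test_that("FWHM measurement matches closed forms", {
  x <- seq(0, 50, by = 0.05)
  rect <- as.numeric(x >= 20 & x <= 27.3)
  expect_equal(cbctqa:::fwhm_linear(x, rect), 7.3, tolerance = 0.06)
  gauss <- exp(-(x - 25)^2 / (2 * 1.7^2))
  expect_equal(cbctqa:::fwhm_linear(x, gauss), 2.3548 * 1.7, tolerance = 1e-3)
})

test_that("tilted-wire geometry turns trace length into slice thickness", {
  # ideal rectangular trace of length L implies thickness L * tan(23 deg)
  L <- 2 / tanpi(23 / 180)
  expect_equal(L * tanpi(23 / 180), 2)
  expect_equal(0.4245 * L, 2, tolerance = 1e-3)
})

test_that("slice thickness is recovered within 5% at default noise", {
  v <- fast_catphan("thorax", seed = 42, sections = 3)
  st <- slice_thickness(v)
  expect_equal(st$slice_thickness_mm, 2, tolerance = 0.05)
  expect_length(st$per_ramp_mm, 4L)
  # raw trace FWHM, unscaled, is thickness / tan(23 deg)
  raw <- slice_thickness(v, scale_by_tan = FALSE)
  expect_equal(raw$slice_thickness_mm,
               st$slice_thickness_mm / tanpi(23 / 180), tolerance = 1e-9)
})

test_that("circular symmetry recovers rendered square sides sub-pixel", {
  lay <- default_catphan_layout()
  for (off in list(c(0, 0), c(0.37, -0.21))) {
    v <- render_catphan(sim_config("thorax", noise_sd_hu = 0, seed = 1,
                                   offset_mm = off), lay, sections = 3)
    cs <- circular_symmetry(v, lay)
    expect_lt(abs(cs$symmetry_mean_mm - 50), 0.53)  # half the 1.05 mm pixel
    expect_equal(dim(cs$sides_mm), c(5L, 4L))
  }
  # a square manufactured at 49.4 mm reads back as 49.4
  lay2 <- lay
  lay2$hole_square$side_mm <- 49.4
  v2 <- render_catphan(sim_config("thorax", noise_sd_hu = 0, seed = 1),
                       lay2, sections = 3)
  expect_lt(abs(circular_symmetry(v2, lay2)$symmetry_mean_mm - 49.4), 0.53)
})

test_that("a displaced hole changes exactly the two adjacent sides", {
  lay <- default_catphan_layout()
  z3 <- lay$section_offsets_mm[["section3"]]
  # fine 0.25 mm grid so un-antialiased holes centroid cleanly
  v <- const_volume(-1000, n = 720, slices = 5, spacing = 0.25,
                    slice_spacing = 2)
  v$origin_mm[3] <- z3 - 5
  cc <- cbctqa:::voxel_centers_xy(v)
  cyl <- outer(cc$y^2, cc$x^2, "+") <= 88^2
  corners <- rbind(c(-25, 25), c(26, 25), c(25, -25), c(-25, -25))  # TR moved +1 in x
  for (k in 1:5) {
    sl <- v$voxels[k, , ]
    sl[cyl] <- 10
    for (i in 1:4) {
      m <- outer((cc$y - corners[i, 2])^2, (cc$x - corners[i, 1])^2, "+") < 1.5^2
      sl[m] <- -1000
    }
    v$voxels[k, , ] <- sl
  }
  cs <- circular_symmetry(v, lay)
  expected <- c(sqrt(51^2), sqrt(1 + 50^2), 50, 50)  # TL-TR, TR-BR, BR-BL, BL-TL
  expect_lt(max(abs(cs$sides_mm[1, ] - expected)), 0.13)  # half a 0.25 mm pixel
  expect_lt(abs(cs$symmetry_mean_mm - mean(expected)), 0.13)
})

test_that("sensitometry CT numbers echo configured nominals when unblurred", {
  lay <- default_catphan_layout()
  v <- render_catphan(sim_config("thorax", noise_sd_hu = 0, psf_sigma_mm = 0,
                                 seed = 1), lay, sections = 3)
  ct <- ct_numbers(v, lay)
  expect_equal(ct$mean_hu, ct$nominal_hu, tolerance = 1e-9)
  expect_true(all(ct$sd_hu == 0))
  expect_true(any(ct$material == "Air 1"))
  # ordering preserved under default blur and noise
  vb <- fast_catphan("thorax", seed = 6, sections = 3)
  ctb <- ct_numbers(vb, lay)
  sub <- ctb[ctb$material != "Air 2", ]  # drop the tied duplicate air target
  expect_equal(order(sub$mean_hu), order(sub$nominal_hu))
  expect_lt(abs(ctb$mean_hu[ctb$material == "Air 1"] + 1000), 15)
})
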