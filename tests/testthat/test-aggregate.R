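curve_from_hu <- function(hu, protocol = "thorax", site = "s") {
  structure(list(points = data.frame(red = red_hu_model(protocol)$anchors$red,
                                     mean_hu = hu, sd_hu = 0),
                 protocol = protocol, site = site),
            class = "calibration_curve")
}

make_reports <- function(n = 6, jitter = 0, seed = 1, protocol = "thorax") {
  anchors <- red_hu_model(protocol)$anchors
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    hu <- anchors$hu + if (jitter > 0) rnorm(nrow(anchors), 0, jitter) else 0
    site_report(paste0("site", i), protocol, curve_from_hu(hu, protocol))
  })
}

test_that("identical sites summarize with zero spread and no z-score", {
  s <- summarize_cohort(make_reports(6, jitter = 0))
  expect_true(all(s$per_red$sd_hu == 0))
  expect_true(all(is.na(s$per_red$max_abs_z)))
  expect_equal(s$per_red$median_hu, red_hu_model("thorax")$anchors$hu)
  expect_equal(s$slope_sd, 0)
  expect_equal(s$slope_mean, s$slope_pooled, tolerance = 1e-12)
})

test_that("median and sd agree with brute-force oracles and site order", {
  reps <- make_reports(6, jitter = 25, seed = 7)
  s <- summarize_cohort(reps)
  hu_mat <- sapply(reps, function(r) r$calibration$points$mean_hu)
  for (i in seq_len(nrow(hu_mat))) {
    xs <- sort(hu_mat[i, ])
    expect_equal(s$per_red$median_hu[i], (xs[3] + xs[4]) / 2)  # n = 6
    expect_equal(s$per_red$sd_hu[i],
                 sqrt(sum((hu_mat[i, ] - mean(hu_mat[i, ]))^2) / 5))
    expect_equal(s$per_red$max_abs_z[i], max_abs_zscore(hu_mat[i, ]))
  }
  # permutation invariance
  s2 <- summarize_cohort(rev(reps))
  expect_equal(s2$per_red, s$per_red)
  expect_equal(s2$slope_pooled, s$slope_pooled)
})

test_that("a printed-style site list yields the expected median", {
  hu <- c(-730, -721, -715, -719, -725, -708)
  expect_equal(median(hu), -720)
  reps <- lapply(seq_along(hu), function(i) {
    anchors <- red_hu_model("thorax")$anchors
    v <- anchors$hu
    v[anchors$red == 0.28] <- hu[i]
    site_report(paste0("s", i), "thorax", curve_from_hu(v))
  })
  s <- summarize_cohort(reps)
  expect_equal(s$per_red$median_hu[s$per_red$red == 0.28], -720)
})

test_that("mixed protocols and tiny cohorts are refused", {
  reps <- make_reports(3)
  reps[[2]]$protocol <- "head"
  expect_error(summarize_cohort(reps), "mix")
  expect_error(summarize_cohort(make_reports(2)), "length")
})

test_that("reports round-trip through JSON and mirror the table in CSV", {
  s <- summarize_cohort(make_reports(6, jitter = 10, seed = 3))
  fj <- withr::local_tempfile(fileext = ".json")
  export_report(s, fj, "json")
  back <- read_report_json(fj)
  expect_equal(back$per_red, s$per_red, tolerance = 1e-12)
  expect_equal(back$slope_pooled, s$slope_pooled, tolerance = 1e-12)
  # idempotent re-export
  fj2 <- withr::local_tempfile(fileext = ".json")
  export_report(back, fj2, "json")
  expect_identical(readLines(fj), readLines(fj2))

  fc <- withr::local_tempfile(fileext = ".csv")
  export_report(s, fc, "csv")
  expect_equal(nrow(read.csv(fc)), nrow(s$per_red))
  expect_error(export_report(s, fc, "xml"))
})

test_that("an end-to-end six-site synthetic cohort behaves like the study", {
  anchors <- red_hu_model("thorax")$anchors
  reports <- lapply(1:6, function(i) {
    m <- red_hu_model("thorax")
    set.seed(100 + i)
    m$anchors$hu <- anchors$hu + rnorm(nrow(anchors), 0, anchors$sd_hu)
    cfg <- sim_config("thorax", noise_sd_hu = 10, psf_sigma_mm = 0.55,
                      seed = 200 + i, site = paste0("site", i))
    v <- render_aed(cfg, model = m, n_slices = 5)
    site_report(paste0("site", i), "thorax", measure_rods(v))
  })
  s <- summarize_cohort(reports)
  # no outliers: the multi-site screen stays under 2, as in the study cohort
  expect_true(all(s$per_red$max_abs_z < 2))
  # medians track the generating anchors within the inter-site spread
  expect_true(all(abs(s$per_red$median_hu - anchors$hu) <
                    3 * pmax(anchors$sd_hu, 5)))
  # both slope conventions agree with the anchor-level fit within 10%
  truth <- fit_piecewise(list(points = data.frame(red = anchors$red,
                                                  mean_hu = anchors$hu)))
  expect_equal(s$slope_mean, truth$slope_high, tolerance = 0.1)
  expect_equal(s$slope_pooled, truth$slope_high, tolerance = 0.1)
})
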