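#' Measure rod HU and build a RED-vs-HU calibration curve
#'
#' Places a circular ROI at each rod position (after recovering the phantom
#' center from the image), averages it over five consecutive slices centered
#' at the axial midpoint, and reports one calibration point per distinct RED.
#' The six solid-water reference rods are pooled: their per-slice means are
#' averaged rod-wise first, so the RED 1.00 point is the mean over the six
#' rods, with the across-slice spread as its uncertainty.
#'
#' @param vol a [volume()] of the electron-density phantom.
#' @param layout an [default_aed_layout()] (or measured copy).
#' @param roi_radius_mm ROI radius (default 10 mm).
#' @param n_slices averaging window (default 5).
#' @return An object of class `calibration_curve`: data frame `points`
#'   (`red`, `mean_hu`, `sd_hu`) sorted by RED, plus `protocol` and `site`
#'   labels from the volume metadata.
#' @export
measure_rods <- function(vol, layout = default_aed_layout(),
                         roi_radius_mm = 10, n_slices = 5L) {
  d <- dim(vol$voxels)
  mid <- (d[1L] + 1L) %/% 2L
  ctr <- locate_phantom_center(vol, mid)
  rods <- layout$rods

  per_rod <- lapply(seq_len(nrow(rods)), function(i) {
    slab_mean(vol, mid, c(rods$x_mm[i] + ctr[1], rods$y_mm[i] + ctr[2]),
              roi_radius_mm, n_slices = n_slices)
  })

  sw <- rods$role == "solid_water_reference"
  # per-slice mean over the six reference rods, then across-slice stats
  sw_mat <- vapply(per_rod[sw], function(s) s$per_slice_means,
                   numeric(n_slices))
  sw_slice_means <- rowMeans(sw_mat)

  ins <- which(!sw)
  pts <- data.frame(
    red = c(rods$red[ins], 1.00),
    mean_hu = c(vapply(per_rod[ins], function(s) s$mean_hu, 0.0),
                mean(sw_slice_means)),
    sd_hu = c(vapply(per_rod[ins], function(s) s$sd_hu, 0.0),
              stats::sd(sw_slice_means))
  )
  pts <- pts[order(pts$red), ]
  rownames(pts) <- NULL
  if (anyDuplicated(pts$red)) stop("layout contains duplicate insert RED values")
  structure(list(points = pts,
                 protocol = vol$series_meta$protocol,
                 site = vol$series_meta$site),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s / %s, %d points\n",
              x$site %||% "?", x$protocol %||% "?", nrow(x$points)))
  print(x$points, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Piecewise linear calibration fit
#'
#' Fits RED as a linear function of HU separately for RED < 1 and RED >= 1
#' (the RED 1.00 reference belongs to the high branch) by ordinary least
#' squares. The regression direction matches the field's convention of
#' quoting slopes in RED/HU, typically displayed as 10^-6 RED/HU.
#'
#' @param curve a [measure_rods()] result, or any list with a `points` data
#'   frame holding `red` and `mean_hu`.
#' @return An object of class `piecewise_fit` with `slope_low`,
#'   `intercept_low`, `slope_high`, `intercept_high` (slopes in RED/HU).
#' @export
fit_piecewise <- function(curve) {
  pts <- curve$points
  lo <- pts[pts$red < 1, ]
  hi <- pts[pts$red >= 1, ]
  if (nrow(lo) < 2L || nrow(hi) < 2L) {
    stop("need at least two calibration points on each side of RED = 1")
  }
  flo <- stats::lm(red ~ mean_hu, data = lo)
  fhi <- stats::lm(red ~ mean_hu, data = hi)
  structure(list(
    slope_low = unname(stats::coef(flo)[2L]),
    intercept_low = unname(stats::coef(flo)[1L]),
    slope_high = unname(stats::coef(fhi)[2L]),
    intercept_high = unname(stats::coef(fhi)[1L]),
    n_low = nrow(lo), n_high = nrow(hi)
  ), class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf("<piecewise_fit> RED<1: %.1f e-6 RED/HU (icpt %.4f, n=%d)\n",
              x$slope_low * 1e6, x$intercept_low, x$n_low))
  cat(sprintf("               RED>=1: %.1f e-6 RED/HU (icpt %.4f, n=%d)\n",
              x$slope_high * 1e6, x$intercept_high, x$n_high))
  invisible(x)
}

#' Maximum absolute z-score of a set of site values
#'
#' Screens per-site measurements for outliers: the largest
#' `|x_i - mean| / sd` using the sample (n-1) standard deviation, suited to
#' the small cohorts (about six sites) this screen is meant for.
#'
#' @param values numeric vector, length >= 3, with nonzero spread.
#' @return The maximum absolute z-score.
#' @export
max_abs_zscore <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("need at least 3 values for a z-score screen")
  s <- stats::sd(values)
  if (s == 0) stop("zero spread: z-scores undefined")
  max(abs(values - mean(values)) / s)
}
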