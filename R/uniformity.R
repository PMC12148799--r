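# Section-1 uniformity metrics. All three follow the same slice convention:
# computed per slice over the five-slice window centered on the section, with
# the across-slice standard deviation as the uncertainty.

uniformity_rois <- function(vol, layout, slice_index) {
  ctr <- locate_phantom_center(vol, slice_index)
  r_pos <- layout$diameter_mm / 2 - layout$border_roi_edge_mm
  list(
    center = ctr,
    borders = list(top = ctr + c(0, r_pos), bottom = ctr - c(0, r_pos),
                   left = ctr - c(r_pos, 0), right = ctr + c(r_pos, 0)),
    radius = layout$roi_radius_mm
  )
}

uniformity_per_slice <- function(vol, layout, n_slices = 5L) {
  idx0 <- section_slice_index(vol, 1L, layout)
  half <- (n_slices - 1L) %/% 2L
  idx <- (idx0 - half):(idx0 - half + n_slices - 1L)
  rois <- uniformity_rois(vol, layout, idx0)
  t(vapply(idx, function(i) {
    ctr_mean <- circular_roi_stats(vol, i, rois$center, rois$radius)$mean_hu
    border_means <- vapply(rois$borders, function(p)
      circular_roi_stats(vol, i, p, rois$radius)$mean_hu, 0.0)
    c(center = ctr_mean, borders = mean(border_means))
  }, c(center = 0, borders = 0)))
}

#' Radial uniformity (RU)
#'
#' Mean HU of four border ROIs (top, bottom, left, right, each 10 mm radius,
#' centered 20 mm in from the phantom edge) minus the central ROI mean,
#' computed per slice and averaged over the five-slice window; the
#' uncertainty is the standard deviation of the five per-slice values.
#'
#' @param vol a [volume()] of the image-quality phantom.
#' @param layout a [default_catphan_layout()].
#' @param n_slices averaging window (default 5).
#' @return list with `ru_hu` and `ru_sd`.
#' @export
radial_uniformity <- function(vol, layout = default_catphan_layout(),
                              n_slices = 5L) {
  m <- uniformity_per_slice(vol, layout, n_slices)
  ru <- m[, "borders"] - m[, "center"]
  list(ru_hu = mean(ru), ru_sd = stats::sd(ru))
}

#' Uniformity index (UI)
#'
#' Radial uniformity expressed as a percentage of the central ROI mean.
#' With a background near 10 HU the denominator is small, so UI is
#' numerically volatile by construction; it errors on an exactly zero
#' center mean.
#'
#' @inheritParams radial_uniformity
#' @return list with `ui_percent` and `ui_sd`.
#' @export
uniformity_index <- function(vol, layout = default_catphan_layout(),
                             n_slices = 5L) {
  m <- uniformity_per_slice(vol, layout, n_slices)
  if (any(m[, "center"] == 0)) {
    stop("central ROI mean is 0 HU: uniformity index undefined")
  }
  ui <- 100 * (m[, "borders"] - m[, "center"]) / m[, "center"]
  list(ui_percent = mean(ui), ui_sd = stats::sd(ui))
}

#' Integral nonuniformity (InU)
#'
#' `(Max - Min) / (Max + Min)` over centered vertical and horizontal line
#' profiles through section 1. Profiles span the central 80% of the phantom
#' diameter and are smoothed with a 5-sample moving average before taking
#' the extrema; the per-slice uncertainty is first-order error propagation
#' `2 sqrt(Min^2 sd_Max^2 + Max^2 sd_Min^2) / (Max + Min)^2` with the local
#' standard deviation in each extremum's smoothing window. Reported values
#' are the five-slice mean with the across-slice sd; the mean propagated
#' per-slice uncertainty is returned alongside.
#'
#' @inheritParams radial_uniformity
#' @return list with `inu_vertical`, `inu_vertical_sd`, `inu_horizontal`,
#'   `inu_horizontal_sd`, and mean propagated uncertainties
#'   `inu_vertical_prop`, `inu_horizontal_prop`.
#' @export
integral_nonuniformity <- function(vol, layout = default_catphan_layout(),
                                   n_slices = 5L) {
  idx0 <- section_slice_index(vol, 1L, layout)
  half_w <- (n_slices - 1L) %/% 2L
  idx <- (idx0 - half_w):(idx0 - half_w + n_slices - 1L)
  ctr <- locate_phantom_center(vol, idx0)
  half_len <- 0.8 * layout$diameter_mm / 2
  step <- min(vol$pixel_spacing_mm)

  one <- function(i, vertical) {
    pr <- if (vertical) {
      line_profile(vol, i, c(ctr[1], ctr[2] - half_len),
                   c(ctr[1], ctr[2] + half_len), step)
    } else {
      line_profile(vol, i, c(ctr[1] - half_len, ctr[2]),
                   c(ctr[1] + half_len, ctr[2]), step)
    }
    v <- pr$values
    sm <- stats::filter(v, rep(1 / 5, 5), sides = 2)
    keep <- !is.na(sm)
    sm <- as.numeric(sm[keep])
    raw_idx <- which(keep)
    i_max <- which.max(sm); i_min <- which.min(sm)
    mx <- sm[i_max]; mn <- sm[i_min]
    if (mx + mn == 0) stop("Max + Min = 0: integral nonuniformity undefined")
    win_sd <- function(j) {
      w <- raw_idx[j] + (-2:2)
      stats::sd(v[w[w >= 1 & w <= length(v)]])
    }
    s_mx <- win_sd(i_max); s_mn <- win_sd(i_min)
    c(inu = (mx - mn) / (mx + mn),
      prop = 2 * sqrt(mn^2 * s_mx^2 + mx^2 * s_mn^2) / (mx + mn)^2)
  }

  vert <- t(vapply(idx, one, c(inu = 0, prop = 0), vertical = TRUE))
  horz <- t(vapply(idx, one, c(inu = 0, prop = 0), vertical = FALSE))
  list(
    inu_vertical = mean(vert[, "inu"]),
    inu_vertical_sd = stats::sd(vert[, "inu"]),
    inu_vertical_prop = mean(vert[, "prop"]),
    inu_horizontal = mean(horz[, "inu"]),
    inu_horizontal_sd = stats::sd(horz[, "inu"]),
    inu_horizontal_prop = mean(horz[, "prop"])
  )
}
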