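#' Contrast-to-noise ratio of a low-contrast rod
#'
#' `CNR = (S_ROI - S_BKG) / ((sigma_ROI + sigma_BKG) / 2)` for the 15 mm
#' contrast rod in section 2. Background is taken from two ROIs of the same
#' size 20 mm inward and outward of the rod center along the radial
#' direction: their means are averaged and the background sd is the
#' population sd of the pooled voxels of both ROIs. Computed per slice,
#' reported as the five-slice mean with across-slice sd.
#'
#' The default ROI radius of 5 mm keeps the ROI strictly inside the 7.5 mm
#' rod so the measured signal is the rod's plateau contrast; an ROI larger
#' than the rod would fold the rim transition into both the signal and the
#' noise term and dilute the contrast by the area ratio.
#'
#' @param vol a [volume()] of the image-quality phantom.
#' @param layout a [default_catphan_layout()].
#' @param contrast_pct which nominal contrast rod to score (default 1).
#' @param roi_radius_mm radius of the rod and background ROIs (default 5).
#' @param n_slices averaging window (default 5).
#' @return list of class `cnr_result`: `cnr`, `cnr_sd`, `contrast_nominal`,
#'   `rod_diameter_mm`.
#' @export
cnr <- function(vol, layout = default_catphan_layout(), contrast_pct = 1,
                roi_radius_mm = 5, n_slices = 5L) {
  cr <- layout$contrast_rods
  i <- match(contrast_pct, cr$contrast_pct)
  if (is.na(i)) stop("no contrast rod at ", contrast_pct, "%")
  idx0 <- section_slice_index(vol, 2L, layout)
  half <- (n_slices - 1L) %/% 2L
  idx <- (idx0 - half):(idx0 - half + n_slices - 1L)
  ctr <- locate_phantom_center(vol, idx0)
  rod <- c(cr$x_mm[i] + ctr[1], cr$y_mm[i] + ctr[2])
  u <- (rod - ctr) / sqrt(sum((rod - ctr)^2))  # radial unit vector
  bg1 <- rod + 20 * u
  bg2 <- rod - 20 * u
  r <- roi_radius_mm

  per <- vapply(idx, function(k) {
    roi <- circular_roi_stats(vol, k, rod, r)
    b1 <- circular_roi_stats(vol, k, bg1, r)
    b2 <- circular_roi_stats(vol, k, bg2, r)
    s_bkg <- (b1$mean_hu + b2$mean_hu) / 2
    # population sd of the pooled voxels of the two background discs
    n1 <- b1$n_voxels; n2 <- b2$n_voxels
    pooled_mean <- (n1 * b1$mean_hu + n2 * b2$mean_hu) / (n1 + n2)
    ss <- n1 * (b1$sd_hu^2 + (b1$mean_hu - pooled_mean)^2) +
          n2 * (b2$sd_hu^2 + (b2$mean_hu - pooled_mean)^2)
    sd_bkg <- sqrt(ss / (n1 + n2))
    denom <- (roi$sd_hu + sd_bkg) / 2
    if (denom == 0) stop("zero noise in both ROIs: CNR undefined (noiseless input?)")
    (roi$mean_hu - s_bkg) / denom
  }, 0.0)

  structure(list(cnr = mean(per), cnr_sd = stats::sd(per),
                 contrast_nominal = cr$contrast_pct[i],
                 rod_diameter_mm = cr$diameter_mm[i]),
            class = "cnr_result")
}

fwhm_linear <- function(positions, values) {
  half <- max(values) / 2
  above <- which(values > half)
  if (!length(above)) stop("profile never exceeds half maximum")
  i1 <- above[1L]; i2 <- above[length(above)]
  left <- if (i1 == 1L) positions[1L] else {
    stats::approx(values[c(i1 - 1L, i1)], positions[c(i1 - 1L, i1)], xout = half)$y
  }
  right <- if (i2 == length(values)) positions[i2] else {
    stats::approx(values[c(i2, i2 + 1L)], positions[c(i2, i2 + 1L)], xout = half)$y
  }
  right - left
}

#' Slice thickness from the tilted-wire ramps
#'
#' For each of the four 23-degree tilted wires in section 3, extracts the
#' in-plane profile across the wire trace, subtracts the background, and
#' measures the full width at half maximum by linear interpolation between
#' the samples bracketing half maximum. Because a wire inclined 23 degrees
#' to the axial plane crosses a slab of thickness `t` over an in-plane run
#' of `t / tan(23)`, the trace FWHM times `tan(23 deg)` recovers the slice
#' thickness. Each ramp's FWHM is averaged over the five-slice section
#' window (the trace advances by a non-integer number of pixels per slice,
#' so the window samples different edge-to-grid phases and averages out the
#' half-pixel discretization of any single slice); the reported value is
#' the mean of the four per-ramp results with their standard deviation.
#'
#' @inheritParams cnr
#' @param scale_by_tan multiply the trace FWHM by `tan(ramp angle)`
#'   (default TRUE); FALSE returns the raw trace FWHM.
#' @return list with `slice_thickness_mm`, `slice_thickness_sd`, and the
#'   per-ramp values `per_ramp_mm`.
#' @export
slice_thickness <- function(vol, layout = default_catphan_layout(),
                            n_slices = 5L, scale_by_tan = TRUE) {
  idx0 <- section_slice_index(vol, 3L, layout)
  half_w <- (n_slices - 1L) %/% 2L
  idx <- (idx0 - half_w):(idx0 - half_w + n_slices - 1L)
  z3 <- layout$section_offsets_mm[["section3"]]
  tan_r <- tanpi(layout$ramp_angle_deg / 180)
  ctr <- locate_phantom_center(vol, idx0)
  ramps <- layout$wire_ramps
  win <- 15                          # half-window along the travel axis, mm

  per <- vapply(seq_len(nrow(ramps)), function(i) {
    x0 <- ramps$x_mm[i] + ctr[1]; y0 <- ramps$y_mm[i] + ctr[2]
    fw <- vapply(idx, function(k) {
      u_ctr <- (slice_z(vol)[k] - z3) / tan_r  # trace center at this slice
      pr <- if (ramps$axis[i] == "x") {
        line_profile(vol, k, c(x0 + u_ctr - win, y0), c(x0 + u_ctr + win, y0), 0.2)
      } else {
        line_profile(vol, k, c(x0, y0 + u_ctr - win), c(x0, y0 + u_ctr + win), 0.2)
      }
      v <- pr$values - stats::median(pr$values)
      if (max(v) < 8 * stats::mad(pr$values)) {
        stop("ramp '", ramps$name[i], "' not detectable above background")
      }
      fwhm_linear(pr$positions_mm, v)
    }, 0.0)
    mean(fw)
  }, 0.0)

  if (scale_by_tan) per <- per * tan_r
  list(slice_thickness_mm = mean(per),
       slice_thickness_sd = stats::sd(per),
       per_ramp_mm = per)
}

#' Circular symmetry from the 50 mm hole square
#'
#' Locates the four 3 mm air holes at the corners of the 50 mm square in
#' section 3 by intensity-weighted centroid (weight = background minus HU,
#' clipped at zero) within a 5 mm search disc around each nominal corner,
#' then averages the four side lengths. Computed per slice over the
#' five-slice window; the uncertainty is the across-slice sd of the
#' per-slice averages.
#'
#' @inheritParams cnr
#' @return list with `symmetry_mean_mm`, `symmetry_sd_mm`, and per-slice
#'   side-length matrix `sides_mm`.
#' @export
circular_symmetry <- function(vol, layout = default_catphan_layout(),
                              n_slices = 5L) {
  idx0 <- section_slice_index(vol, 3L, layout)
  half_w <- (n_slices - 1L) %/% 2L
  idx <- (idx0 - half_w):(idx0 - half_w + n_slices - 1L)
  ctr <- locate_phantom_center(vol, idx0)
  half <- layout$hole_square$side_mm / 2
  corners <- cbind(x = c(-half, half, half, -half) + ctr[1],
                   y = c(half, half, -half, -half) + ctr[2])
  search_r <- 5
  cc <- voxel_centers_xy(vol)

  centroid <- function(slice, cx, cy) {
    cols <- which(abs(cc$x - cx) <= search_r)
    rows <- which(abs(cc$y - cy) <= search_r)
    sub <- slice[rows, cols]
    w <- pmax(layout$uniformity_hu - sub, 0)
    w[outer((cc$y[rows] - cy)^2, (cc$x[cols] - cx)^2, "+") > search_r^2] <- 0
    if (sum(w) <= 0) stop(sprintf("no hole found within %g mm of (%.1f, %.1f)",
                                  search_r, cx, cy))
    c(sum(t(w) * cc$x[cols]) / sum(w), sum(w * cc$y[rows]) / sum(w))
  }

  sides <- t(vapply(idx, function(k) {
    slice <- vol$voxels[k, , ]
    pts <- t(vapply(1:4, function(i) centroid(slice, corners[i, 1], corners[i, 2]),
                    numeric(2)))
    vapply(1:4, function(i) {
      j <- if (i == 4L) 1L else i + 1L
      sqrt(sum((pts[i, ] - pts[j, ])^2))
    }, 0.0)
  }, numeric(4)))

  per_slice <- rowMeans(sides)
  list(symmetry_mean_mm = mean(per_slice),
       symmetry_sd_mm = stats::sd(per_slice),
       sides_mm = sides)
}

#' Sensitometry CT numbers
#'
#' Mean HU in a 5 mm radius ROI at each sensitometry target of section 3,
#' averaged over the five-slice window with the across-slice sd as the
#' uncertainty.
#'
#' @inheritParams cnr
#' @param roi_radius_mm ROI radius (default 5 mm).
#' @return data frame with `material`, `nominal_hu`, `mean_hu`, `sd_hu`.
#' @export
ct_numbers <- function(vol, layout = default_catphan_layout(),
                       roi_radius_mm = 5, n_slices = 5L) {
  idx0 <- section_slice_index(vol, 3L, layout)
  ctr <- locate_phantom_center(vol, idx0)
  sens <- layout$sensitometry
  res <- lapply(seq_len(nrow(sens)), function(i) {
    s <- slab_mean(vol, idx0, c(sens$x_mm[i] + ctr[1], sens$y_mm[i] + ctr[2]),
                   roi_radius_mm, n_slices = n_slices)
    c(mean_hu = s$mean_hu, sd_hu = s$sd_hu)
  })
  out <- data.frame(material = sens$material, nominal_hu = sens$nominal_hu,
                    mean_hu = vapply(res, `[[`, 0.0, "mean_hu"),
                    sd_hu = vapply(res, `[[`, 0.0, "sd_hu"))
  rownames(out) <- NULL
  out
}
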