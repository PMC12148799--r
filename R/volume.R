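#' CT volume in physical coordinates
#'
#' A `cbct_volume` holds a 3-D Hounsfield-unit voxel grid together with its
#' physical geometry. Voxels are indexed `[slice, row, column]`; voxel centers
#' sit at `(index - 0.5) * spacing` from the grid corner `origin_mm`, so all
#' ROI and profile geometry is expressed in continuous millimetres.
#'
#' @param voxels 3-D numeric array of HU, dimensions (slice, row, column).
#'   A matrix is accepted and treated as a single slice.
#' @param pixel_spacing_mm length-2 positive numeric, (row, column) spacing.
#' @param slice_spacing_mm positive scalar, axial spacing between slices.
#' @param origin_mm length-3 numeric, physical (x, y, z) of the grid corner of
#'   voxel (1, 1, 1). Defaults to centering the grid on (0, 0, 0).
#' @param series_meta named list of acquisition metadata (protocol, kvp, mas,
#'   site); free-form.
#'
#' @return An object of class `cbct_volume`.
#' @export
volume <- function(voxels, pixel_spacing_mm, slice_spacing_mm,
                   origin_mm = NULL, series_meta = list()) {
  if (is.matrix(voxels)) {
    voxels <- array(voxels, dim = c(1L, nrow(voxels), ncol(voxels)))
  }
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
  if (length(pixel_spacing_mm) == 1L) pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  if (any(pixel_spacing_mm <= 0) || slice_spacing_mm <= 0) {
    stop("all voxel spacings must be strictly positive")
  }
  d <- dim(voxels)
  if (d[1L] < 1L) stop("volume must contain at least one slice")
  if (is.null(origin_mm)) {
    origin_mm <- c(-d[3L] * pixel_spacing_mm[2L] / 2,
                   -d[2L] * pixel_spacing_mm[1L] / 2,
                   -d[1L] * slice_spacing_mm / 2)
  }
  structure(list(
    voxels = voxels,
    pixel_spacing_mm = pixel_spacing_mm,
    slice_spacing_mm = as.numeric(slice_spacing_mm),
    origin_mm = as.numeric(origin_mm),
    series_meta = series_meta
  ), class = "cbct_volume")
}

#' @export
print.cbct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<cbct_volume> %d slices of %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  pixel spacing %.4f x %.4f mm, slice spacing %.3f mm\n",
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2], x$slice_spacing_mm))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$voxels), max(x$voxels)))
  if (length(x$series_meta)) {
    cat("  meta:", paste(names(x$series_meta),
                         vapply(x$series_meta, function(v) paste(v, collapse = ","), ""),
                         sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Physical coordinates of voxel centers
#'
#' @param vol a [volume()].
#' @return `voxel_centers_xy` gives a list with vectors `x` (per column) and
#'   `y` (per row); `slice_z` gives the axial center of each slice.
#' @keywords internal
voxel_centers_xy <- function(vol) {
  d <- dim(vol$voxels)
  list(
    x = vol$origin_mm[1] + (seq_len(d[3]) - 0.5) * vol$pixel_spacing_mm[2],
    y = vol$origin_mm[2] + (seq_len(d[2]) - 0.5) * vol$pixel_spacing_mm[1]
  )
}

#' @rdname voxel_centers_xy
#' @keywords internal
slice_z <- function(vol) {
  vol$origin_mm[3] + (seq_len(dim(vol$voxels)[1]) - 0.5) * vol$slice_spacing_mm
}

disc_mask <- function(vol, center_mm, radius_mm) {
  cc <- voxel_centers_xy(vol)
  dx2 <- outer((cc$y - center_mm[2])^2, (cc$x - center_mm[1])^2, "+")
  dx2 < radius_mm^2
}

#' Circular ROI statistics on one slice
#'
#' Mean and population standard deviation of the voxels whose centers lie
#' strictly inside a disc. Membership is voxel-center-in-disc with no
#' partial-volume weighting; at the standard 10 mm ROI radius on ~1 mm pixels
#' the discretization error on the mean is negligible.
#'
#' @param vol a [volume()].
#' @param slice_index 1-based slice index.
#' @param center_mm length-2 (x, y) disc center in mm.
#' @param radius_mm disc radius in mm.
#' @return A list of class `roi_stats`: `mean_hu`, `sd_hu` (population sd),
#'   `n_voxels`, `center_mm`, `radius_mm`.
#' @export
circular_roi_stats <- function(vol, slice_index, center_mm, radius_mm) {
  stopifnot(inherits(vol, "cbct_volume"), radius_mm > 0)
  d <- dim(vol$voxels)
  if (slice_index < 1L || slice_index > d[1L]) stop("slice_index out of range")
  cc <- voxel_centers_xy(vol)
  xr <- range(cc$x); yr <- range(cc$y)
  hx <- vol$pixel_spacing_mm[2] / 2; hy <- vol$pixel_spacing_mm[1] / 2
  if (center_mm[1] - radius_mm < xr[1] - hx || center_mm[1] + radius_mm > xr[2] + hx ||
      center_mm[2] - radius_mm < yr[1] - hy || center_mm[2] + radius_mm > yr[2] + hy) {
    stop(sprintf("ROI disc at (%.1f, %.1f) mm with radius %.1f mm extends beyond the slice",
                 center_mm[1], center_mm[2], radius_mm))
  }
  m <- disc_mask(vol, center_mm, radius_mm)
  v <- vol$voxels[slice_index, , ][m]
  if (!length(v)) stop("ROI contains no voxel centers")
  n <- length(v)
  structure(list(
    mean_hu = mean(v),
    sd_hu = sqrt(sum((v - mean(v))^2) / n),
    n_voxels = n,
    center_mm = as.numeric(center_mm),
    radius_mm = radius_mm
  ), class = "roi_stats")
}

#' Slab-averaged ROI statistics
#'
#' Applies a circular ROI to `n_slices` consecutive slices centered on
#' `center_slice`. The reported mean is the mean of the per-slice ROI means;
#' the reported sd is the sample standard deviation of those per-slice means,
#' which estimates across-slice repeatability rather than within-ROI noise.
#'
#' @inheritParams circular_roi_stats
#' @param center_slice central slice of the window.
#' @param n_slices window length (default 5).
#' @return `roi_stats` with `per_slice_means` attached.
#' @export
slab_mean <- function(vol, center_slice, center_mm, radius_mm, n_slices = 5L) {
  d <- dim(vol$voxels)
  half <- (n_slices - 1L) %/% 2L
  idx <- (center_slice - half):(center_slice - half + n_slices - 1L)
  if (idx[1L] < 1L || idx[length(idx)] > d[1L]) {
    stop(sprintf("%d-slice window at slice %d falls outside the volume (1..%d)",
                 n_slices, center_slice, d[1L]))
  }
  per <- vapply(idx, function(i)
    circular_roi_stats(vol, i, center_mm, radius_mm)$mean_hu, 0.0)
  structure(list(
    mean_hu = mean(per),
    sd_hu = if (length(per) > 1L) stats::sd(per) else 0,
    n_voxels = circular_roi_stats(vol, idx[1L], center_mm, radius_mm)$n_voxels,
    center_mm = as.numeric(center_mm),
    radius_mm = radius_mm,
    per_slice_means = per,
    slices = idx
  ), class = "roi_stats")
}

#' Line profile through a slice
#'
#' Samples the slice by bilinear interpolation at equally spaced positions
#' along the segment from `start_mm` to `end_mm`, endpoints inclusive.
#'
#' @inheritParams circular_roi_stats
#' @param start_mm,end_mm (x, y) segment endpoints in mm.
#' @param sampling_mm requested sample spacing; the actual spacing divides the
#'   segment length exactly so positions are strictly uniform.
#' @return A list of class `profile`: `positions_mm` (distance from start),
#'   `values`, `sampling_mm`.
#' @export
line_profile <- function(vol, slice_index, start_mm, end_mm, sampling_mm) {
  stopifnot(inherits(vol, "cbct_volume"), sampling_mm > 0)
  len <- sqrt(sum((end_mm - start_mm)^2))
  if (len == 0) stop("zero-length profile segment")
  n <- max(2L, floor(len / sampling_mm + 1e-9) + 1L)
  t <- seq(0, 1, length.out = n)
  xs <- start_mm[1] + t * (end_mm[1] - start_mm[1])
  ys <- start_mm[2] + t * (end_mm[2] - start_mm[2])
  vals <- bilinear_sample(vol, slice_index, xs, ys)
  structure(list(
    positions_mm = t * len,
    values = vals,
    sampling_mm = len / (n - 1L)
  ), class = "profile")
}

# Bilinear interpolation at physical (x, y); errors if any point falls outside
# the hull of voxel centers.
bilinear_sample <- function(vol, slice_index, xs, ys) {
  d <- dim(vol$voxels)
  if (slice_index < 1L || slice_index > d[1L]) stop("slice_index out of range")
  sl <- vol$voxels[slice_index, , ]
  dx <- vol$pixel_spacing_mm[2]; dy <- vol$pixel_spacing_mm[1]
  # fractional column/row index of each point (1-based, at voxel centers)
  fc <- (xs - vol$origin_mm[1]) / dx + 0.5
  fr <- (ys - vol$origin_mm[2]) / dy + 0.5
  if (any(fc < 1 - 1e-9 | fc > d[3] + 1e-9 | fr < 1 - 1e-9 | fr > d[2] + 1e-9)) {
    stop("profile endpoint outside the voxel grid")
  }
  fc <- pmin(pmax(fc, 1), d[3]); fr <- pmin(pmax(fr, 1), d[2])
  c0 <- pmin(floor(fc), d[3] - 1L); r0 <- pmin(floor(fr), d[2] - 1L)
  wc <- fc - c0; wr <- fr - r0
  v00 <- sl[cbind(r0, c0)];     v01 <- sl[cbind(r0, c0 + 1)]
  v10 <- sl[cbind(r0 + 1, c0)]; v11 <- sl[cbind(r0 + 1, c0 + 1)]
  (1 - wr) * ((1 - wc) * v00 + wc * v01) + wr * ((1 - wc) * v10 + wc * v11)
}
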