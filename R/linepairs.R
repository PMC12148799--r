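#' Highest resolved line-pair frequency
#'
#' Scores the section-4 bar patterns: for each set, in increasing line-pair
#' frequency, extracts the profile across the bars on the single best slice
#' of the section window (the one with the largest profile range), detects
#' peaks and valleys with [pracma::findpeaks()], and declares the set
#' resolved when the expected number of bar peaks is found and the mean
#' peak-to-valley difference exceeds 30% of the profile maximum over
#' baseline. Scanning stops at the first unresolved set; the result is the
#' highest resolved frequency (0 if none).
#'
#' Extrema must clear a prominence floor of 10% of the profile range, which
#' replaces per-image visual inspection with a user-independent rule.
#'
#' @param vol a [volume()] of the image-quality phantom.
#' @param layout a [default_catphan_layout()].
#' @param n_slices window searched for the best slice (default 5).
#' @return list with `max_lp_per_cm` (integer, 0-5) and a per-set logical
#'   vector `resolved`.
#' @export
max_line_pairs <- function(vol, layout = default_catphan_layout(),
                           n_slices = 5L) {
  idx0 <- section_slice_index(vol, 4L, layout)
  half <- (n_slices - 1L) %/% 2L
  idx <- (idx0 - half):(idx0 - half + n_slices - 1L)
  idx <- idx[idx >= 1L & idx <= dim(vol$voxels)[1L]]
  ctr <- locate_phantom_center(vol, idx0)
  lp <- layout$line_pairs
  sampling <- 0.1

  resolved <- logical(nrow(lp))
  for (i in seq_len(nrow(lp))) {
    gap <- lp$gap_mm[i]; nb <- lp$n_bars[i]
    width <- (2 * nb - 1) * gap
    x0 <- lp$center_x_mm[i] + ctr[1] - width / 2 - 3
    x1 <- lp$center_x_mm[i] + ctr[1] + width / 2 + 3
    y <- lp$center_y_mm[i] + ctr[2]

    profiles <- lapply(idx, function(k)
      line_profile(vol, k, c(x0, y), c(x1, y), sampling))
    best <- which.max(vapply(profiles, function(p) diff(range(p$values)), 0.0))
    v <- profiles[[best]]$values

    baseline <- stats::median(c(utils::head(v, 25), utils::tail(v, 25)))
    rng <- max(v) - min(v)
    if (rng <= 0) break
    min_dist <- max(3L, round(0.6 * 2 * gap / sampling))
    floor_hu <- 0.1 * rng  # prominence floor
    # zero = "+" lets flat-topped (unblurred) bars count as single extrema
    pk <- pracma::findpeaks(v, minpeakdistance = min_dist, zero = "+",
                            minpeakheight = baseline + floor_hu)
    vl <- pracma::findpeaks(-v, minpeakdistance = min_dist, zero = "+")
    ok <- FALSE
    if (!is.null(pk) && nrow(pk) == nb && !is.null(vl)) {
      span <- range(pk[, 2])
      inner <- vl[vl[, 2] > span[1] & vl[, 2] < span[2], , drop = FALSE]
      if (nrow(inner) == nb - 1L) {
        pv <- mean(pk[, 1]) - mean(-inner[, 1])
        ok <- pv > 0.3 * (max(v) - baseline)
      }
    }
    resolved[i] <- ok
    if (!ok) break
  }
  last <- if (any(resolved)) max(which(resolved)) else 0L
  list(max_lp_per_cm = if (last == 0L) 0L else as.integer(lp$lp_per_cm[last]),
       resolved = resolved)
}
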