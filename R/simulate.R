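# Voxelized phantom rendering: protocol-dependent HU via the anchor model,
# Gaussian point-spread blur, i.i.d. Gaussian noise. Rendering is a pure
# function of (config, layout); the seed fixes the noise exactly.

#' Simulation configuration
#'
#' Bundles the acquisition protocol with the generator's tuning knobs.
#'
#' @param protocol protocol name or list from [cbct_protocol()].
#' @param noise_sd_hu i.i.d. Gaussian noise sd in HU added after blur;
#'   `NULL` takes the protocol default.
#' @param psf_sigma_mm isotropic Gaussian blur sigma in mm (0 disables).
#'   The default 0.55 mm puts the wire-derived MTF f50 near 0.35 / mm.
#' @param seed integer seed fixing the noise realization.
#' @param offset_mm in-plane (x, y) displacement of the phantom.
#' @param roll_deg rotation of the phantom structure positions about the
#'   axial axis (positions only; bar-pattern orientation stays axis-aligned).
#' @param site free-text site label carried into `series_meta`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(protocol = "thorax", noise_sd_hu = NULL,
                       psf_sigma_mm = 0.55, seed = 1L,
                       offset_mm = c(0, 0), roll_deg = 0,
                       site = "synthetic") {
  if (is.character(protocol)) protocol <- cbct_protocol(protocol)
  if (is.null(noise_sd_hu)) noise_sd_hu <- protocol$noise_sd_hu
  stopifnot(noise_sd_hu >= 0, psf_sigma_mm >= 0)
  structure(list(protocol = protocol, noise_sd_hu = noise_sd_hu,
                 psf_sigma_mm = psf_sigma_mm, seed = as.integer(seed),
                 offset_mm = offset_mm, roll_deg = roll_deg, site = site),
            class = "sim_config")
}

with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# pixel-center coordinate vectors for a protocol grid, phantom-centered
grid_coords <- function(protocol) {
  n <- protocol$matrix
  dx <- protocol$fov_mm / n
  x <- (seq_len(n) - 0.5) * dx - protocol$fov_mm / 2
  list(x = x, y = x, dx = dx)
}

rotate_offset <- function(x, y, config) {
  th <- config$roll_deg * pi / 180
  cbind(x * cos(th) - y * sin(th) + config$offset_mm[1],
        x * sin(th) + y * cos(th) + config$offset_mm[2])
}

# Anti-aliased disc: mixes `hu` into `slice` with per-pixel coverage
# computed on an ss x ss subgrid (additive = TRUE adds hu * coverage).
add_disc <- function(slice, g, center, radius, hu, additive = FALSE, ss = 5L) {
  cols <- which(abs(g$x - center[1]) < radius + g$dx)
  rows <- which(abs(g$y - center[2]) < radius + g$dx)
  if (!length(cols) || !length(rows)) return(slice)
  off <- ((seq_len(ss) - 0.5) / ss - 0.5) * g$dx
  cov <- matrix(0, length(rows), length(cols))
  for (oy in off) {
    dy2 <- (g$y[rows] + oy - center[2])^2
    for (ox in off) {
      dx2 <- (g$x[cols] + ox - center[1])^2
      cov <- cov + (outer(dy2, dx2, "+") < radius^2)
    }
  }
  cov <- cov / ss^2
  if (additive) {
    slice[rows, cols] <- slice[rows, cols] + hu * cov
  } else {
    slice[rows, cols] <- slice[rows, cols] * (1 - cov) + hu * cov
  }
  slice
}

# Anti-aliased axis-aligned rectangle [x0,x1] x [y0,y1], additive.
add_rect <- function(slice, g, x0, x1, y0, y1, hu, ss = 5L) {
  cols <- which(g$x > x0 - g$dx & g$x < x1 + g$dx)
  rows <- which(g$y > y0 - g$dx & g$y < y1 + g$dx)
  if (!length(cols) || !length(rows)) return(slice)
  off <- ((seq_len(ss) - 0.5) / ss - 0.5) * g$dx
  fx <- rowMeans(vapply(off, function(o) {
    xx <- g$x[cols] + o; as.numeric(xx >= x0 & xx <= x1)
  }, numeric(length(cols))))
  fy <- rowMeans(vapply(off, function(o) {
    yy <- g$y[rows] + o; as.numeric(yy >= y0 & yy <= y1)
  }, numeric(length(rows))))
  slice[rows, cols] <- slice[rows, cols] + hu * outer(fy, fx)
  slice
}

# Deposit a sub-voxel wire (treated as a point source of integrated signal
# in HU * mm^2) with the exact physical transfer: Gaussian point spread
# followed by integration over each pixel aperture. Each pixel receives
# S * [Phi((x+ - xw)/s) - Phi((x- - xw)/s)] * [same in y] / dx^2, the
# separable Gauss-times-box response; with zero blur this degenerates to
# whole-signal deposition into the containing pixel. Added after the scene
# blur (the surrounding background is flat, so blurring commutes).
add_wire_analytic <- function(slice, g, x, y, sigma_mm, signal_hu_mm2) {
  h <- g$dx / 2
  if (sigma_mm <= 0) {
    r <- round((y - g$y[1]) / g$dx + 1); c <- round((x - g$x[1]) / g$dx + 1)
    if (r >= 1 && r <= nrow(slice) && c >= 1 && c <= ncol(slice)) {
      slice[r, c] <- slice[r, c] + signal_hu_mm2 / g$dx^2
    }
    return(slice)
  }
  win <- 4 * sigma_mm + g$dx
  cols <- which(abs(g$x - x) < win)
  rows <- which(abs(g$y - y) < win)
  wx <- stats::pnorm((g$x[cols] + h - x) / sigma_mm) -
        stats::pnorm((g$x[cols] - h - x) / sigma_mm)
  wy <- stats::pnorm((g$y[rows] + h - y) / sigma_mm) -
        stats::pnorm((g$y[rows] - h - y) / sigma_mm)
  slice[rows, cols] <- slice[rows, cols] +
    signal_hu_mm2 / g$dx^2 * outer(wy, wx)
  slice
}

blur_slice <- function(slice, sigma_mm, dx) {
  if (sigma_mm <= 0) return(slice)
  EBImage::gblur(slice, sigma = sigma_mm / dx)
}

#' Render a synthetic electron-density phantom volume
#'
#' Rasterizes the elliptical solid-water body and its rods on the protocol
#' grid, mapping each rod's RED through the anchor model, then applies
#' Gaussian blur and seeded Gaussian noise. Geometry is axially invariant,
#' so one rendered slice is replicated and only the noise differs per slice.
#'
#' @param config a [sim_config()].
#' @param layout an [default_aed_layout()] (or edited copy).
#' @param model a [red_hu_model()]; defaults to the config protocol's model.
#' @param n_slices number of slices; default covers the 206 mm scan depth.
#' @return A [volume()].
#' @export
render_aed <- function(config, layout = default_aed_layout(),
                       model = red_hu_model(config$protocol),
                       n_slices = NULL) {
  p <- config$protocol
  t <- p$slice_thickness_mm
  if (is.null(n_slices)) n_slices <- round(206 / t)
  g <- grid_coords(p)
  a <- layout$body_mm[["width"]] / 2; b <- layout$body_mm[["height"]] / 2

  body_hu <- red_to_hu(model, 1.00)
  ctr <- rotate_offset(0, 0, config)
  ell <- outer((g$y - ctr[2])^2 / b^2, (g$x - ctr[1])^2 / a^2, "+") <= 1
  base <- matrix(-1000, p$matrix, p$matrix)
  base[ell] <- body_hu

  rods <- layout$rods
  pos <- rotate_offset(rods$x_mm, rods$y_mm, config)
  r <- rods$diameter_mm / 2
  inside <- ((abs(pos[, 1] - ctr[1]) + r)^2 / a^2 +
             (abs(pos[, 2] - ctr[2]) + r)^2 / b^2) <= 1.0001
  if (!all(inside)) stop("rod(s) fall outside the phantom body after offset/roll")
  for (i in seq_len(nrow(rods))) {
    base <- add_disc(base, g, pos[i, ], r[i], red_to_hu(model, rods$red[i]))
  }
  base <- blur_slice(base, config$psf_sigma_mm, g$dx)

  vox <- array(0, dim = c(n_slices, p$matrix, p$matrix))
  with_preserved_seed(config$seed, {
    for (k in seq_len(n_slices)) {
      vox[k, , ] <- base +
        if (config$noise_sd_hu > 0)
          matrix(stats::rnorm(p$matrix^2, 0, config$noise_sd_hu),
                 p$matrix, p$matrix)
        else 0
    }
  })
  volume(vox, pixel_spacing_mm = g$dx, slice_spacing_mm = t,
         origin_mm = c(-p$fov_mm / 2, -p$fov_mm / 2, -n_slices * t / 2),
         series_meta = list(protocol = p$name, kvp = p$kvp, mas = p$mas,
                            site = config$site))
}

#' Render a synthetic image-quality phantom volume
#'
#' Rasterizes the four-section cylindrical phantom: a uniform slab, the
#' low-contrast rods, the geometry/sensitometry/wire section (tilted-wire
#' ramps whose in-plane trace advances by slice-thickness / tan(23 deg) per
#' slice, 3 mm air holes at the 50 mm square corners, sensitometry targets,
#' and the sub-voxel MTF wire deposited by area-weighted splatting), and the
#' bar patterns at 1-5 line pairs per cm. Blur and noise as in
#' [render_aed()].
#'
#' @param config a [sim_config()].
#' @param layout a [default_catphan_layout()] (or edited copy).
#' @param sections which sections' axial extent to render (contiguous range
#'   covering them); default all four over the full 154 mm depth.
#' @param depth_mm full scan depth when all sections are rendered.
#' @return A [volume()].
#' @export
render_catphan <- function(config, layout = default_catphan_layout(),
                           sections = 1:4, depth_mm = 154) {
  p <- config$protocol
  t <- p$slice_thickness_mm
  g <- grid_coords(p)
  offs <- layout$section_offsets_mm
  stopifnot(all(sections %in% 1:4))

  centers <- seq(-depth_mm / 2 + t / 2, depth_mm / 2 - t / 2, by = t)
  if (length(sections) < 4L) {
    zmin <- min(offs[sections]) - 3.5 * t
    zmax <- max(offs[sections]) + 3.5 * t
    centers <- centers[centers >= zmin & centers <= zmax]
  }
  n <- length(centers)
  if (n < 1L) stop("requested sections outside the rendered depth")

  ctr <- rotate_offset(0, 0, config)
  R <- layout$diameter_mm / 2
  cyl <- outer((g$y - ctr[2])^2, (g$x - ctr[1])^2, "+") <= R^2
  base <- matrix(-1000, p$matrix, p$matrix)
  base[cyl] <- layout$uniformity_hu

  section_of <- function(z) {
    d <- abs(z - offs)
    if (min(d) <= 12) which.min(d) else 0L
  }

  render_static <- function(sec) {
    sl <- base
    if (sec == 2L) {
      cr <- layout$contrast_rods
      pos <- rotate_offset(cr$x_mm, cr$y_mm, config)
      for (i in seq_len(nrow(cr))) {
        sl <- add_disc(sl, g, pos[i, ], cr$diameter_mm[i] / 2,
                       layout$uniformity_hu + cr$nominal_hu[i])
      }
    } else if (sec == 4L) {
      lp <- layout$line_pairs
      h <- layout$lp_bar_height_mm
      for (i in seq_len(nrow(lp))) {
        gmm <- lp$gap_mm[i]; nb <- lp$n_bars[i]
        width <- (2 * nb - 1) * gmm
        cen <- rotate_offset(lp$center_x_mm[i], lp$center_y_mm[i], config)
        xl <- cen[1] - width / 2
        for (kbar in seq_len(nb)) {
          x0 <- xl + (2 * (kbar - 1)) * gmm
          sl <- add_rect(sl, g, x0, x0 + gmm,
                         cen[2] - h / 2, cen[2] + h / 2, layout$lp_bar_hu)
        }
      }
    }
    blur_slice(sl, config$psf_sigma_mm, g$dx)
  }

  render_section3 <- function(z) {
    sl <- base
    hs <- layout$hole_square
    half <- hs$side_mm / 2
    corners <- rotate_offset(c(-half, half, half, -half),
                             c(half, half, -half, -half), config)
    for (i in 1:4) {
      sl <- add_disc(sl, g, corners[i, ], hs$hole_diameter_mm / 2, -1000)
    }
    sens <- layout$sensitometry
    spos <- rotate_offset(sens$x_mm, sens$y_mm, config)
    for (i in seq_len(nrow(sens))) {
      sl <- add_disc(sl, g, spos[i, ], sens$diameter_mm[i] / 2, sens$nominal_hu[i])
    }
    ramps <- layout$wire_ramps
    tan_ramp <- tanpi(layout$ramp_angle_deg / 180)
    rw <- 0.3  # rendered ramp wire width, mm
    z3 <- offs[["section3"]]
    rpos <- rotate_offset(ramps$x_mm, ramps$y_mm, config)
    for (i in seq_len(nrow(ramps))) {
      u0 <- (z - t / 2 - z3) / tan_ramp
      u1 <- (z + t / 2 - z3) / tan_ramp
      if (ramps$axis[i] == "x") {
        sl <- add_rect(sl, g, rpos[i, 1] + u0, rpos[i, 1] + u1,
                       rpos[i, 2] - rw / 2, rpos[i, 2] + rw / 2, 4000)
      } else {
        sl <- add_rect(sl, g, rpos[i, 1] - rw / 2, rpos[i, 1] + rw / 2,
                       rpos[i, 2] + u0, rpos[i, 2] + u1, 4000)
      }
    }
    sl <- blur_slice(sl, config$psf_sigma_mm, g$dx)
    w <- layout$mtf_wire
    wpos <- rotate_offset(w$x_mm, w$y_mm, config)
    drift <- (z - z3) * tanpi(w$tilt_deg / 180)
    add_wire_analytic(sl, g, wpos[1] + drift, wpos[2], config$psf_sigma_mm, 2000)
  }

  static_cache <- list()
  vox <- array(0, dim = c(n, p$matrix, p$matrix))
  for (k in seq_len(n)) {
    sec <- section_of(centers[k])
    if (sec == 3L) {
      vox[k, , ] <- render_section3(centers[k])
    } else {
      key <- as.character(sec)
      if (is.null(static_cache[[key]])) static_cache[[key]] <- render_static(sec)
      vox[k, , ] <- static_cache[[key]]
    }
  }
  if (config$noise_sd_hu > 0) {
    with_preserved_seed(config$seed, {
      for (k in seq_len(n)) {
        vox[k, , ] <- vox[k, , ] +
          matrix(stats::rnorm(p$matrix^2, 0, config$noise_sd_hu),
                 p$matrix, p$matrix)
      }
    })
  }
  volume(vox, pixel_spacing_mm = g$dx, slice_spacing_mm = t,
         origin_mm = c(-p$fov_mm / 2, -p$fov_mm / 2, centers[1] - t / 2),
         series_meta = list(protocol = p$name, kvp = p$kvp, mas = p$mas,
                            site = config$site))
}
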