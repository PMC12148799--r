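#' Default electron-density phantom layout
#'
#' Machine-readable layout of an advanced electron density (AED) phantom: an
#' elliptical solid-water body 400 mm wide by 300 mm high holding sixteen
#' 30 mm diameter rods — ten graded inserts spanning relative electron
#' density (RED) 0.28 to 1.78 plus six solid-water reference rods at RED
#' 1.00 placed at the center and periphery. The manufacturer does not publish
#' rod coordinates, so the shipped positions are a reconstruction of the
#' typical arrangement (two rings plus a central rod); analyses always read
#' positions from the layout, never hard-code them, and the layout can be
#' edited or loaded from YAML.
#'
#' @return An object of class `aed_layout` with fields `body_mm`
#'   (width, height of the ellipse) and `rods` (data frame with `label`,
#'   `red`, `x_mm`, `y_mm`, `diameter_mm`, `role`).
#' @export
default_aed_layout <- function() {
  insert <- data.frame(
    label = c("Lung LN-300", "Lung LN-450", "Adipose", "Breast", "Brain",
              "Liver", "Inner Bone", "CaCO3 30%", "CaCO3 50%", "Cortical Bone"),
    red = c(0.28, 0.44, 0.94, 0.97, 1.02, 1.05, 1.16, 1.27, 1.46, 1.78),
    angle_deg = c(0, 60, 120, 180, 240, 300, 30, 210, 90, 270),
    stringsAsFactors = FALSE
  )
  r_outer <- 125
  insert$x_mm <- r_outer * cospi(insert$angle_deg / 180)
  insert$y_mm <- r_outer * sinpi(insert$angle_deg / 180)
  insert$angle_deg <- NULL
  insert$role <- "insert"

  sw_ang_outer <- c(150, 330)
  sw_ang_inner <- c(90, 210, 330)
  sw <- data.frame(
    label = paste0("Solid Water ", 1:6),
    red = 1.00,
    x_mm = c(0, r_outer * cospi(sw_ang_outer / 180), 65 * cospi(sw_ang_inner / 180)),
    y_mm = c(0, r_outer * sinpi(sw_ang_outer / 180), 65 * sinpi(sw_ang_inner / 180)),
    role = "solid_water_reference",
    stringsAsFactors = FALSE
  )
  rods <- rbind(insert[c("label", "red", "x_mm", "y_mm", "role")],
                sw[c("label", "red", "x_mm", "y_mm", "role")])
  rods$diameter_mm <- 30
  rownames(rods) <- NULL
  layout <- structure(list(body_mm = c(width = 400, height = 300), rods = rods),
                      class = "aed_layout")
  validate_aed_layout(layout)
  layout
}

validate_aed_layout <- function(layout) {
  rods <- layout$rods
  stopifnot(all(rods$red > 0), all(rods$diameter_mm > 0))
  if (sum(rods$role == "solid_water_reference") != 6L) {
    stop("layout must contain exactly six solid-water reference rods")
  }
  a <- layout$body_mm[["width"]] / 2; b <- layout$body_mm[["height"]] / 2
  r <- rods$diameter_mm / 2
  inside <- (abs(rods$x_mm) + r)^2 / a^2 + (abs(rods$y_mm) + r)^2 / b^2 <= 1.0001
  if (!all(inside)) stop("rod(s) outside the phantom body: ",
                         paste(rods$label[!inside], collapse = ", "))
  dd <- as.matrix(stats::dist(rods[, c("x_mm", "y_mm")]))
  diag(dd) <- Inf
  if (any(dd < outer(r, r, "+"))) stop("overlapping rods in layout")
  invisible(layout)
}

#' Default image-quality phantom layout
#'
#' Layout of a CatPhan-style four-section cylindrical image quality phantom
#' (200 mm diameter): section 1 a uniform slab (~10 HU); section 2
#' low-contrast rods at nominal 1%, 0.5% and 0.3% contrast (about 10, 5 and
#' 3 HU, the 15 mm diameter targets); section 3 with four 23-degree tilted
#' wire ramps for slice thickness, four 3 mm holes at the corners of a 50 mm
#' square for circular symmetry, ten sensitometry targets, and a central
#' 50 micrometre wire (tilted 5 degrees) for the modulation transfer
#' function; section 4 with bar patterns at 1–5 line pairs per cm (gaps 5,
#' 2.5, 1.67, 1.25 and 1 mm). Angular placements are configurable defaults
#' reconstructed from the phantom's typical arrangement, not measurements.
#'
#' @return An object of class `catphan_layout`.
#' @export
default_catphan_layout <- function() {
  contrast <- data.frame(
    contrast_pct = c(1, 0.5, 0.3),
    nominal_hu = c(10, 5, 3),
    diameter_mm = 15,
    x_mm = 50 * cospi(c(90, 210, 330) / 180),
    y_mm = 50 * sinpi(c(90, 210, 330) / 180)
  )
  ramps <- data.frame(
    name = c("coronal_top", "coronal_bottom", "sagittal_right", "sagittal_left"),
    x_mm = c(0, 0, 38, -38),
    y_mm = c(38, -38, 0, 0),
    axis = c("x", "x", "y", "y"),  # in-plane direction the trace advances along
    stringsAsFactors = FALSE
  )
  sens <- data.frame(
    material = c("Air 1", "PMP", "LDPE", "Polystyrene", "Acrylic",
                 "Bone 20%", "Delrin", "Bone 50%", "Teflon", "Air 2"),
    nominal_hu = c(-1000, -200, -100, -35, 120, 240, 340, 670, 990, -1000),
    stringsAsFactors = FALSE
  )
  ang <- 90 + 36 * (seq_len(nrow(sens)) - 1)
  sens$x_mm <- 72 * cospi(ang / 180)
  sens$y_mm <- 72 * sinpi(ang / 180)
  sens$diameter_mm <- 12

  lp <- data.frame(
    lp_per_cm = 1:5,
    gap_mm = c(5, 2.5, 5 / 3, 1.25, 1),
    center_x_mm = c(-55, -20, 2, 20, 35),
    center_y_mm = 0,
    n_bars = 4L
  )
  stopifnot(all(diff(lp$lp_per_cm) > 0), all(diff(lp$gap_mm) < 0))

  structure(list(
    diameter_mm = 200,
    section_offsets_mm = c(section1 = -55, section2 = -20,
                           section3 = 20, section4 = 58),
    uniformity_hu = 10,
    border_roi_edge_mm = 20,   # border ROIs centered this far from the edge
    roi_radius_mm = 10,
    contrast_rods = contrast,
    wire_ramps = ramps,
    ramp_angle_deg = 23,
    hole_square = list(side_mm = 50, hole_diameter_mm = 3),
    sensitometry = sens,
    # generic sub-pixel position: avoids the knife-edge case of a wire
    # sitting exactly on a pixel corner of the default 512 grid
    mtf_wire = list(x_mm = 0.25, y_mm = 0.25, diameter_mm = 0.05, tilt_deg = 5),
    line_pairs = lp,
    lp_bar_hu = 850,           # aluminium sheets over urethane background
    lp_bar_height_mm = 15
  ), class = "catphan_layout")
}

#' Locate the phantom center on a slice
#'
#' Centroid of the thresholded foreground mask in physical mm. Works for any
#' solid phantom surrounded by air; the threshold splits air from material.
#'
#' @param vol a [volume()].
#' @param slice_index slice to analyse.
#' @param threshold_hu voxels above this count as foreground (default -500,
#'   midway between air and water-like material).
#' @param fill_holes fill interior holes of the foreground mask before taking
#'   the centroid (default TRUE), so air-like internal structures (lung rods,
#'   air sensitometry targets) do not bias the center.
#' @return length-2 numeric (x, y) in mm.
#' @export
locate_phantom_center <- function(vol, slice_index, threshold_hu = -500,
                                  fill_holes = TRUE) {
  sl <- vol$voxels[slice_index, , ]
  m <- sl > threshold_hu
  if (!any(m)) stop("no foreground voxels above ", threshold_hu, " HU")
  if (fill_holes) {
    m <- as.matrix(EBImage::fillHull(EBImage::Image(m * 1))) > 0.5
  }
  cc <- voxel_centers_xy(vol)
  w <- which(m, arr.ind = TRUE)
  c(mean(cc$x[w[, 2]]), mean(cc$y[w[, 1]]))
}

#' Slice index of an image-quality phantom section
#'
#' Maps a section's axial offset (from the layout's reference) to the nearest
#' slice. Callers typically analyse the five-slice window centered there.
#'
#' @param vol a [volume()].
#' @param section integer 1..4.
#' @param layout a [default_catphan_layout()] (or edited copy).
#' @return 1-based slice index.
#' @export
section_slice_index <- function(vol, section, layout) {
  stopifnot(section %in% 1:4)
  z <- layout$section_offsets_mm[[section]]
  zc <- slice_z(vol)
  if (z < zc[1L] - vol$slice_spacing_mm / 2 ||
      z > zc[length(zc)] + vol$slice_spacing_mm / 2) {
    stop(sprintf("section %d (z = %g mm) lies outside the volume [%g, %g] mm",
                 section, z, zc[1L], zc[length(zc)]))
  }
  which.min(abs(zc - z))
}

# --- YAML / JSON serialization --------------------------------------------

#' Save or load a phantom layout
#'
#' Layouts round-trip through YAML unchanged, so sites can version-control
#' their measured rod/target positions. `layout_to_json` writes a resolved
#' layout for downstream tooling.
#'
#' @param layout an `aed_layout` or `catphan_layout`.
#' @param path file path.
#' @return `read_layout_yaml` returns the restored layout object.
#' @export
write_layout_yaml <- function(layout, path) {
  # data frames and named vectors become YAML maps so names survive
  obj <- lapply(unclass(layout), function(x) {
    if (is.data.frame(x) || (is.atomic(x) && !is.null(names(x)))) as.list(x) else x
  })
  obj$.class <- class(layout)[1L]
  yaml::write_yaml(obj, path, precision = 12L)
  invisible(path)
}

#' @rdname write_layout_yaml
#' @export
read_layout_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$.class
  obj$.class <- NULL
  df_fields <- c("rods", "contrast_rods", "wire_ramps", "sensitometry", "line_pairs")
  for (f in intersect(df_fields, names(obj))) {
    obj[[f]] <- as.data.frame(obj[[f]], stringsAsFactors = FALSE)
  }
  for (f in intersect(c("body_mm", "section_offsets_mm"), names(obj))) {
    obj[[f]] <- unlist(obj[[f]])
  }
  layout <- structure(obj, class = cls)
  if (identical(cls, "aed_layout")) validate_aed_layout(layout)
  layout
}

#' @rdname write_layout_yaml
#' @export
layout_to_json <- function(layout, path) {
  jsonlite::write_json(unclass(layout), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
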