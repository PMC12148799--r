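# Small fixture volumes built in code.

# n x n single- or multi-slice volume with constant HU
const_volume <- function(value = 0, n = 64, slices = 1, spacing = 1,
                         slice_spacing = 2) {
  volume(array(value, dim = c(slices, n, n)),
         pixel_spacing_mm = spacing, slice_spacing_mm = slice_spacing)
}

# slice whose HU ramps 1 HU/mm along +x
ramp_volume <- function(n = 64, spacing = 1) {
  v <- const_volume(0, n = n, spacing = spacing)
  cc <- cbctqa:::voxel_centers_xy(v)
  v$voxels[1, , ] <- matrix(rep(cc$x, each = n), n, n)
  v
}

# uniform disc phantom in air, for center-finding tests
disc_volume <- function(center = c(0, 0), radius = 60, hu = 50, n = 160,
                        spacing = 1, slices = 1) {
  v <- const_volume(-1000, n = n, spacing = spacing, slices = slices)
  cc <- cbctqa:::voxel_centers_xy(v)
  m <- outer((cc$y - center[2])^2, (cc$x - center[1])^2, "+") <= radius^2
  for (k in seq_len(slices)) {
    sl <- v$voxels[k, , ]
    sl[m] <- hu
    v$voxels[k, , ] <- sl
  }
  v
}

# brute-force count of voxel centers strictly inside a disc
brute_force_disc_count <- function(vol, center, radius) {
  cc <- cbctqa:::voxel_centers_xy(vol)
  n <- 0L
  for (r in seq_along(cc$y)) {
    for (c in seq_along(cc$x)) {
      if ((cc$x[c] - center[1])^2 + (cc$y[r] - center[2])^2 < radius^2) {
        n <- n + 1L
      }
    }
  }
  n
}

fast_catphan <- function(..., sections = 3) {
  render_catphan(sim_config(...), default_catphan_layout(), sections = sections)
}

# Section-2-like cylinder with a contrast rod and a deterministic
# checkerboard "noise" texture of known population sd.
section2_volume <- function(rod_hu = 10, texture_sd = 5, slices = 5) {
  lay <- default_catphan_layout()
  z2 <- lay$section_offsets_mm[["section2"]]
  v <- const_volume(-1000, n = 250, slices = slices, spacing = 1,
                    slice_spacing = 2)
  v$origin_mm[3] <- z2 - slices
  cc <- cbctqa:::voxel_centers_xy(v)
  cyl <- outer(cc$y^2, cc$x^2, "+") <= 100^2
  rod <- lay$contrast_rods[1, ]
  rodm <- outer((cc$y - rod$y_mm)^2, (cc$x - rod$x_mm)^2, "+") < (rod$diameter_mm / 2)^2
  chk <- texture_sd * (2 * ((outer(1:250, 1:250, "+")) %% 2) - 1)
  for (k in seq_len(slices)) {
    sl <- v$voxels[k, , ]
    sl[cyl] <- 0
    sl[rodm] <- rod_hu
    sl[cyl] <- sl[cyl] + chk[cyl]
    v$voxels[k, , ] <- sl
  }
  v
}
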