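#' CBCT acquisition protocols
#'
#' The default protocol table for O-ring linac CBCT: name, tube potential
#' (kVp), exposure (mAs) and reconstructed slice thickness, all on a 512
#' matrix over a 538 mm field of view. The planning-grade (`cbctp_*`)
#' protocols are carried as configuration entries only.
#'
#' Per-protocol default noise levels are generator tuning choices, not
#' measured values: the three reference protocols (head, thorax,
#' pelvis_large) are set so the rendered 1%-contrast CNR lands near 0.5, 1
#' and 2 respectively; the rest scale from the thorax value with the inverse
#' square root of exposure.
#'
#' @param name protocol name; see `cbct_protocols()` for the list.
#' @return `cbct_protocol()` returns one protocol as a list; the default
#'   table as a data frame from `cbct_protocols()`.
#' @export
cbct_protocols <- function() {
  p <- data.frame(
    name = c("breast", "head", "thorax", "pelvis", "pelvis_large",
             "cbctp_head", "cbctp_pelvis", "cbctp_abdomen_lg"),
    kvp = c(125, 100, 125, 125, 140, 125, 125, 140),
    mas = c(29, 88, 176, 469, 528, 804, 528, 880),
    slice_thickness_mm = c(2, 2, 2, 2, 2, 3, 3, 3),
    fov_mm = 538,
    matrix = 512L,
    stringsAsFactors = FALSE
  )
  p$noise_sd_hu <- 10 * sqrt(176 / p$mas)
  p$noise_sd_hu[p$name == "head"] <- 20
  p$noise_sd_hu[p$name == "thorax"] <- 10
  p$noise_sd_hu[p$name == "pelvis_large"] <- 5
  p
}

#' @rdname cbct_protocols
#' @export
cbct_protocol <- function(name) {
  p <- cbct_protocols()
  i <- match(name, p$name)
  if (is.na(i)) stop("unknown protocol '", name, "'; one of: ",
                     paste(p$name, collapse = ", "))
  as.list(p[i, ])
}

# Median HU across the six institutions for the eleven RED inserts, per
# reference protocol (rows indexed by kVp). These anchor the synthetic
# HU mapping; the sds drive the multi-site spread emulation.
.red_hu_anchors <- local({
  red <- c(0.28, 0.44, 0.94, 0.97, 1.00, 1.02, 1.05, 1.16, 1.27, 1.46, 1.78)
  list(
    red = red,
    hu = list(
      "100" = c(-721, -515, -75, -35, -3, 35, 61, 360, 520, 960, 1720),
      "125" = c(-720, -518, -68, -29, 0.1, 40, 61, 320, 480, 870, 1480),
      "140" = c(-712, -520, -73, -38, -7, 33, 51, 290, 440, 800, 1380)
    ),
    sd = list(
      "100" = c(16, 11, 19, 6, 16, 14, 14, 30, 30, 60, 110),
      "125" = c(16, 8, 8, 5, 6.3, 6, 16, 30, 30, 50, 50),
      "140" = c(14, 10, 5, 3, 6, 6, 9, 18, 30, 50, 50)
    )
  )
})

#' RED-to-HU interpolation model
#'
#' Piecewise-linear mapping from relative electron density (RED) to HU,
#' anchored on the median HU measured across six institutions for each of
#' the eleven phantom inserts at the protocol's tube potential. This is the
#' generator's substitute for beam-spectrum physics: measured medians are the
#' printed ground truth, so synthetic rods land where real scanners put them.
#'
#' @param protocol a protocol name or a list from [cbct_protocol()].
#' @return An object of class `red_hu_model` with an `anchors` data frame
#'   (`red`, `hu`, `sd_hu`) and the kVp it applies to.
#' @export
red_hu_model <- function(protocol = "thorax") {
  if (is.character(protocol)) protocol <- cbct_protocol(protocol)
  key <- as.character(protocol$kvp)
  if (!key %in% names(.red_hu_anchors$hu)) {
    stop("no HU anchors for ", protocol$kvp,
         " kVp; available: ", paste(names(.red_hu_anchors$hu), collapse = ", "))
  }
  structure(list(
    anchors = data.frame(red = .red_hu_anchors$red,
                         hu = .red_hu_anchors$hu[[key]],
                         sd_hu = .red_hu_anchors$sd[[key]]),
    kvp = protocol$kvp
  ), class = "red_hu_model")
}

#' Interpolate HU for a RED value
#'
#' Linear interpolation between the model's anchors; RED outside the anchor
#' range is an error (no extrapolation).
#'
#' @param model a [red_hu_model()].
#' @param red relative electron density value(s).
#' @return HU value(s).
#' @export
red_to_hu <- function(model, red) {
  a <- model$anchors
  if (any(red < min(a$red) - 1e-12 | red > max(a$red) + 1e-12)) {
    stop(sprintf("RED outside anchor range [%g, %g]; no extrapolation",
                 min(a$red), max(a$red)))
  }
  stats::approx(a$red, a$hu, xout = red, rule = 1)$y
}
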