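# Minimal single-frame CT DICOM codec: explicit VR little endian only,
# one file per axial slice, signed 16-bit pixels with linear HU rescale.
# Deliberately narrow: no sequences, no compressed transfer syntaxes,
# no multi-frame, axial orientation only.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_CLASS_CT <- "1.2.840.10008.5.1.4.1.1.2"
UID_ROOT <- "1.2.826.0.1.3680043.10.1474."

.uid_counter <- local({
  i <- 0L
  function() {
    i <<- i + 1L
    paste0(UID_ROOT,
           format(round(as.numeric(Sys.time()) * 1000) %% 1e10, scientific = FALSE),
           ".", Sys.getpid() %% 10000L, ".", i)
  }
})

u16_raw <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
u32_raw <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

# VRs using the 4-byte length form
.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_element <- function(group, element, vr, value_raw) {
  n <- length(value_raw)
  if (n %% 2L == 1L) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
    n <- n + 1L
  }
  head <- c(u16_raw(group), u16_raw(element), charToRaw(vr))
  if (vr %in% .long_vrs) {
    c(head, as.raw(c(0L, 0L)), u32_raw(n), value_raw)
  } else {
    if (n > 65534L) stop("value too long for short-form VR")
    c(head, u16_raw(n), value_raw)
  }
}

dcm_str <- function(group, element, vr, s) {
  dcm_element(group, element, vr, charToRaw(as.character(s)))
}

dcm_us <- function(group, element, x) dcm_element(group, element, "US", u16_raw(x))

fmt_ds <- function(x) {
  paste(vapply(x, function(v) formatC(v, format = "g", digits = 10), ""),
        collapse = "\\")
}

#' Write a volume as a DICOM CT series
#'
#' One explicit-little-endian single-frame file per slice. HU are stored as
#' signed 16-bit with rescale slope 1 and intercept -1024, so values are
#' rounded to the nearest integer HU on write (the native granularity of CT
#' data); integer-valued volumes round-trip exactly.
#'
#' @param vol a [volume()].
#' @param directory output directory, created if absent.
#' @return Invisibly, the vector of file paths written, ordered by slice.
#' @export
write_dicom_series <- function(vol, directory) {
  stopifnot(inherits(vol, "cbct_volume"))
  d <- dim(vol$voxels)
  if (prod(d) == 0L) stop("cannot write an empty volume")
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("directory is not writable: ", directory)
  }
  intercept <- -1024
  stored <- round(vol$voxels) - intercept
  if (min(stored) < -32768 || max(stored) > 32767) {
    stop("HU range does not fit 16-bit storage with intercept -1024")
  }
  series_uid <- .uid_counter()
  study_uid <- .uid_counter()
  meta <- vol$series_meta
  zpos <- slice_z(vol)
  # corner-origin convention -> DICOM ImagePositionPatient is the first
  # voxel *center* of each slice
  x0 <- vol$origin_mm[1] + 0.5 * vol$pixel_spacing_mm[2]
  y0 <- vol$origin_mm[2] + 0.5 * vol$pixel_spacing_mm[1]
  paths <- character(d[1L])
  for (k in seq_len(d[1L])) {
    sop_uid <- .uid_counter()
    body <- c(
      dcm_str(0x0008, 0x0016, "UI", SOP_CLASS_CT),
      dcm_str(0x0008, 0x0018, "UI", sop_uid),
      dcm_str(0x0008, 0x0060, "CS", "CT"),
      if (!is.null(meta$site)) dcm_str(0x0008, 0x0080, "LO", meta$site),
      if (!is.null(meta$protocol)) dcm_str(0x0008, 0x103E, "LO", meta$protocol),
      dcm_str(0x0018, 0x0050, "DS", fmt_ds(vol$slice_spacing_mm)),
      if (!is.null(meta$kvp)) dcm_str(0x0018, 0x0060, "DS", fmt_ds(meta$kvp)),
      if (!is.null(meta$mas)) dcm_str(0x0018, 0x1152, "IS", as.character(round(meta$mas))),
      dcm_str(0x0020, 0x000D, "UI", study_uid),
      dcm_str(0x0020, 0x000E, "UI", series_uid),
      dcm_str(0x0020, 0x0013, "IS", as.character(k)),
      dcm_str(0x0020, 0x0032, "DS", fmt_ds(c(x0, y0, zpos[k]))),
      dcm_str(0x0020, 0x0037, "DS", fmt_ds(c(1, 0, 0, 0, 1, 0))),
      dcm_us(0x0028, 0x0002, 1L),
      dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_us(0x0028, 0x0010, d[2L]),
      dcm_us(0x0028, 0x0011, d[3L]),
      dcm_str(0x0028, 0x0030, "DS", fmt_ds(vol$pixel_spacing_mm)),
      dcm_us(0x0028, 0x0100, 16L),
      dcm_us(0x0028, 0x0101, 16L),
      dcm_us(0x0028, 0x0102, 15L),
      dcm_us(0x0028, 0x0103, 1L),
      dcm_str(0x0028, 0x1052, "DS", fmt_ds(intercept)),
      dcm_str(0x0028, 0x1053, "DS", fmt_ds(1)),
      dcm_element(0x7FE0, 0x0010, "OW",
                  writeBin(as.integer(t(stored[k, , ])), raw(),
                           size = 2L, endian = "little"))
    )
    meta_group <- c(
      dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
      dcm_str(0x0002, 0x0002, "UI", SOP_CLASS_CT),
      dcm_str(0x0002, 0x0003, "UI", sop_uid),
      dcm_str(0x0002, 0x0010, "UI", TS_EXPLICIT_LE)
    )
    meta_group <- c(dcm_element(0x0002, 0x0000, "UL", u32_raw(length(meta_group))),
                   meta_group)
    paths[k] <- file.path(directory, sprintf("slice_%04d.dcm", k))
    con <- file(paths[k], "wb")
    writeBin(c(raw(128L), charToRaw("DICM"), meta_group, body), con)
    close(con)
  }
  invisible(paths)
}

# --- reading ---------------------------------------------------------------

# strip trailing NUL/space padding and decode as character
.raw_to_str <- function(r) {
  n <- length(r)
  while (n > 0L && (r[n] == as.raw(0L) || r[n] == as.raw(32L))) n <- n - 1L
  if (n == 0L) "" else rawToChar(r[seq_len(n)])
}

.rd_u16 <- function(r, i) as.integer(r[i]) + 256L * as.integer(r[i + 1L])
.rd_u32 <- function(r, i) {
  as.numeric(r[i]) + 256 * as.numeric(r[i + 1L]) +
    65536 * as.numeric(r[i + 2L]) + 16777216 * as.numeric(r[i + 3L])
}

read_dicom_file <- function(path) {
  r <- readBin(path, raw(), file.size(path))
  if (length(r) < 140L || rawToChar(r[129:132]) != "DICM") {
    stop("not a DICOM part-10 file: ", path)
  }
  i <- 133L
  out <- list()
  ts <- NULL
  repeat {
    if (i + 7L > length(r)) break
    group <- .rd_u16(r, i); element <- .rd_u16(r, i + 2L)
    vr <- rawToChar(r[(i + 4L):(i + 5L)])
    if (vr %in% .long_vrs) {
      len <- .rd_u32(r, i + 8L); vstart <- i + 12L
    } else if (grepl("^[A-Z]{2}$", vr)) {
      len <- .rd_u16(r, i + 6L); vstart <- i + 8L
    } else {
      stop("implicit VR or unsupported transfer syntax in ", path,
           "; only explicit little endian is supported")
    }
    val_raw <- if (len > 0) r[vstart:(vstart + len - 1L)] else raw(0L)
    key <- sprintf("%04X%04X", group, element)
    out[[key]] <- list(vr = vr, raw = val_raw)
    if (group == 0x0002 && element == 0x0010) {
      ts <- .raw_to_str(val_raw)
    }
    i <- vstart + len
    if (group == 0x7FE0 && element == 0x0010) break
  }
  if (!is.null(ts) && ts != TS_EXPLICIT_LE) {
    stop("unsupported transfer syntax ", ts, " (explicit little endian only)")
  }
  out
}

tag_str <- function(el, key) {
  e <- el[[key]]
  if (is.null(e)) return(NULL)
  .raw_to_str(e$raw)
}

tag_ds <- function(el, key) {
  s <- tag_str(el, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

tag_us <- function(el, key) {
  e <- el[[key]]
  if (is.null(e)) return(NULL)
  .rd_u16(e$raw, 1L)
}

#' Read a DICOM CT series into a volume
#'
#' Reads every `.dcm` file in `directory`, checks they belong to one series,
#' sorts slices by axial position and applies the stored linear HU rescale.
#'
#' @param directory directory containing one single-frame CT series.
#' @return A [volume()].
#' @export
read_dicom_series <- function(directory) {
  files <- list.files(directory, pattern = "\\.dcm$", full.names = TRUE)
  if (!length(files)) stop("no DICOM files found in ", directory)
  slices <- lapply(files, read_dicom_file)

  series_uids <- vapply(slices, function(el) {
    u <- tag_str(el, "0020000E")
    if (is.null(u)) stop("missing SeriesInstanceUID (0020,000E)")
    u
  }, "")
  if (length(unique(series_uids)) != 1L) {
    stop("directory mixes multiple DICOM series: ",
         paste(unique(series_uids), collapse = ", "))
  }

  first <- slices[[1L]]
  spacing <- tag_ds(first, "00280030")
  if (is.null(spacing)) stop("missing required tag PixelSpacing (0028,0030)")
  thickness <- tag_ds(first, "00180050")
  if (is.null(thickness)) stop("missing required tag SliceThickness (0018,0050)")
  rows <- tag_us(first, "00280010"); cols <- tag_us(first, "00280011")
  if (is.null(rows) || is.null(cols)) stop("missing Rows/Columns (0028,0010/0011)")

  zpos <- vapply(slices, function(el) {
    p <- tag_ds(el, "00200032")
    if (is.null(p)) stop("missing ImagePositionPatient (0020,0032)")
    p[3L]
  }, 0.0)
  ord <- order(zpos)
  slices <- slices[ord]; zpos <- zpos[ord]

  n <- length(slices)
  vox <- array(0.0, dim = c(n, rows, cols))
  for (k in seq_len(n)) {
    el <- slices[[k]]
    slope <- tag_ds(el, "00281053"); icpt <- tag_ds(el, "00281052")
    if (is.null(slope)) slope <- 1
    if (is.null(icpt)) icpt <- 0
    signed <- identical(tag_us(el, "00280103"), 1L)
    pix <- el[["7FE00010"]]
    if (is.null(pix)) stop("missing PixelData (7FE0,0010)")
    stored <- readBin(pix$raw, integer(), n = rows * cols, size = 2L,
                      signed = signed, endian = "little")
    vox[k, , ] <- matrix(stored * slope + icpt, nrow = rows, byrow = TRUE)
  }

  slice_sp <- if (n > 1L) {
    dz <- diff(zpos)
    if (any(dz <= 0) || diff(range(dz)) > 1e-6) {
      stop("slice positions are not uniformly increasing")
    }
    mean(dz)
  } else thickness[1L]

  first_sorted <- slices[[1L]]
  ipp <- tag_ds(first_sorted, "00200032")
  origin <- c(ipp[1L] - 0.5 * spacing[2L],
              ipp[2L] - 0.5 * spacing[1L],
              zpos[1L] - 0.5 * slice_sp)

  meta <- list()
  p <- tag_str(first_sorted, "0008103E"); if (!is.null(p)) meta$protocol <- p
  s <- tag_str(first_sorted, "00080080"); if (!is.null(s)) meta$site <- s
  kv <- tag_ds(first_sorted, "00180060"); if (!is.null(kv)) meta$kvp <- kv
  ma <- tag_str(first_sorted, "00181152"); if (!is.null(ma)) meta$mas <- as.numeric(ma)

  volume(vox, pixel_spacing_mm = spacing, slice_spacing_mm = slice_sp,
         origin_mm = origin, series_meta = meta)
}
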