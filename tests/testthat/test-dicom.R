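make_series_volume <- function(slices = 4, n = 24) {
  v <- const_volume(0, n = n, slices = slices, spacing = 1.0508,
                    slice_spacing = 2)
  set.seed(42)
  v$voxels[] <- round(runif(length(v$voxels), -1000, 1800))
  v$series_meta <- list(protocol = "thorax", kvp = 125, mas = 176,
                        site = "siteA")
  v
}

test_that("a written series reads back voxel-for-voxel with its geometry", {
  v <- make_series_volume()
  d <- withr::local_tempdir()
  paths <- write_dicom_series(v, d)
  expect_length(paths, 4L)
  v2 <- read_dicom_series(d)
  expect_identical(v2$voxels, v$voxels)
  expect_equal(v2$pixel_spacing_mm, v$pixel_spacing_mm)
  expect_equal(v2$slice_spacing_mm, v$slice_spacing_mm)
  expect_equal(v2$origin_mm, v$origin_mm)
  expect_equal(v2$series_meta$protocol, "thorax")
  expect_equal(v2$series_meta$site, "siteA")
  expect_equal(v2$series_meta$kvp, 125)
  expect_equal(v2$series_meta$mas, 176)
})

test_that("HU spanning the full CT range survive the rescale encoding", {
  v <- const_volume(0, n = 16, slices = 2)
  v$voxels[1, , ] <- -1000
  v$voxels[2, , ] <- 1800
  d <- withr::local_tempdir()
  write_dicom_series(v, d)
  v2 <- read_dicom_series(d)
  expect_identical(v2$voxels, v$voxels)
  # fractional HU are rounded to the nearest integer (native CT granularity)
  v$voxels[1, , ] <- -0.4
  write_dicom_series(v, d)
  expect_true(all(read_dicom_series(d)$voxels[1, , ] == 0))
})

test_that("pydicom independently decodes our files to the same HU", {
  v <- make_series_volume(slices = 1, n = 8)
  d <- withr::local_tempdir()
  p <- write_dicom_series(v, d)
  script <- sprintf(paste0(
    "import pydicom, sys\n",
    "ds = pydicom.dcmread(r'%s')\n",
    "hu = ds.pixel_array * float(ds.RescaleSlope) + float(ds.RescaleIntercept)\n",
    "print(float(hu[0, 0]), float(hu[4, 6]), float(ds.PixelSpacing[0]),",
    " float(ds.ImagePositionPatient[2]))\n"), p[1])
  f <- withr::local_tempfile(fileext = ".py")
  writeLines(script, f)
  out <- suppressWarnings(system2("python", f, stdout = TRUE, stderr = TRUE))
  vals <- as.numeric(strsplit(tail(out, 1), " ")[[1]])
  expect_equal(vals[1], v$voxels[1, 1, 1])
  expect_equal(vals[2], v$voxels[1, 5, 7])
  expect_equal(vals[3], 1.0508, tolerance = 1e-6)
  expect_equal(vals[4], cbctqa:::slice_z(v)[1])
})

test_that("slices are ordered by axial position regardless of file names", {
  v <- make_series_volume(slices = 6)
  d <- withr::local_tempdir()
  paths <- write_dicom_series(v, d)
  # shuffle by renaming
  set.seed(1)
  newnames <- file.path(d, sprintf("x%02d.dcm", sample(6)))
  file.rename(paths, newnames)
  v2 <- read_dicom_series(d)
  expect_identical(v2$voxels, v$voxels)
  expect_equal(v2$slice_spacing_mm, 2)
  expect_true(all(diff(cbctqa:::slice_z(v2)) > 0))
})

test_that("mixed series and missing required tags are rejected", {
  v <- make_series_volume(slices = 2)
  d <- withr::local_tempdir()
  write_dicom_series(v, d)
  # a second series in the same directory
  v$voxels <- v$voxels + 1
  p2 <- write_dicom_series(v, file.path(d, "other"))
  file.copy(p2[1], file.path(d, "intruder.dcm"))
  expect_error(read_dicom_series(d), "multiple DICOM series")

  # corrupt the PixelSpacing tag (0028,0030) into an unknown element
  d2 <- withr::local_tempdir()
  paths <- write_dicom_series(make_series_volume(slices = 1), d2)
  raw <- readBin(paths[1], raw(), file.size(paths[1]))
  tag <- as.raw(c(0x28, 0x00, 0x30, 0x00))
  hit <- which(vapply(seq_len(length(raw) - 3L), function(i)
    all(raw[i:(i + 3L)] == tag), TRUE))[1]
  raw[hit + 2L] <- as.raw(0x31)
  writeBin(raw, paths[1])
  expect_error(read_dicom_series(d2), "PixelSpacing")
})

test_that("an empty volume cannot be written", {
  v <- const_volume(0, n = 8)
  v$voxels <- array(0, dim = c(1, 0, 0))
  expect_error(write_dicom_series(v, withr::local_tempdir()), "empty")
})
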