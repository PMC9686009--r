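test_that("image volumes validate geometry and modality ranges", {
  expect_error(image_volume(matrix(0, 4, 4), spacing = c(0, 1)), "positive")
  expect_error(image_volume(array(0, c(2, 4, 4))), "single-slice")
  v3 <- image_volume(array(1:16, c(1, 4, 4)), modality = "mvcbct")
  expect_identical(dim(v3), c(4L, 4L))
  expect_equal(hu_range("kvct"), c(-1000, 3000))
  expect_equal(hu_range("mvcbct"), c(-1000, 1400))
  expect_equal(hu_range(v3), c(-1000, 1400))
})

test_that("clamp_hu clips to the modality range, idempotently and monotonely", {
  mv <- image_volume(matrix(c(-2000, 0, 2200, 1400), 2), modality = "mvcbct")
  expect_equal(as.vector(clamp_hu(mv)$values), c(-1000, 0, 1400, 1400))
  ct <- image_volume(matrix(c(3200, 500), 1), modality = "kvct")
  expect_equal(as.vector(clamp_hu(ct)$values), c(3000, 500))
  # idempotence and order preservation on random values
  set.seed(4)
  x <- image_volume(matrix(runif(64, -5000, 5000), 8), modality = "mvcbct")
  c1 <- clamp_hu(x); c2 <- clamp_hu(c1)
  expect_identical(c1$values, c2$values)
  o <- order(x$values)
  expect_true(all(diff(c1$values[o]) >= 0))
})

test_that("resample_crop preserves constants, shrinks 0.54 mm grids, pads air", {
  const <- image_volume(matrix(50, 32, 32), spacing = c(1, 1))
  inner <- resample_crop(const, 0.5, c(32, 32))$values
  expect_true(all(abs(inner - 50) < 1e-9))
  # 0.54 mm acquisition grid resampled to 1 mm: the covered field shrinks
  # by a factor of about 0.54 per in-plane axis
  mv <- image_volume(matrix(100, 64, 64), spacing = c(0.54, 0.54),
                     modality = "mvcbct")
  shp <- round(64 * 0.54)
  rs <- resample_crop(mv, 1, c(shp, shp))
  expect_equal(dim(rs), c(shp, shp))
  expect_true(all(abs(rs$values - 100) < 1e-9))
  # cropping wider than the field pads with air
  big <- resample_crop(mv, 1, c(64, 64))
  expect_equal(big$values[1, 1], -1000)
  expect_equal(big$values[32, 32], 100)
  # nearest interpolation keeps masks binary
  msk <- image_volume(matrix(as.numeric(diag(8)), 8), spacing = c(1, 1))
  rsn <- resample_crop(msk, 0.7, c(10, 10), interpolation = "nearest",
                       fill = 0)
  expect_true(all(rsn$values %in% c(0, 1)))
})

test_that("structure masks are strictly boolean and shape-checked", {
  expect_error(structure_mask("m", matrix(c(0, 2), 1)), "boolean")
  m <- structure_mask("mandible", matrix(c(TRUE, FALSE), 1))
  expect_identical(m$name, "mandible")
  expect_type(m$mask, "logical")
})

test_that("NIfTI write/read round-trips HU within int16 quantisation", {
  tmp <- withr::local_tempfile(fileext = ".nii.gz")
  vol <- random_volume(16, seed = 7)
  write_volume(vol, tmp)
  back <- read_volume(tmp, modality = "kvct")
  expect_equal(back$values, vol$values)
  expect_equal(back$spacing, vol$spacing)
  # extreme in-range value survives the int16 encoding
  v2 <- image_volume(matrix(3000, 4, 4))
  tmp2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v2, tmp2)
  expect_equal(read_volume(tmp2)$values, v2$values)
  # all-zero slice round-trips exactly
  z <- image_volume(matrix(0, 16, 16))
  tmp3 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(z, tmp3)
  expect_equal(read_volume(tmp3)$values, z$values)
  expect_error(write_volume(image_volume(matrix(NaN, 2, 2)), tmp3),
               "non-finite")
})

test_that("DICOM slices round-trip and apply rescale slope/intercept", {
  tmp <- withr::local_tempfile(fileext = ".dcm")
  vol <- random_volume(12, seed = 9)
  write_dicom_slice(vol, tmp)
  back <- read_dicom_slice(tmp)
  expect_equal(back$values, vol$values)
  expect_equal(back$spacing, vol$spacing)
  # stored value 1024 with slope 1 / intercept -1024 decodes to 0 HU
  zero <- image_volume(matrix(0, 4, 4))
  tmpz <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_slice(zero, tmpz)
  el <- mvmar:::dcm_parse(tmpz)
  sv <- readBin(el[["7FE0,0010"]]$raw, "integer", n = 16, size = 2,
                signed = TRUE, endian = "little")
  expect_true(all(sv == 1024))
  expect_equal(read_dicom_slice(tmpz)$values, zero$values)
})

test_that("malformed DICOM input is rejected with informative errors", {
  dir <- withr::local_tempdir()
  expect_error(read_volume(dir, format = "dicom-series"), "0 slices")
  # a file missing the rescale tags names the missing tag
  bad <- file.path(dir, "bad.dcm")
  bytes <- c(raw(128), charToRaw("DICM"),
             mvmar:::dcm_element(0x0028, 0x0010, "US", 2),
             mvmar:::dcm_element(0x0028, 0x0011, "US", 2))
  writeBin(bytes, bad)
  expect_error(read_dicom_slice(bad), "RescaleSlope")
  # mixed orientations across a series are rejected
  dir2 <- withr::local_tempdir()
  v <- random_volume(6, seed = 2)
  write_dicom_slice(v, file.path(dir2, "a.dcm"))
  write_dicom_slice(v, file.path(dir2, "b.dcm"))
  raw_b <- readBin(file.path(dir2, "b.dcm"), "raw",
                   file.info(file.path(dir2, "b.dcm"))$size)
  pat <- charToRaw("1\\0\\0\\0\\1\\0")
  idx <- which(vapply(seq_len(length(raw_b) - length(pat) + 1), function(i)
    identical(raw_b[i:(i + length(pat) - 1)], pat), logical(1)))[1]
  raw_b[idx:(idx + length(pat) - 1)] <- charToRaw("0\\1\\0\\1\\0\\0")
  writeBin(raw_b, file.path(dir2, "b.dcm"))
  expect_error(read_dicom_series(dir2), "[Oo]rientation")
})

test_that("masks round-trip through NIfTI", {
  tmp <- withr::local_tempfile(fileext = ".nii.gz")
  m <- structure_mask("parotid", matrix(rep(c(TRUE, FALSE), 32), 8))
  write_mask(m, tmp)
  back <- read_mask(tmp, "parotid")
  expect_identical(back$mask, m$mask)
})
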