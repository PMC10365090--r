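test_that("NIfTI volume and mask round-trip preserves geometry and values", {
  set.seed(7)
  vol <- ct_volume(array(round(rnorm(6 * 5 * 4, 0, 100)), c(6, 5, 4)),
                   spacing_mm = c(0.8, 0.8, 1.25), origin_mm = c(-3, 2, 10))
  for (ext in c(".nii", ".nii.gz")) {
    path <- tempfile(fileext = ext)
    write_ct_volume(vol, path)
    back <- read_ct_series(path)
    expect_identical(back$intensities, vol$intensities)
    expect_true(all(abs(back$spacing_mm - vol$spacing_mm) <= 1e-6))
    expect_true(all(abs(back$origin_mm - vol$origin_mm) <= 1e-5))
    unlink(path)
  }
  fg <- array(FALSE, dim(vol$intensities)); fg[2:4, 2:3, 2:3] <- TRUE
  mask <- segmentation_mask(fg, vol)
  mpath <- tempfile(fileext = ".nii.gz")
  write_mask(mask, mpath)
  back <- read_mask(mpath, vol)
  expect_identical(back$labels, mask$labels)
  unlink(mpath)
})

test_that("DICOM series round-trips and applies rescale slope/intercept", {
  set.seed(1)
  vol <- ct_volume(array(sample(-1000:1000, 8 * 7 * 16, replace = TRUE),
                         c(8, 7, 16)),
                   spacing_mm = c(0.7, 0.9, 2.5), origin_mm = c(1, 2, 3))
  dir <- tempfile()
  write_dicom_series(vol, dir)
  back <- read_ct_series(dir)
  expect_identical(back$intensities, vol$intensities * 1.0)
  expect_equal(back$spacing_mm, vol$spacing_mm, tolerance = 1e-9)

  # stored value 512 with slope 2, intercept -1024 must read back as HU 0:
  # a voxel at 0 HU is stored as (0 + 1024) / 2 = 512
  v0 <- ct_volume(array(0, c(4, 4, 3)), spacing_mm = c(1, 1, 1))
  d0 <- tempfile()
  write_dicom_series(v0, d0, slope = 2, intercept = -1024)
  raw <- radiomix:::dcm_parse_file(list.files(d0, full.names = TRUE)[1])
  stored <- readBin(raw[["7fe0,0010"]], "integer", n = 16, size = 2,
                    endian = "little")
  expect_true(all(stored == 512L))
  expect_true(all(read_ct_series(d0)$intensities == 0))
  unlink(c(dir, d0), recursive = TRUE)
})

test_that("shuffled DICOM slice files reconstruct the sorted volume", {
  set.seed(2)
  vol <- ct_volume(array(sample(-500:500, 6 * 6 * 9, replace = TRUE),
                         c(6, 6, 9)), spacing_mm = c(1, 1, 2))
  d1 <- tempfile(); d2 <- tempfile()
  write_dicom_series(vol, d1)
  dir.create(d2)
  files <- list.files(d1, full.names = TRUE)
  set.seed(3)
  perm <- sample(length(files))
  for (i in seq_along(files))
    file.copy(files[perm[i]],
              file.path(d2, sprintf("slice_%s.dcm", LETTERS[i])))
  expect_identical(read_ct_series(d2)$intensities,
                   read_ct_series(d1)$intensities)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("series integrity errors: mixed series and non-uniform slice gap", {
  vol <- ct_volume(array(0, c(4, 4, 3)), spacing_mm = c(1, 1, 1))
  d <- tempfile()
  write_dicom_series(vol, d)
  write_dicom_series(ct_volume(array(0, c(4, 4, 1)), c(1, 1, 1),
                               origin_mm = c(0, 0, 9)),
                     d2 <- tempfile(), series_uid = "1.2.3.4")
  file.copy(list.files(d2, full.names = TRUE),
            file.path(d, "CT9999.dcm"))
  expect_error(read_ct_series(d), "mixed series")
  unlink(c(d, d2), recursive = TRUE)

  d <- tempfile()
  write_dicom_series(vol, d)
  # duplicate the last slice at a shifted position -> non-uniform gap
  v2 <- ct_volume(array(0, c(4, 4, 1)), c(1, 1, 1), origin_mm = c(0, 0, 2.7))
  write_dicom_series(v2, d3 <- tempfile())
  file.copy(list.files(d3, full.names = TRUE), file.path(d, "CT0099.dcm"))
  expect_error(read_ct_series(d), "non-uniform slice gap")
  unlink(c(d, d3), recursive = TRUE)
})

test_that("read_mask binarizes labels, keeps largest lesion, rejects bad input", {
  vol <- ct_volume(array(0, c(10, 8, 6)), spacing_mm = c(1, 1, 1))
  lab <- array(0L, c(10, 8, 6))
  lab[2:4, 2:4, 2:4] <- 1L   # 27 voxels
  lab[8:9, 6:7, 5] <- 2L     # 4 voxels, disconnected
  p <- tempfile(fileext = ".nii")
  write_nifti(lab, p, spacing = c(1, 1, 1), datatype = 2L)
  m <- read_mask(p, vol)
  # nonzero labels {1,2} are foreground, then the largest 26-connected
  # component (the 27-voxel blob) is kept
  expect_equal(sum(m$labels), 27)
  expect_true(all(which(m$labels, arr.ind = TRUE)[, 1] <= 4))

  # binarization without a second component keeps everything
  lab2 <- lab; lab2[8:9, 6:7, 5] <- 0L; lab2[3, 3, 3] <- 2L
  write_nifti(lab2, p, spacing = c(1, 1, 1), datatype = 2L)
  expect_equal(sum(read_mask(p, vol)$labels), 27)

  write_nifti(array(0L, c(10, 8, 6)), p, spacing = c(1, 1, 1), datatype = 2L)
  expect_error(read_mask(p, vol), "empty segmentation")

  write_nifti(array(1L, c(5, 8, 6)), p, spacing = c(1, 1, 1), datatype = 2L)
  expect_error(read_mask(p, vol), "geometry error")
  unlink(p)
})

test_that("world coordinates follow (index, spacing, origin) across formats", {
  vol <- ct_volume(array(seq_len(4 * 4 * 4) * 1.0, c(4, 4, 4)),
                   spacing_mm = c(0.5, 2, 1.5), origin_mm = c(10, -5, 0))
  p1 <- tempfile(fileext = ".nii"); d1 <- tempfile()
  write_ct_volume(vol, p1)
  write_dicom_series(vol, d1)
  for (back in list(read_ct_series(p1), read_ct_series(d1))) {
    expect_equal(world_coordinate(c(3, 2, 4), back),
                 c(10, -5, 0) + c(2, 1, 3) * c(0.5, 2, 1.5),
                 tolerance = 1e-6)
  }
  unlink(p1); unlink(d1, recursive = TRUE)
})
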