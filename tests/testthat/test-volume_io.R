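test_that("NIfTI write/read round-trips data and affine", {
  td <- withr::local_tempdir()
  v <- volume_grid(array(as.double(0:7), c(2, 2, 2)), diag(4))
  f <- file.path(td, "t.nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_identical(v2$data, v$data)
  expect_equal(v2$affine, v$affine, tolerance = 1e-6)

  # write-then-reread is a fixed point
  f2 <- file.path(td, "t2.nii.gz")
  write_volume(v2, f2)
  expect_identical(read_volume(f2)$data, v2$data)
})

test_that("phantom volumes survive the file round trip with their geometry", {
  td <- withr::local_tempdir()
  ph <- small_phantom()
  f <- file.path(td, "ph.nii.gz")
  write_volume(ph$volume, f)
  v2 <- read_volume(f)
  expect_equal(unname(voxel_size(v2)), small_spec()$voxel_size,
               tolerance = 1e-5)
  expect_equal(v2$data, ph$volume$data, tolerance = 1e-4) # float32 storage
})

test_that("ingest rejects bad inputs and sanitizes non-finite voxels", {
  td <- withr::local_tempdir()
  expect_error(read_volume(file.path(td, "missing.nii")), class = "gd_io_error")

  # more than 3 non-singleton dimensions
  arr4 <- array(0, c(4, 4, 4, 2))
  img <- RNifti::asNifti(arr4)
  f4 <- file.path(td, "4d.nii.gz")
  RNifti::writeNifti(img, f4)
  expect_error(read_volume(f4), class = "gd_validation_error")

  # NaN on disk is sanitized with a warning
  arr <- array(1, c(3, 3, 3)); arr[1] <- NaN
  fn <- file.path(td, "nan.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), fn)
  expect_warning(v <- read_volume(fn), "non-finite")
  expect_true(all(is.finite(v$data)))

  # and refused on write
  vbad <- volume_grid(array(1, c(2, 2, 2)), diag(4))
  vbad$data[1] <- Inf
  expect_error(write_volume(vbad, file.path(td, "x.nii")),
               class = "gd_validation_error")
})

test_that("written files carry no header extensions from the source", {
  td <- withr::local_tempdir()
  img <- RNifti::asNifti(array(as.double(1:64), c(4, 4, 4)))
  img <- RNifti::`extension<-`(img, 6L, charToRaw("patient-name: secret"))
  fin <- file.path(td, "with_ext.nii")
  RNifti::writeNifti(img, fin)
  stopifnot(length(RNifti::extensions(RNifti::readNifti(fin))) > 0)

  fout <- file.path(td, "clean.nii")
  write_volume(read_volume(fin), fout)
  expect_length(RNifti::extensions(RNifti::readNifti(fout)), 0)
  con <- file(fout, "rb"); on.exit(close(con))
  seek(con, 348)
  expect_identical(readBin(con, "raw", 4), as.raw(c(0, 0, 0, 0)))
})

test_that("to_canonical restores RAS order and preserves world coordinates", {
  ph <- small_phantom()
  v <- ph$volume
  expect_identical(orientation_codes(v$affine), c("R", "A", "S"))
  expect_identical(to_canonical(v)$data, v$data)  # fixed point

  # flip axis 1, then swap axes 1 and 2
  d <- dim(v$data)
  arr <- v$data[d[1]:1, , ]
  aff <- v$affine
  aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 1] * (d[1] - 1)
  aff[1:3, 1] <- -aff[1:3, 1]
  vper <- volume_grid(aperm(arr, c(2, 1, 3)), aff[, c(2, 1, 3, 4)])
  expect_false(identical(orientation_codes(vper$affine), c("R", "A", "S")))

  vc <- to_canonical(vper)
  expect_identical(orientation_codes(vc$affine), c("R", "A", "S"))
  expect_identical(vc$data, v$data)
  expect_lt(max(abs(vc$affine - v$affine)), 1e-6)

  # track a marked voxel's world coordinate through the transform
  mark <- c(10L, 20L, 30L)
  w_orig <- geodeface:::voxel_to_world(matrix(mark, 1), v$affine)
  val <- v$data[mark[1] + 1L, mark[2] + 1L, mark[3] + 1L]
  idx_c <- round(geodeface:::world_to_voxel(w_orig, vc$affine)) + 1L
  expect_identical(vc$data[idx_c[1], idx_c[2], idx_c[3]], val)
})
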