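test_that("self-registration recovers the identity transform", {
  ph <- small_phantom()
  tr <- suppressWarnings(register(ph$volume, ph$volume))
  dev <- tr$affine - diag(4)
  expect_lt(max(abs(dev[1:3, 4])), max(voxel_size(ph$volume)))  # < 1 voxel
  expect_lt(max(abs(dev[1:3, 1:3])), 0.02)
})

test_that("a known translation is recovered to sub-millimetre accuracy", {
  ph <- small_phantom()
  shift <- c(10, -5, 3)
  aff2 <- ph$volume$affine
  aff2[1:3, 4] <- aff2[1:3, 4] + shift
  subj <- volume_grid(ph$volume$data, aff2)
  tr <- suppressWarnings(register(subj, ph$volume))
  expect_lt(sqrt(sum((tr$affine[1:3, 4] - shift)^2)), 1)
  expect_lt(max(abs(tr$affine[1:3, 1:3] - diag(3))), 0.01)
})

test_that("demons refinement is stable and its field is finite", {
  ph <- small_phantom()
  tr <- suppressWarnings(register(ph$volume, ph$volume,
                                  mode = "affine+demons"))
  expect_false(is.null(tr$displacement))
  expect_true(all(is.finite(tr$displacement$field)))
  # on identical volumes the refinement has nothing to do
  expect_lt(max(abs(tr$displacement$field)), 0.1)
  p <- matrix(c(10, 20, 30), 1)
  expect_true(all(is.finite(geodeface:::transform_points(tr, p))))
})

test_that("an (effectively) empty field-of-view overlap is an error", {
  # centroid initialization can rescue pure shifts, so probe the metric
  # itself with a transform that leaves no overlap
  ph <- small_phantom()
  lv <- geodeface:::reg_level(geodeface:::downsample_volume(ph$volume, 4))
  A_far <- diag(4); A_far[1:3, 4] <- 1e5
  expect_error(geodeface:::reg_metric(A_far, lv, lv),
               class = "gd_geometry_error")
})
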