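test_that("extract_surface reproduces closed-form volume and area", {
  # interior cube, 10 mm edge on a 1 mm grid, no smoothing
  cmask <- array(FALSE, c(20, 20, 20)); cmask[6:15, 6:15, 6:15] <- TRUE
  cm <- extract_surface(cmask, diag(4), "cube", smooth_iters = 0,
                        pre_smooth_sd = 0)
  expect_lt(abs(mesh_volume(cm) / 1000 - 1), 0.05)
  expect_true(mesh_audit(cm)$watertight)

  # sphere r = 20 mm on a 1 mm grid
  d <- rep(50L, 3); aff <- diag(4); aff[1:3, 4] <- -24.5
  idx <- geodeface:::index_grid(d)
  w <- geodeface:::voxel_to_world(idx, aff)
  smask <- array(sqrt(rowSums(w^2)) <= 20, dim = d)
  sm <- extract_surface(smask, aff, "sphere")
  expect_lt(abs(mesh_area(sm) / (4 * pi * 400) - 1), 0.05)
  expect_lt(abs(mesh_volume(sm) / (4 / 3 * pi * 8000) - 1), 0.05)

  expect_error(extract_surface(array(FALSE, c(5, 5, 5)), diag(4)),
               class = "gd_geometry_error")
})

test_that("surface volume error shrinks as the voxel size shrinks", {
  err_at <- function(vox) {
    n <- as.integer(ceiling(50 / vox))
    aff <- diag(4) * vox; aff[4, 4] <- 1
    aff[1:3, 4] <- -(n - 1) / 2 * vox
    idx <- geodeface:::index_grid(rep(n, 3L))
    w <- geodeface:::voxel_to_world(idx, aff)
    mask <- array(sqrt(rowSums(w^2)) <= 20, dim = rep(n, 3L))
    m <- extract_surface(mask, aff, "sphere")
    abs(mesh_volume(m) / (4 / 3 * pi * 8000) - 1)
  }
  expect_lt(err_at(1), err_at(2))
})

test_that("noise-free phantom segmentation recovers truth labels exactly", {
  ph0 <- small_phantom_noisefree()
  seg <- segment_head(ph0$volume)
  expect_identical(seg$head_mask, ph0$truth$labels > 0)
  expect_identical(seg$brain_mask, ph0$truth$labels == 4L)
  expect_identical(seg$skull_mask, array(ph0$truth$labels %in% c(2L, 3L), dim(ph0$truth$labels)))
})

test_that("noisy phantom segmentation stays near truth across seeds", {
  for (s in c(11L, 12L)) {
    ph <- make_phantom(small_spec(seed = s))
    seg <- segment_head(ph$volume)
    expect_gte(dice(seg$head_mask, ph$truth$labels > 0), 0.98)
    expect_gte(dice(seg$brain_mask, ph$truth$labels == 4L), 0.98)
  }
})

test_that("degenerate contrast raises a segmentation error", {
  expect_error(segment_head(volume_grid(array(5, c(16, 16, 16)), diag(4))),
               class = "gd_geometry_error")
})

test_that("extract_bem_set yields four watertight nested surfaces", {
  ph <- small_phantom()
  bem <- extract_bem_set(ph$volume)
  expect_named(bem$surfaces, c("brain", "inner_skull", "outer_skull", "skin"))
  for (m in bem$surfaces) expect_true(mesh_audit(m)$watertight)
  expect_true(bem$nesting$ok)

  # defaced-surrogate input still yields surfaces with nesting preserved
  bl <- degrade_like(ph$volume, ph$truth, "blank-face")
  bem_bl <- extract_bem_set(bl)
  expect_true(mesh_audit(bem_bl$surfaces$skin)$watertight)
  expect_true(bem_bl$nesting$ok)
})

test_that("phantom skin surface matches analytic truth to voxel accuracy", {
  ph <- small_phantom()
  sh <- phantom_shell(ph, "small")
  h <- hausdorff(sh$skin, ph$truth$surfaces$skin, 5000)
  expect_lte(h$symmetric, 2 * max(voxel_size(ph$volume)))
})
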