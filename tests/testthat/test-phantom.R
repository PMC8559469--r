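test_that("phantom generation is deterministic and respects its spec", {
  a <- make_phantom(small_spec())
  b <- make_phantom(small_spec())
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$labels, b$truth$labels)

  # different seed, different noise
  c_ <- make_phantom(small_spec(seed = 99L))
  expect_false(identical(a$volume$data, c_$volume$data))

  # noise-free: voxel at the head centre has exactly the brain mean
  ph0 <- small_phantom_noisefree()
  sp <- ph0$truth$spec
  ctr_idx <- round(geodeface:::world_to_voxel(matrix(sp$head_centre, 1),
                                              ph0$volume$affine)) + 1L
  expect_identical(ph0$volume$data[ctr_idx[1], ctr_idx[2], ctr_idx[3]],
                   unname(sp$tissue_means["brain"]))
})

test_that("phantom spec validation rejects broken geometry", {
  expect_error(small_spec(brain_radii = c(60, 74, 55)),  # not nested
               class = "gd_validation_error")
  expect_error(small_spec(noise_sd = 20),                # means too close
               class = "gd_validation_error")
  expect_error(small_spec(tissue_means = c(background = 200, scalp = 100,
                                           skull = 40, brain = 130)),
               class = "gd_validation_error")
  expect_error(phantom_spec(shape = rep(40L, 3), voxel_size = rep(2, 3)),
               class = "gd_validation_error")  # head does not fit FOV
})

test_that("truth surfaces are watertight, nested and match closed forms", {
  # featureless phantom: skin volume has an exact closed form
  sp <- phantom_spec(nose = FALSE, ears = FALSE)
  ph <- make_phantom(sp)
  vol <- mesh_volume(ph$truth$surfaces$skin)
  expect_lt(abs(vol / (4 / 3 * pi * prod(sp$skin_radii)) - 1), 0.02)

  ph2 <- small_phantom()
  vols <- numeric(0)
  for (nm in c("brain", "inner_skull", "outer_skull", "skin")) {
    a <- mesh_audit(ph2$truth$surfaces[[nm]])
    expect_true(a$watertight, info = nm)
    expect_identical(a$n_components, 1L)
    expect_equal(a$genus, 0, info = nm)
    expect_identical(geodeface:::mesh_self_intersections(
      ph2$truth$surfaces[[nm]]), 0L)
    vols[nm] <- a$volume
  }
  expect_true(all(diff(vols) > 0))  # strictly nested volumes
})

test_that("truth landmarks lie on the skin surface and labels partition", {
  ph <- small_phantom()
  d <- mesh_closest_point(geodeface:::cps_matrix(ph$truth$landmarks),
                          ph$truth$surfaces$skin)$distance
  expect_lt(max(d), max(ph$truth$spec$voxel_size) / 2)
  expect_true(all(ph$truth$labels %in% 0:4))
  expect_identical(dim(ph$truth$labels), dim(ph$volume$data))
  # feature voxels are scalp-labelled and outside the base head compartments
  for (nm in names(ph$truth$feature_masks))
    expect_true(all(ph$truth$labels[ph$truth$feature_masks[[nm]]] == 1L))
})

test_that("degrade_like produces the intended surrogates", {
  ph <- small_phantom()
  bl <- degrade_like(ph$volume, ph$truth, "blank-face")
  face <- ph$truth$landmarks$points
  face <- face[face$label == "face", ]
  idx <- geodeface:::index_grid(dim(bl$data))
  w <- geodeface:::voxel_to_world(idx, bl$affine)
  in_face <- rep(FALSE, nrow(w))
  for (i in seq_len(nrow(face)))
    in_face <- in_face | ((w[, 1] - face$x[i])^2 + (w[, 2] - face$y[i])^2 +
                            (w[, 3] - face$z[i])^2 <= face$radius[i]^2)
  surface_tissue <- as.vector(ph$truth$labels) <= 1L
  expect_true(all(bl$data[in_face & surface_tissue] == 0))
  expect_identical(bl$data[!(in_face & surface_tissue)],
                   ph$volume$data[!(in_face & surface_tissue)])

  # blur with kernel sd -> 0 is the identity
  expect_identical(degrade_like(ph$volume, ph$truth, "blur-face",
                                blur_sd = 0)$data,
                   ph$volume$data)

  # face removal leaves the brain untouched: Jaccard of brain masks is 1
  seg_o <- segment_head(ph$volume)
  seg_b <- segment_head(bl)
  expect_identical(jaccard(seg_o$brain_mask, seg_b$brain_mask), 1)
})
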