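test_that("build_shell matches the closed-form volume of a spherical shell", {
  d <- rep(100L, 3); aff <- diag(4); aff[1:3, 4] <- -49.5
  v <- volume_grid(array(0, d), aff)
  sh <- build_shell(v, sphere_mesh(40), sphere_mesh(30))
  expect_lt(abs(sum(sh$shell) / (4 / 3 * pi * (40^3 - 30^3)) - 1), 0.03)

  # degenerate: identical surfaces -> empty shell
  expect_error(build_shell(v, sphere_mesh(30), sphere_mesh(30)),
               class = "gd_geometry_error")
  # non-nested surfaces
  expect_error(build_shell(v, sphere_mesh(30), sphere_mesh(40)),
               class = "gd_geometry_error")
})

test_that("the shell excludes every truth brain voxel", {
  ph <- small_phantom()
  sh <- phantom_shell(ph, "small")$shell
  expect_identical(sum(sh$shell & (ph$truth$labels == 4L)), 0L)
})

test_that("apply_influence builds the union-of-balls active mask", {
  ph <- small_phantom()
  sh <- phantom_shell(ph, "small")$shell
  cps <- ph$truth$landmarks

  # nose point alone covers (almost all of) the nose feature inside the shell
  nose_only <- control_point_set(cps$points[1, ], "subject", complete = FALSE)
  a1 <- apply_influence(sh, nose_only)
  feat <- ph$truth$feature_masks$nose & sh$shell
  expect_gte(sum(a1$active & feat) / sum(feat), 0.95)

  # two disjoint ear points give exactly two connected components
  ears <- control_point_set(cps$points[cps$points$label != "face", ],
                            "subject", complete = FALSE)
  a2 <- apply_influence(sh, ears)
  labs <- geodeface:::.mc_label_components(as.logical(a2$active),
                                           dim(a2$active), 26L)
  expect_identical(max(labs), 2L)

  # radius -> 0 empties the active mask (with a warning)
  tiny <- ears; tiny$points$radius <- 1e-9
  expect_warning(a3 <- apply_influence(sh, tiny), "0 active voxels")
  expect_identical(sum(a3$active), 0L)
})

test_that("fit_distribution is the empirical shell distribution", {
  ph <- small_phantom()
  sh <- phantom_shell(ph, "small")$shell
  dist <- fit_distribution(ph$volume, sh)
  expect_identical(length(dist$sample_pool), sum(sh$shell))

  # a constant shell can only yield that constant
  vconst <- volume_grid(array(42, dim(ph$volume$data)), ph$volume$affine)
  dc <- fit_distribution(vconst, sh)
  set.seed(1)
  expect_true(all(sample(dc$sample_pool, 500, replace = TRUE) == 42))

  # sampling consistency: fresh draws match the pool (two-sample KS)
  set.seed(2)
  ks <- suppressWarnings(ks.test(sample(dist$sample_pool, 1e4, replace = TRUE),
                                 sample(dist$sample_pool, 1e4,
                                        replace = TRUE)))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("deface applies exactly the three-way voxel rule", {
  ph <- small_phantom()
  fx <- phantom_shell(ph, "small")
  shell <- apply_influence(fx$shell, ph$truth$landmarks)
  dist <- fit_distribution(ph$volume, shell)
  out <- deface(ph$volume, shell, dist, fx$skin, seed = 3L)

  # (i) active voxels are fresh draws from the pool
  expect_true(all(out$data[shell$active] %in% dist$sample_pool))
  # (ii) strictly outside the skin: zero
  expect_true(all(out$data[!shell$inside_skin] == 0))
  # (iii) everything else bitwise unchanged (conservation)
  untouched <- !shell$active & shell$inside_skin
  expect_identical(out$data[untouched], ph$volume$data[untouched])
  # brain in particular
  expect_identical(out$data[ph$truth$labels == 4L],
                   ph$volume$data[ph$truth$labels == 4L])

  # determinism under the seed; different seed, different fill
  out2 <- deface(ph$volume, shell, dist, fx$skin, seed = 3L)
  expect_identical(out$data, out2$data)
  out3 <- deface(ph$volume, shell, dist, fx$skin, seed = 4L)
  expect_false(identical(out$data, out3$data))

  # grid mismatch is rejected
  vsmall <- volume_grid(array(0, c(8, 8, 8)), diag(4))
  expect_error(deface(vsmall, shell, dist, fx$skin, seed = 1L),
               class = "gd_validation_error")
})

test_that("anonymize composes the pipeline and reports what it did", {
  td <- withr::local_tempdir()
  ph <- small_phantom()
  res <- anonymize(ph$volume, ph$truth$landmarks, seed = 5L,
                   qa_dir = file.path(td, "qa"))
  expect_identical(res$volume$data[ph$truth$labels == 4L],
                   ph$volume$data[ph$truth$labels == 4L])
  expect_identical(res$report$seed, 5L)
  expect_gt(res$report$n_voxels_replaced, 0)
  expect_true(file.exists(file.path(td, "qa", "qa_report.json")))
  expect_true(file.exists(file.path(td, "qa", "slice_axial.png")))

  # re-anonymizing the anonymized volume leaves the brain bitwise intact
  res2 <- anonymize(res$volume, ph$truth$landmarks, seed = 5L)
  expect_identical(res2$volume$data[ph$truth$labels == 4L],
                   ph$volume$data[ph$truth$labels == 4L])

  # zero-exterior off preserves the background
  res3 <- anonymize(ph$volume, ph$truth$landmarks,
                    params = anonymize_params(zero_exterior = "off"),
                    seed = 5L)
  outside <- !res$shell$inside_skin & !res$shell$active
  expect_identical(res3$volume$data[outside], ph$volume$data[outside])
})
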