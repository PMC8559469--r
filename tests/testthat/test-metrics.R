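test_that("jaccard matches a brute-force voxel-count oracle", {
  a <- array(FALSE, c(3, 3, 3)); a[1:2, , ] <- TRUE
  expect_identical(jaccard(a, a), 1)
  b <- array(FALSE, c(3, 3, 3)); b[3, , ] <- TRUE
  expect_identical(jaccard(a, b), 0)
  expect_identical(jaccard(array(FALSE, c(2, 2, 2)),
                           array(FALSE, c(2, 2, 2))), 1)  # empty convention

  # 3x3x3 cube shifted by one voxel: 18/36
  a <- array(FALSE, c(8, 8, 8)); a[3:5, 3:5, 3:5] <- TRUE
  b <- array(FALSE, c(8, 8, 8)); b[4:6, 3:5, 3:5] <- TRUE
  expect_identical(jaccard(a, b), 0.5)

  # 100 random pairs against an elementwise-counting oracle
  set.seed(1)
  for (i in 1:100) {
    a <- array(runif(512) < 0.4, c(8, 8, 8))
    b <- array(runif(512) < 0.4, c(8, 8, 8))
    av <- as.vector(a); bv <- as.vector(b)
    inter <- 0L; uni <- 0L
    for (j in seq_along(av)) {
      if (av[j] && bv[j]) inter <- inter + 1L
      if (av[j] || bv[j]) uni <- uni + 1L
    }
    oracle <- if (uni == 0L) 1 else inter / uni
    expect_identical(jaccard(a, b), oracle)
    expect_identical(jaccard(b, a), jaccard(a, b))  # symmetry
  }

  expect_error(jaccard(a, array(FALSE, c(4, 4, 4))),
               class = "gd_validation_error")
})

test_that("hausdorff matches closed forms and metric properties", {
  s30 <- cached("s30", sphere_mesh(30))
  s40 <- cached("s40", sphere_mesh(40))
  expect_lt(hausdorff(s30, s30, 1000)$symmetric, 1e-9)

  h <- hausdorff(s30, s40, 10000)
  expect_lt(abs(h$symmetric - 10), 0.2)
  expect_identical(h$symmetric, max(h$directed_12, h$directed_21))

  # aligned parallel unit patches 3 mm apart
  p1 <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                rbind(c(1, 2, 3), c(1, 3, 4)), "p1")
  p2 <- trimesh(rbind(c(0, 0, 3), c(1, 0, 3), c(1, 1, 3), c(0, 1, 3)),
                rbind(c(1, 2, 3), c(1, 3, 4)), "p2")
  expect_equal(hausdorff(p1, p2, 1000)$symmetric, 3, tolerance = 1e-9)

  # denser sampling cannot decrease the directed distance (up to sampling
  # jitter well below discretization scale)
  h_lo <- hausdorff(s30, s40, 500)$symmetric
  h_hi <- hausdorff(s30, s40, 20000)$symmetric
  expect_gte(h_hi, h_lo - 0.05)

  # triangle inequality, spot check
  s35 <- cached("s35", sphere_mesh(35))
  h_ac <- hausdorff(s30, s40, 3000)$symmetric
  h_ab <- hausdorff(s30, s35, 3000)$symmetric
  h_bc <- hausdorff(s35, s40, 3000)$symmetric
  expect_lte(h_ac, h_ab + h_bc + 0.1)

  expect_error(hausdorff(trimesh(matrix(0, 0, 3),
                                 matrix(0L, 0, 3)), s30),
               class = "gd_geometry_error")
})

test_that("usability screening classifies usable/distorted/failed", {
  ph <- small_phantom()
  m <- ph$truth$surfaces$skin
  ref <- list(volume_range = mesh_volume(m) * c(0.75, 1.25))
  expect_identical(screen_usability(m, ref)$status, "usable")

  # 30% of vertices displaced 10 mm: distorted
  set.seed(2)
  pick <- sample(nrow(m$vertices), round(0.3 * nrow(m$vertices)))
  dirs <- matrix(rnorm(length(pick) * 3), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  m2 <- m
  m2$vertices[pick, ] <- m2$vertices[pick, ] + 10 * dirs
  u <- screen_usability(m2, ref)
  expect_identical(u$status, "distorted")
  expect_gt(length(u$reasons), 0)

  # volume criterion alone
  m3 <- m; m3$vertices <- m3$vertices * 1.2   # ~1.7x volume
  expect_identical(screen_usability(m3, ref)$status, "distorted")

  # failure token and non-watertight mesh
  expect_identical(screen_usability(NULL)$status, "failed")
  m4 <- m; m4$faces <- m4$faces[-1, , drop = FALSE]
  expect_identical(screen_usability(m4, ref)$status, "failed")
})

test_that("compare_pair is neutral on self-comparison", {
  ph <- small_phantom()
  rep <- compare_pair(ph$volume, ph$volume, n_samples = 2000)
  expect_identical(rep$jaccard, 1)
  for (s in names(rep$usability)) {
    expect_identical(rep$usability[[s]]$status, "usable")
    expect_lt(rep$hausdorff[[s]]$symmetric, 1e-9)
  }
  expect_identical(rep$n_usable_pairs, 4L)

  td <- withr::local_tempdir()
  f <- file.path(td, "rep.json")
  write_report(rep, f)
  expect_identical(jsonlite::read_json(f)$jaccard, 1L)
})

test_that("report_stats wraps the standard paired tests", {
  set.seed(3)
  hd <- list(a = runif(12, 1, 3), b = runif(12, 4, 8), c = runif(12, 4, 8))
  us <- list(a = rep(TRUE, 12), b = c(rep(TRUE, 6), rep(FALSE, 6)))
  st <- report_stats(hd, us)
  expect_identical(nrow(st$wilcoxon), 3L)
  expect_true(all(st$wilcoxon$p_holm >= st$wilcoxon$p, na.rm = TRUE))
  expect_lt(st$wilcoxon$p_holm[st$wilcoxon$method_a == "a" &
                                 st$wilcoxon$method_b == "b"], 0.05)
  expect_identical(nrow(st$mcnemar), 1L)
})
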