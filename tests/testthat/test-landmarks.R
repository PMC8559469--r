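test_that("control point files round-trip through FCSV and JSON", {
  td <- withr::local_tempdir()
  cps <- small_phantom()$truth$landmarks
  for (ext in c("fcsv", "json")) {
    f <- file.path(td, paste0("p.", ext))
    write_points(cps, f)
    cps2 <- read_points(f, space = "subject")
    expect_identical(cps2$points$label, cps$points$label)
    expect_equal(as.matrix(cps2$points[, c("x", "y", "z")]),
                 as.matrix(cps$points[, c("x", "y", "z")]),
                 tolerance = 1e-5, ignore_attr = TRUE)
    expect_equal(cps2$points$radius, cps$points$radius)
  }
})

fcsv_header <- c(
  "# Markups fiducial file version = 4.11",
  "# CoordinateSystem = LPS",
  "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID")

fcsv_row <- function(id, x, y, z, label) {
  sprintf("%s,%g,%g,%g,0,0,0,1,1,1,0,%s,,", id, x, y, z, label)
}

test_that("FCSV coordinate conventions are honoured", {
  td <- withr::local_tempdir()
  rows <- c(fcsv_row("f1", 10, 20, 30, "face"),
            fcsv_row("f2", 1, 0, 0, "face"), fcsv_row("f3", 2, 0, 0, "face"),
            fcsv_row("e1", 0, 1, 0, "ear_L"), fcsv_row("e2", 0, 2, 0, "ear_R"))
  f <- file.path(td, "lps.fcsv")
  writeLines(c(fcsv_header, rows), f)
  p <- read_points(f, space = "subject")
  expect_equal(unlist(p$points[1, c("x", "y", "z")]), c(x = -10, y = -20,
                                                        z = 30))

  # missing CoordinateSystem: LPS assumed, with a warning
  f2 <- file.path(td, "nocs.fcsv")
  writeLines(c(fcsv_header[c(1, 3)], rows), f2)
  expect_warning(p2 <- read_points(f2, space = "subject"), "assuming LPS")
  expect_equal(p2$points$x[1], -10)

  # RAS-declared file is taken verbatim
  f3 <- file.path(td, "ras.fcsv")
  writeLines(c(fcsv_header[1], "# CoordinateSystem = RAS", fcsv_header[3],
               rows), f3)
  expect_equal(read_points(f3, space = "subject")$points$x[1], 10)
})

test_that("point-set validation enforces labels and completeness", {
  td <- withr::local_tempdir()
  f <- file.path(td, "bad.fcsv")
  writeLines(c(fcsv_header, fcsv_row("x", 0, 0, 0, "nose")), f)
  expect_error(read_points(f, space = "subject"),
               class = "gd_validation_error")

  # no face points at all
  f2 <- file.path(td, "noface.fcsv")
  writeLines(c(fcsv_header, fcsv_row("e1", 0, 1, 0, "ear_L"),
               fcsv_row("e2", 0, 2, 0, "ear_R")), f2)
  expect_error(read_points(f2, space = "subject"),
               class = "gd_validation_error")

  expect_error(control_point_set(
    data.frame(label = "face", x = 0, y = 0, z = 0, radius = -1),
    complete = FALSE), class = "gd_validation_error")
})

test_that("template bundles round-trip and detect tampering", {
  td <- withr::local_tempdir()
  ph <- small_phantom()
  tdir <- file.path(td, "tpl")
  tb <- make_template(ph$volume, ph$truth$landmarks, tdir, name = "small")
  expect_s3_class(tb, "template_bundle")
  tb2 <- load_template(tdir)
  expect_identical(tb2$name, "small")
  expect_identical(tb2$control_points$points$label,
                   ph$truth$landmarks$points$label)

  # out-of-FOV point is rejected
  far <- ph$truth$landmarks
  far$points$x[1] <- 1e4
  expect_error(make_template(ph$volume, far, file.path(td, "tpl2")),
               class = "gd_validation_error")

  # checksum mismatch is an integrity error
  writeLines("tampered", file.path(tdir, "points.fcsv"))
  expect_error(load_template(tdir), class = "gd_validation_error")
})

test_that("transfer_points projects onto the skin and preserves fixed points", {
  ph <- small_phantom()
  sh <- phantom_shell(ph, "small")
  identity_tr <- structure(list(affine = diag(4), displacement = NULL),
                           class = "spatial_transform")
  tpl <- control_point_set(ph$truth$landmarks$points, space = "template")

  # points already on the skin: projection moves them at most one voxel
  out <- transfer_points(tpl, identity_tr, sh$skin)
  expect_identical(out$space, "subject")
  moved <- sqrt(rowSums((geodeface:::cps_matrix(out) -
                           geodeface:::cps_matrix(tpl))^2))
  expect_lt(max(moved), max(voxel_size(ph$volume)))

  # a point displaced off the skin along its normal comes back onto it
  perturbed <- tpl
  perturbed$points$y[1] <- perturbed$points$y[1] + 3
  out2 <- transfer_points(perturbed, identity_tr, sh$skin)
  d_on <- mesh_closest_point(geodeface:::cps_matrix(out2), sh$skin)$distance
  expect_lt(max(d_on), 1e-6)  # on-surface invariant

  # hopeless registration: all points far away -> transfer error
  off <- tpl
  off$points[, c("x", "y", "z")] <- off$points[, c("x", "y", "z")] + 500
  expect_error(transfer_points(off, identity_tr, sh$skin, max_projection = 15),
               class = "gd_convergence_error")
})
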