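#' Labelled control points for face and ear masking
#'
#' A `control_point_set` holds labelled 3D landmarks in world mm (RAS), each
#' with an influence radius: the defacing mask is the union of balls of these
#' radii around the points, intersected with the skull-to-skin shell. Labels
#' are `"face"`, `"ear_L"`, `"ear_R"`. A complete set has at least 3 face
#' points and at least one point per ear.
#'
#' @param points Data frame with columns `label`, `x`, `y`, `z`, `radius`.
#' @param space Coordinate frame tag: `"template"` or `"subject"`.
#' @param complete Require the face/ear minimum point counts.
#' @return A `control_point_set`.
#' @export
control_point_set <- function(points, space = c("subject", "template"),
                              complete = TRUE) {
  space <- match.arg(space)
  need <- c("label", "x", "y", "z", "radius")
  if (!all(need %in% names(points)))
    stop_gd("validation", "control points need columns %s",
            paste(need, collapse = ", "))
  points <- as.data.frame(points)[need]
  points$label <- as.character(points$label)
  for (col in c("x", "y", "z", "radius"))
    points[[col]] <- as.numeric(points[[col]])
  allowed <- c("face", "ear_L", "ear_R")
  if (!all(points$label %in% allowed))
    stop_gd("validation", "unknown control-point label(s) %s; allowed: %s",
            paste(setdiff(points$label, allowed), collapse = ", "),
            paste(allowed, collapse = ", "))
  if (any(!is.finite(as.matrix(points[c("x", "y", "z", "radius")]))))
    stop_gd("validation", "control-point positions/radii must be finite")
  if (any(points$radius <= 0))
    stop_gd("validation", "control-point radii must be positive")
  if (complete) {
    if (sum(points$label == "face") < 3)
      stop_gd("validation", "a complete set needs >= 3 face points (got %d)",
              sum(points$label == "face"))
    for (ear in c("ear_L", "ear_R"))
      if (sum(points$label == ear) < 1)
        stop_gd("validation", "a complete set needs >= 1 %s point", ear)
  }
  structure(list(points = points, space = space), class = "control_point_set")
}

#' @export
print.control_point_set <- function(x, ...) {
  cat(sprintf("<control_point_set> %d points (%s space): %s\n",
              nrow(x$points), x$space,
              paste(sprintf("%s x%d", names(table(x$points$label)),
                            table(x$points$label)), collapse = ", ")))
  invisible(x)
}

cps_matrix <- function(cps) as.matrix(cps$points[c("x", "y", "z")])

#' Read and write control points (Slicer FCSV or JSON)
#'
#' FCSV follows the 3D Slicer markups fiducial dialect: `#`-prefixed header
#' lines, then comma-separated rows `id,x,y,z,ow,ox,oy,oz,vis,sel,lock,
#' label,desc,associatedNodeID`. Positions are interpreted per the file's
#' `CoordinateSystem` header (LPS is assumed, with a warning, when absent —
#' the Slicer default) and converted to RAS. The per-point influence radius
#' travels in the `desc` column as `radius=<mm>`. The JSON schema declares
#' its coordinate convention explicitly and carries radii as a first-class
#' field.
#'
#' @param path File path; format chosen by extension (`.fcsv` or `.json`).
#' @param space Space tag to attach to the result.
#' @param default_radius Radius assigned to points that do not carry one.
#' @param complete Enforce face/ear minimum counts.
#' @return A [control_point_set()].
#' @export
read_points <- function(path, space = c("subject", "template"),
                        default_radius = 25, complete = TRUE) {
  space <- match.arg(space)
  if (!file.exists(path))
    stop_gd("io", "cannot read points: no such file '%s'", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "fcsv") {
    lines <- readLines(path, warn = FALSE)
    header <- lines[startsWith(lines, "#")]
    rows <- lines[!startsWith(lines, "#") & nzchar(lines)]
    cs_line <- grep("CoordinateSystem", header, value = TRUE)
    if (length(cs_line) == 0) {
      warn_gd("FCSV '%s' has no CoordinateSystem header; assuming LPS", path)
      cs <- "LPS"
    } else {
      cs_val <- trimws(sub(".*=", "", cs_line[1]))
      cs <- if (cs_val %in% c("0", "RAS")) "RAS" else "LPS"
    }
    if (length(rows) == 0)
      stop_gd("validation", "FCSV '%s' contains no points", path)
    tab <- read.csv(text = rows, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 12)
      stop_gd("validation", "FCSV '%s' has %d columns; need >= 12", path,
              ncol(tab))
    pos <- as.matrix(tab[, 2:4])
    if (cs == "LPS") pos[, 1:2] <- -pos[, 1:2]
    label_raw <- as.character(tab[, 12])
    label <- sub("^(face|ear_L|ear_R).*", "\\1", label_raw)
    bad <- !label %in% c("face", "ear_L", "ear_R")
    if (any(bad))
      stop_gd("validation",
              "unknown label(s) %s in '%s'; allowed: face, ear_L, ear_R",
              paste(unique(label_raw[bad]), collapse = ", "), path)
    radius <- rep(default_radius, nrow(tab))
    if (ncol(tab) >= 13) {
      rdesc <- regmatches(tab[, 13],
                          regexpr("radius=([0-9.]+)", tab[, 13]))
      has <- lengths(regmatches(tab[, 13],
                                gregexpr("radius=", tab[, 13]))) > 0
      radius[has] <- as.numeric(sub("radius=", "", rdesc))
    }
    pts <- data.frame(label = label, x = pos[, 1], y = pos[, 2],
                      z = pos[, 3], radius = radius)
  } else if (ext == "json") {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(doc$coordinate_system, "RAS"))
      stop_gd("validation",
              "points JSON '%s' must declare coordinate_system \"RAS\"", path)
    p <- doc$points
    pos <- do.call(rbind, lapply(p$position, as.numeric))
    pts <- data.frame(label = p$label, x = pos[, 1], y = pos[, 2],
                      z = pos[, 3],
                      radius = p$radius %||% default_radius)
  } else {
    stop_gd("validation", "unsupported points format '%s' (use fcsv/json)",
            ext)
  }
  control_point_set(pts, space = space, complete = complete)
}

#' @rdname read_points
#' @param cps A [control_point_set()].
#' @export
write_points <- function(cps, path) {
  stopifnot(inherits(cps, "control_point_set"))
  ext <- tolower(tools::file_ext(path))
  p <- cps$points
  if (ext == "fcsv") {
    # Slicer convention: store LPS, declare it in the header
    lines <- c(
      "# Markups fiducial file version = 4.11",
      "# CoordinateSystem = LPS",
      "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID",
      sprintf("vtkMRMLMarkupsFiducialNode_%d,%.6f,%.6f,%.6f,0,0,0,1,1,1,0,%s,radius=%g,",
              seq_len(nrow(p)) - 1L, -p$x, -p$y, p$z, p$label, p$radius)
    )
    writeLines(lines, path)
  } else if (ext == "json") {
    doc <- list(
      schema = "geodeface-points-1",
      coordinate_system = "RAS",
      space = cps$space,
      points = data.frame(label = p$label, radius = p$radius)
    )
    doc$points$position <- lapply(seq_len(nrow(p)),
                                  function(i) c(p$x[i], p$y[i], p$z[i]))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop_gd("validation", "unsupported points format '%s' (use fcsv/json)",
            ext)
  }
  invisible(path)
}

#' Transfer template control points onto a subject's skin surface
#'
#' Maps each template-space point through the registration transform, then
#' projects it to the nearest point on the subject's extracted skin mesh so
#' the on-surface invariant holds regardless of registration quality
#' (registration error surfaces only as tangential placement error). Points
#' whose projection distance exceeds `max_projection` mm are flagged; if more
#' than half are flagged the transfer errors, recommending manual points.
#'
#' @param cps Template-space [control_point_set()].
#' @param transform A transform from [register()].
#' @param skin Subject skin [trimesh()].
#' @param max_projection Flagging threshold in mm.
#' @return Subject-space [control_point_set()] with a `projection` attribute
#'   (distances and flags).
#' @export
transfer_points <- function(cps, transform, skin, max_projection = 15) {
  stopifnot(inherits(cps, "control_point_set"))
  if (cps$space != "template")
    stop_gd("validation", "transfer_points expects template-space points")
  P <- cps_matrix(cps)
  Pm <- transform_points(transform, P)
  proj <- mesh_closest_point(Pm, skin)
  flagged <- proj$distance > max_projection
  if (mean(flagged) > 0.5)
    stop_gd("convergence",
            "%d/%d transferred points project > %g mm from the skin; registration likely failed, supply manual points",
            sum(flagged), length(flagged), max_projection)
  out <- cps$points
  out$x <- proj$point[, 1]; out$y <- proj$point[, 2]; out$z <- proj$point[, 3]
  res <- control_point_set(out, space = "subject", complete = FALSE)
  attr(res, "projection") <- list(distance = proj$distance, flagged = flagged)
  res
}

# apply a spatial_transform (affine + optional displacement field) to points
transform_points <- function(transform, P) {
  Pt <- P
  if (!is.null(transform$displacement)) {
    disp <- transform$displacement
    idx <- world_to_voxel(P, disp$affine)
    for (k in 1:3) {
      u <- .mc_interp(as.double(disp$field[, , , k]), disp$dims, idx, 0)
      Pt[, k] <- Pt[, k] + u
    }
  }
  t(transform$affine %*% rbind(t(Pt), 1))[, 1:3, drop = FALSE]
}

#' Create a reusable template bundle
#'
#' Writes a directory containing `template.nii.gz`, `points.fcsv` and a
#' `manifest.json` with checksums, loadable by [load_template()] and by the
#' CLI's `anonymize --template`.
#'
#' @param volume Template [volume_grid()].
#' @param cps Complete [control_point_set()] (any space tag; stored as
#'   template space).
#' @param out Output directory (created if needed).
#' @param name,version Identification strings stored in the manifest.
#' @return A `template_bundle` (invisibly the loaded bundle).
#' @export
make_template <- function(volume, cps, out, name = "template",
                          version = "1") {
  stopifnot(inherits(volume, "volume_grid"))
  cps <- control_point_set(cps$points, space = "template", complete = TRUE)
  # in-FOV check
  idx <- world_to_voxel(cps_matrix(cps), volume$affine)
  d <- dim(volume$data)
  inside <- idx[, 1] >= -0.5 & idx[, 1] <= d[1] - 0.5 &
    idx[, 2] >= -0.5 & idx[, 2] <= d[2] - 0.5 &
    idx[, 3] >= -0.5 & idx[, 3] <= d[3] - 0.5
  if (!all(inside))
    stop_gd("validation", "%d control point(s) outside the template FOV",
            sum(!inside))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  vol_path <- file.path(out, "template.nii.gz")
  pts_path <- file.path(out, "points.fcsv")
  write_volume(volume, vol_path)
  write_points(cps, pts_path)
  manifest <- list(
    schema = "geodeface-template-1", name = name, version = version,
    files = list(
      volume = list(path = "template.nii.gz",
                    md5 = unname(tools::md5sum(vol_path))),
      points = list(path = "points.fcsv",
                    md5 = unname(tools::md5sum(pts_path)))
    )
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(load_template(out))
}

#' @rdname make_template
#' @param dir Template bundle directory.
#' @export
load_template <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path))
    stop_gd("io", "'%s' is not a template bundle (no manifest.json)", dir)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  for (f in man$files) {
    p <- file.path(dir, f$path)
    if (!file.exists(p))
      stop_gd("io", "template bundle file missing: '%s'", p)
    if (!identical(unname(tools::md5sum(p)), f$md5))
      stop_gd("validation", "template bundle integrity error: checksum mismatch for '%s'",
              f$path)
  }
  volume <- read_volume(file.path(dir, man$files$volume$path))
  cps <- read_points(file.path(dir, man$files$points$path),
                     space = "template")
  structure(list(volume = volume, control_points = cps,
                 name = man$name, version = man$version, dir = dir),
            class = "template_bundle")
}
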