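#' Triangulated surface meshes
#'
#' A `trimesh` holds a triangulated closed surface: an N x 3 matrix of vertex
#' coordinates in world mm and an M x 3 matrix of 1-based vertex indices,
#' plus a surface label (`"skin"`, `"outer_skull"`, `"inner_skull"`,
#' `"brain"`, or free-form). Meshes produced by [extract_surface()] are
#' watertight, single-component and outward-oriented (positive signed
#' volume); [mesh_audit()] verifies these properties for any mesh.
#'
#' @param vertices N x 3 numeric matrix (world mm).
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @param label Surface label string.
#' @return A `trimesh` object.
#' @export
trimesh <- function(vertices, faces, label = "surface") {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3 || ncol(faces) != 3)
    stop_gd("validation", "vertices and faces must have 3 columns")
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop_gd("validation", "face indices out of range")
  if (any(!is.finite(vertices)))
    stop_gd("validation", "mesh vertices contain non-finite values")
  structure(list(vertices = vertices, faces = faces, label = label),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh '%s'> %d vertices, %d faces, volume %.1f mm^3\n",
              x$label, nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  invisible(x)
}

#' Audit a mesh for watertightness, orientation and topology
#'
#' @param m A [trimesh()].
#' @return List with edge counts (`n_boundary_edges`, `n_nonmanifold_edges`,
#'   `n_misoriented_edges`), `n_components`, Euler characteristic, `volume`
#'   (signed, mm^3), `area` (mm^2), plus derived flags `watertight` and
#'   `genus`.
#' @export
mesh_audit <- function(m) {
  a <- .mc_mesh_audit(m$vertices, m$faces - 1L)
  a$watertight <- a$n_boundary_edges == 0L && a$n_nonmanifold_edges == 0L &&
    a$n_misoriented_edges == 0L
  a$genus <- (2L * a$n_components - a$euler) / 2
  a
}

#' @rdname mesh_audit
#' @export
mesh_volume <- function(m) .mc_mesh_audit(m$vertices, m$faces - 1L)$volume

#' @rdname mesh_audit
#' @export
mesh_area <- function(m) .mc_mesh_audit(m$vertices, m$faces - 1L)$area

# keep only the largest connected component (by face count)
mesh_largest_component <- function(m) {
  comp <- .mc_mesh_vertex_components(nrow(m$vertices), m$faces - 1L)
  if (max(comp) <= 1L) return(m)
  face_comp <- comp[m$faces[, 1]]
  keep_comp <- as.integer(names(which.max(table(face_comp))))
  keep_faces <- m$faces[face_comp == keep_comp, , drop = FALSE]
  used <- sort(unique(as.vector(keep_faces)))
  remap <- integer(nrow(m$vertices))
  remap[used] <- seq_along(used)
  trimesh(m$vertices[used, , drop = FALSE],
          matrix(remap[keep_faces], ncol = 3), m$label)
}

# flip face orientation so signed volume is positive (outward normals)
mesh_orient_outward <- function(m) {
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2), drop = FALSE]
  m
}

#' Smooth a mesh with Taubin's lambda/mu method
#'
#' Feature-preserving smoothing that, unlike plain Laplacian smoothing, does
#' not systematically shrink the surface.
#'
#' @param m A [trimesh()].
#' @param iterations Number of lambda+mu passes.
#' @param lambda,mu Taubin coefficients (`mu` slightly more negative than
#'   `-lambda`).
#' @return Smoothed [trimesh()].
#' @export
taubin_smooth <- function(m, iterations = 10, lambda = 0.5, mu = -0.53) {
  if (iterations <= 0) return(m)
  V <- .mc_taubin_smooth(m$vertices, m$faces - 1L, as.integer(iterations),
                         lambda, mu)
  trimesh(V, m$faces, m$label)
}

#' Closest points on a mesh
#'
#' Exact point-to-triangle distances from query points to a mesh, with the
#' closest surface point for each query (uniform-grid accelerated).
#'
#' @param points Q x 3 matrix of world-mm query points.
#' @param m A [trimesh()].
#' @return List with `distance` (length Q), `point` (Q x 3 closest surface
#'   points) and `face` (1-based supporting triangle index).
#' @export
mesh_closest_point <- function(points, m) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(m$faces) == 0) stop_gd("geometry", "mesh has no faces")
  .mc_closest_points(points, m$vertices, m$faces - 1L)
}

# deterministic area-weighted surface samples (plus optionally vertices)
mesh_sample_points <- function(m, n, include_vertices = TRUE) {
  P <- .mc_sample_surface(m$vertices, m$faces - 1L, as.integer(n))
  if (include_vertices) P <- rbind(m$vertices, P)
  P
}

#' Voxelize a closed mesh onto a volume grid
#'
#' Marks every voxel whose centre lies inside the mesh, by parity counting of
#' scanline/triangle crossings in voxel-index space.
#'
#' @param m A [trimesh()] in world mm.
#' @param affine 4x4 voxel-to-world transform of the target grid.
#' @param dims Grid dimensions.
#' @return Logical 3D array.
#' @export
voxelize_mesh <- function(m, affine, dims) {
  Vidx <- world_to_voxel(m$vertices, affine)
  array(.mc_voxelize(Vidx, m$faces - 1L, as.integer(dims)), dim = dims)
}

# count of intersecting non-adjacent triangle pairs (capped); contacts with
# penetration below tol mm are geometric noise, not distortion
mesh_self_intersections <- function(m, max_count = 1000L, tol = 1e-4) {
  .mc_self_intersections(m$vertices, m$faces - 1L, as.integer(max_count), tol)
}

#' Write a mesh to PLY or STL
#'
#' ASCII PLY or STL chosen by file extension.
#'
#' @param m A [trimesh()].
#' @param path Output path ending in `.ply` or `.stl`.
#' @return Invisibly, `path`.
#' @export
write_mesh <- function(m, path) {
  ext <- tolower(tools::file_ext(path))
  con <- file(path, "w")
  on.exit(close(con))
  if (ext == "ply") {
    writeLines(c(
      "ply", "format ascii 1.0",
      sprintf("comment surface label: %s", m$label),
      sprintf("element vertex %d", nrow(m$vertices)),
      "property float x", "property float y", "property float z",
      sprintf("element face %d", nrow(m$faces)),
      "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.6f %.6f %.6f", m$vertices[, 1], m$vertices[, 2],
                       m$vertices[, 3]), con)
    writeLines(sprintf("3 %d %d %d", m$faces[, 1] - 1L, m$faces[, 2] - 1L,
                       m$faces[, 3] - 1L), con)
  } else if (ext == "stl") {
    writeLines(sprintf("solid %s", m$label), con)
    for (f in seq_len(nrow(m$faces))) {
      a <- m$vertices[m$faces[f, 1], ]
      b <- m$vertices[m$faces[f, 2], ]
      c_ <- m$vertices[m$faces[f, 3], ]
      n <- c((b[2]-a[2])*(c_[3]-a[3]) - (b[3]-a[3])*(c_[2]-a[2]),
             (b[3]-a[3])*(c_[1]-a[1]) - (b[1]-a[1])*(c_[3]-a[3]),
             (b[1]-a[1])*(c_[2]-a[2]) - (b[2]-a[2])*(c_[1]-a[1]))
      nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
      writeLines(c(
        sprintf("  facet normal %.6f %.6f %.6f", n[1], n[2], n[3]),
        "    outer loop",
        sprintf("      vertex %.6f %.6f %.6f", a[1], a[2], a[3]),
        sprintf("      vertex %.6f %.6f %.6f", b[1], b[2], b[3]),
        sprintf("      vertex %.6f %.6f %.6f", c_[1], c_[2], c_[3]),
        "    endloop", "  endfacet"), con)
    }
    writeLines(sprintf("endsolid %s", m$label), con)
  } else {
    stop_gd("validation", "unsupported mesh format '%s' (use .ply or .stl)",
            ext)
  }
  invisible(path)
}
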