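#' Volume container and NIfTI input/output
#'
#' A `volume_grid` is the package's in-memory representation of a 3D
#' anatomical image: a numeric array of intensities plus a 4x4 affine mapping
#' 0-based voxel indices to world coordinates in mm (RAS convention after
#' [to_canonical()]). All geometry downstream (meshes, control points,
#' influence radii) lives in world mm.
#'
#' @param data 3D numeric array of intensities.
#' @param affine 4x4 voxel-index-to-world transform (mm). The last row must
#'   be `c(0, 0, 0, 1)`.
#' @return A `volume_grid` object with fields `data` and `affine`.
#' @examples
#' v <- volume_grid(array(0, c(4, 4, 4)), diag(4))
#' voxel_size(v)
#' @export
volume_grid <- function(data, affine) {
  if (length(dim(data)) != 3L)
    stop_gd("validation", "volume data must be a 3D array")
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4, 4)) ||
      abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    stop_gd("validation", "affine must be an invertible 4x4 matrix")
  if (any(!is.finite(data)))
    stop_gd("validation", "volume data contains non-finite values")
  structure(list(data = data, affine = affine), class = "volume_grid")
}

#' @rdname volume_grid
#' @param v A `volume_grid`.
#' @export
voxel_size <- function(v) voxel_sizes(v$affine)

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  vs <- round(voxel_size(x), 3)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm (%s)\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3],
              paste(orientation_codes(x$affine), collapse = "")))
  invisible(x)
}

#' Anatomical orientation codes of an affine
#'
#' For each voxel axis, reports the anatomical direction (one of R/L, A/P,
#' S/I) in which that axis predominantly increases. A canonical volume reads
#' `c("R", "A", "S")`.
#'
#' @param affine 4x4 voxel-to-world matrix.
#' @return Character vector of three direction codes.
#' @export
orientation_codes <- function(affine) {
  R <- affine[1:3, 1:3]
  codes_pos <- c("R", "A", "S")
  codes_neg <- c("L", "P", "I")
  out <- character(3)
  for (j in 1:3) {
    dom <- which.max(abs(R[, j]))
    out[j] <- if (R[dom, j] >= 0) codes_pos[dom] else codes_neg[dom]
  }
  out
}

#' Read a volume from disk
#'
#' Reads NIfTI-1 (`.nii`, `.nii.gz`) and any other format the RNifti backend
#' handles natively. Trailing singleton dimensions are dropped; volumes with
#' more than three non-singleton dimensions are rejected. Non-finite voxels
#' are sanitized to zero with a warning so downstream geometry never sees
#' NaN/Inf.
#'
#' @param path Path to the image file.
#' @return A [volume_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop_gd("io", "cannot read volume: no such file '%s'", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop_gd("io", "failed to parse '%s': %s", path,
                            conditionMessage(e)))
  arr <- as.array(img)
  d <- dim(arr)
  if (sum(d > 1L) > 3L)
    stop_gd("validation", "'%s' has %d non-singleton dimensions; need <= 3",
            path, sum(d > 1L))
  if (length(d) > 3L) d <- d[d > 1L][1:3]
  if (length(d) == 2L) d <- c(d, 1L)
  arr <- array(as.double(arr), dim = d)   # plain array, no backend attributes
  aff <- unname(structure(RNifti::xform(img), imagedim = NULL, code = NULL))
  aff <- matrix(as.numeric(aff[1:4, 1:4]), 4, 4)
  if (any(!is.finite(arr))) {
    n_bad <- sum(!is.finite(arr))
    arr[!is.finite(arr)] <- 0
    warn_gd("sanitized %d non-finite voxels in '%s' to 0", n_bad, path)
  }
  volume_grid(arr, aff)
}

#' Write a volume as NIfTI
#'
#' Always writes a fresh NIfTI-1 header generated from the volume's own
#' geometry; no descriptive fields or header extensions from any source file
#' are ever propagated, so written files carry no identifying metadata beyond
#' the image itself.
#'
#' @param v A [volume_grid()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type (default single-precision float).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(v, path, datatype = "float") {
  stopifnot(inherits(v, "volume_grid"))
  if (any(!is.finite(v$data)))
    stop_gd("validation", "refusing to write volume with non-finite voxels")
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop_gd("io", "output directory does not exist: '%s'", dir)
  img <- RNifti::asNifti(v$data)
  # pixdim must be set before the xforms: RNifti rebuilds the quaternion
  # form against the image's pixdim
  RNifti::pixdim(img) <- voxel_sizes(v$affine)
  RNifti::sform(img) <- structure(v$affine, code = 2L)
  RNifti::qform(img) <- structure(v$affine, code = 2L)
  ok <- tryCatch({
    RNifti::writeNifti(img, path, datatype = datatype)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path))
    stop_gd("io", "failed to write '%s'", path)
  invisible(path)
}

#' Reorient a volume to the closest canonical (RAS) axis order
#'
#' Permutes and flips the voxel axes so that axis 1 increases to the right,
#' axis 2 to anterior and axis 3 to superior, updating the affine so that the
#' world coordinate of every voxel centre is unchanged. Oblique acquisitions
#' beyond `obliquity_tol` (maximum angle between a voxel axis and its
#' dominant world axis, degrees) trigger a warning; computation still
#' proceeds correctly in world space.
#'
#' @param v A [volume_grid()].
#' @param obliquity_tol Obliquity warning threshold in degrees.
#' @return A canonical [volume_grid()].
#' @export
to_canonical <- function(v, obliquity_tol = 20) {
  R <- v$affine[1:3, 1:3]
  dom <- integer(3); sgn <- numeric(3)
  for (j in 1:3) {
    dom[j] <- which.max(abs(R[, j]))
    sgn[j] <- sign(R[dom[j], j])
  }
  if (anyDuplicated(dom)) {
    # heavily oblique: greedy assignment of remaining axes
    warn_gd("volume is too oblique for unique axis codes; using greedy order")
    taken <- logical(3)
    for (j in order(-apply(abs(R), 2, max))) {
      cand <- order(-abs(R[, j]))
      dom[j] <- cand[!taken[cand]][1]
      taken[dom[j]] <- TRUE
      sgn[j] <- sign(R[dom[j], j])
    }
  }
  ang <- numeric(3)
  for (j in 1:3)
    ang[j] <- acos(min(1, abs(R[dom[j], j]) / sqrt(sum(R[, j]^2)))) * 180 / pi
  if (max(ang) > obliquity_tol)
    warn_gd("obliquity %.1f deg exceeds tolerance %.1f deg", max(ang),
            obliquity_tol)

  arr <- v$data
  aff <- v$affine
  d <- dim(arr)
  # flip axes with negative direction
  for (j in 1:3) {
    if (sgn[j] < 0) {
      idx <- switch(j, list(rev(seq_len(d[1])), TRUE, TRUE),
                    list(TRUE, rev(seq_len(d[2])), TRUE),
                    list(TRUE, TRUE, rev(seq_len(d[3]))))
      arr <- do.call(`[`, c(list(arr), idx, drop = FALSE))
      aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, j] * (d[j] - 1)
      aff[1:3, j] <- -aff[1:3, j]
    }
  }
  # permute so voxel axis j maps to world axis j
  perm <- order(dom)
  if (!all(perm == 1:3)) {
    arr <- aperm(arr, perm)
    aff[1:3, 1:3] <- aff[1:3, perm]
  }
  volume_grid(arr, aff)
}
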