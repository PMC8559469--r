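#' Jaccard similarity of two voxel masks
#'
#' The ratio between the intersection and the union of the two sets. By
#' documented convention the value is 1 when both masks are empty.
#'
#' @param a,b Logical arrays on the same grid.
#' @return A number in `[0, 1]`.
#' @examples
#' a <- array(FALSE, c(3, 3, 3)); a[1:2, , ] <- TRUE
#' jaccard(a, a)
#' @export
jaccard <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop_gd("validation", "jaccard: masks are on different grids")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Dice coefficient of two voxel masks
#'
#' @inheritParams jaccard
#' @return A number in `[0, 1]` (1 when both masks are empty).
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop_gd("validation", "dice: masks are on different grids")
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

#' Hausdorff distance between two surfaces
#'
#' Directed distance from mesh 1 to mesh 2 is the maximum, over points
#' sampled densely on mesh 1 (all vertices plus `n_samples` area-weighted
#' face-interior samples), of the exact point-to-triangle distance to mesh 2;
#' the symmetric distance is the larger of the two directed values.
#' Vertex-only evaluation underestimates, hence the face-interior samples.
#'
#' @param m1,m2 [trimesh()] surfaces.
#' @param n_samples Face-interior samples per mesh.
#' @return List with `directed_12`, `directed_21`, `symmetric` (mm).
#' @export
hausdorff <- function(m1, m2, n_samples = 10000) {
  if (nrow(m1$faces) == 0 || nrow(m2$faces) == 0)
    stop_gd("geometry", "hausdorff: empty mesh")
  p1 <- mesh_sample_points(m1, n_samples)
  p2 <- mesh_sample_points(m2, n_samples)
  d12 <- max(mesh_closest_point(p1, m2)$distance)
  d21 <- max(mesh_closest_point(p2, m1)$distance)
  list(directed_12 = d12, directed_21 = d21, symmetric = max(d12, d21))
}

#' Automated surface-usability screening
#'
#' A reproducible proxy for visual inspection of watershed reconstructions:
#' `"failed"` when extraction errored or the mesh is not watertight after
#' repair; `"distorted"` when the mesh is watertight but has more than one
#' component, genus above zero, self-intersections, or an enclosed volume
#' outside the reference range; `"usable"` otherwise.
#'
#' @param m A [trimesh()], or anything else (e.g. a `try-error`) to denote
#'   extraction failure.
#' @param reference_stats Optional list with `volume_range` (length-2, mm^3).
#' @param max_self_intersections Tolerated intersecting triangle pairs.
#' @return List with `status` and `reasons`.
#' @export
screen_usability <- function(m, reference_stats = NULL,
                             max_self_intersections = 0) {
  if (!inherits(m, "trimesh") || nrow(m$faces) == 0)
    return(list(status = "failed", reasons = "surface extraction failed"))
  audit <- mesh_audit(m)
  if (!audit$watertight)
    return(list(status = "failed",
                reasons = sprintf("not watertight (%d boundary, %d non-manifold, %d misoriented edges)",
                                  audit$n_boundary_edges,
                                  audit$n_nonmanifold_edges,
                                  audit$n_misoriented_edges)))
  reasons <- character(0)
  if (audit$n_components > 1)
    reasons <- c(reasons, sprintf("%d components", audit$n_components))
  if (audit$genus > 0)
    reasons <- c(reasons, sprintf("genus %g", audit$genus))
  nsi <- mesh_self_intersections(m, max_count = max_self_intersections + 1L)
  if (nsi > max_self_intersections)
    reasons <- c(reasons, sprintf(">= %d self-intersecting triangle pairs",
                                  nsi))
  if (!is.null(reference_stats$volume_range)) {
    vol <- audit$volume
    rng <- reference_stats$volume_range
    if (vol < rng[1] || vol > rng[2])
      reasons <- c(reasons,
                   sprintf("volume %.0f mm^3 outside reference [%.0f, %.0f]",
                           vol, rng[1], rng[2]))
  }
  list(status = if (length(reasons)) "distorted" else "usable",
       reasons = reasons)
}

#' Geometric similarity report for an original/deidentified pair
#'
#' Reproduces the evaluation battery on any pair of volumes of the same
#' subject: (1) Jaccard similarity of the brain masks from the package's own
#' watershed segmentation of each volume (the skull-strip stand-in, applied
#' identically to both members of the pair); (2) usability screening of the
#' four surfaces re-extracted from the deidentified volume, with the
#' original volume's surface volumes (+/- `volume_tol`) as reference ranges;
#' (3) symmetric Hausdorff distance per surface, computed only where the
#' surface is usable in both volumes — matching the conditional design of
#' the original analysis.
#'
#' @param original,deidentified [volume_grid()] objects on the same subject
#'   geometry.
#' @param params Segmentation parameters, see [segment_params()].
#' @param n_samples Hausdorff sampling density.
#' @param volume_tol Usability volume tolerance (fraction of the original
#'   surface's enclosed volume).
#' @return A `similarity_report`: `jaccard`, `hausdorff` (per surface:
#'   directed both ways + symmetric, NA where not usable in both),
#'   `usability` (per surface status + reasons), bookkeeping counts.
#' @export
compare_pair <- function(original, deidentified, params = segment_params(),
                         n_samples = 10000, volume_tol = 0.25) {
  stopifnot(inherits(original, "volume_grid"),
            inherits(deidentified, "volume_grid"))
  if (!all(dim(original$data) == dim(deidentified$data)))
    stop_gd("validation", "compare_pair: volumes are on different grids")
  bem_o <- tryCatch(extract_bem_set(original, params),
                    gd_error = function(e) e)
  bem_d <- tryCatch(extract_bem_set(deidentified, params),
                    gd_error = function(e) e)
  if (inherits(bem_o, "condition"))
    stop_gd("geometry", "compare_pair: original volume failed segmentation: %s",
            conditionMessage(bem_o))

  jac <- if (inherits(bem_d, "condition")) NA_real_ else
    jaccard(bem_o$segmentation$brain_mask, bem_d$segmentation$brain_mask)

  surfaces <- c("brain", "inner_skull", "outer_skull", "skin")
  usability <- list(); hd <- list()
  n_usable <- 0L
  for (s in surfaces) {
    mo <- bem_o$surfaces[[s]]
    md <- if (inherits(bem_d, "condition")) NULL else bem_d$surfaces[[s]]
    ref <- list(volume_range = mesh_volume(mo) * c(1 - volume_tol,
                                                   1 + volume_tol))
    u_o <- screen_usability(mo, ref)
    u_d <- screen_usability(md, ref)
    usability[[s]] <- u_d
    if (u_o$status == "usable" && u_d$status == "usable") {
      hd[[s]] <- hausdorff(mo, md, n_samples)
      n_usable <- n_usable + 1L
    } else {
      hd[[s]] <- list(directed_12 = NA_real_, directed_21 = NA_real_,
                      symmetric = NA_real_)
    }
  }
  structure(list(
    jaccard = jac, hausdorff = hd, usability = usability,
    n_usable_pairs = n_usable,
    n_voxels = prod(dim(original$data)),
    n_vertices = vapply(bem_o$surfaces, function(m) nrow(m$vertices), 0L)
  ), class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("<similarity_report>\n")
  cat(sprintf("  brain-mask Jaccard: %s\n",
              ifelse(is.na(x$jaccard), "NA", sprintf("%.4f", x$jaccard))))
  for (s in names(x$usability)) {
    hd <- x$hausdorff[[s]]$symmetric
    cat(sprintf("  %-12s %-9s %s\n", s, x$usability[[s]]$status,
                ifelse(is.na(hd), "", sprintf("Hausdorff %.2f mm", hd))))
  }
  invisible(x)
}

#' Serialize a similarity report to JSON
#'
#' @param report A `similarity_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}

#' Paired statistics over batched similarity reports
#'
#' Thin wrapper over standard tests for comparing deidentification methods
#' across subjects: pairwise Wilcoxon signed-rank tests on per-surface
#' Hausdorff distances with Holm correction, and McNemar tests on usability
#' indicators.
#'
#' @param hausdorff_by_method Named list: method -> numeric vector of
#'   per-subject Hausdorff distances (aligned across methods).
#' @param usable_by_method Optional named list: method -> logical vector of
#'   per-subject usability (aligned).
#' @return List with `wilcoxon` (data frame of pairwise Holm-adjusted
#'   p-values) and `mcnemar` (data frame or NULL).
#' @export
report_stats <- function(hausdorff_by_method, usable_by_method = NULL) {
  methods <- names(hausdorff_by_method)
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  wtab <- do.call(rbind, lapply(pairs, function(pr) {
    x <- hausdorff_by_method[[pr[1]]]; y <- hausdorff_by_method[[pr[2]]]
    ok <- is.finite(x) & is.finite(y)
    p <- if (sum(ok) >= 3)
      suppressWarnings(stats::wilcox.test(x[ok], y[ok], paired = TRUE)$p.value)
    else NA_real_
    data.frame(method_a = pr[1], method_b = pr[2], n = sum(ok), p = p)
  }))
  wtab$p_holm <- stats::p.adjust(wtab$p, method = "holm")
  mtab <- NULL
  if (!is.null(usable_by_method)) {
    pairs2 <- utils::combn(names(usable_by_method), 2, simplify = FALSE)
    mtab <- do.call(rbind, lapply(pairs2, function(pr) {
      a <- usable_by_method[[pr[1]]]; b <- usable_by_method[[pr[2]]]
      tab <- table(factor(a, c(FALSE, TRUE)), factor(b, c(FALSE, TRUE)))
      p <- if (sum(tab[1, 2], tab[2, 1]) > 0)
        suppressWarnings(stats::mcnemar.test(tab)$p.value)
      else NA_real_
      data.frame(method_a = pr[1], method_b = pr[2], p = p)
    }))
    mtab$p_holm <- stats::p.adjust(mtab$p, method = "holm")
  }
  list(wilcoxon = wtab, mcnemar = mtab)
}
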