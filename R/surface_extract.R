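#' Default parameters for head segmentation
#'
#' @param smooth_sd Gaussian pre-smoothing sd in voxels (0 disables; use 0
#'   for noise-free data).
#' @param marker_erosion Erosion radius (voxels) applied to the suprathreshold
#'   mask to obtain interior head markers for the watershed.
#' @param min_contrast Minimum separation between the background and tissue
#'   intensity clusters, as a fraction of the intensity range, below which
#'   segmentation aborts with a degenerate-contrast error.
#' @param inner_skull_margin Dilation radius (voxels) of the brain mask used
#'   to place the inner-skull surface.
#' @return Named list of parameters.
#' @export
segment_params <- function(smooth_sd = 1, marker_erosion = 2,
                           min_contrast = 0.05, inner_skull_margin = 2) {
  list(smooth_sd = smooth_sd, marker_erosion = marker_erosion,
       min_contrast = min_contrast, inner_skull_margin = inner_skull_margin)
}

# deterministic k-means on intensities: centres seeded at fixed quantiles
intensity_kmeans <- function(x, probs) {
  centres <- as.numeric(quantile(x, probs, names = FALSE))
  rng <- diff(range(x))
  if (rng == 0) return(NULL)
  # de-duplicate seeds (flat quantiles happen on near-piecewise-constant data)
  for (i in seq_along(centres)[-1]) {
    if (centres[i] - centres[i - 1] < 1e-9 * rng)
      centres[i] <- centres[i - 1] + 0.02 * rng
  }
  km <- suppressWarnings(kmeans(x, centers = matrix(centres, ncol = 1),
                                iter.max = 50, algorithm = "Lloyd"))
  sort(as.numeric(km$centers))
}

#' Watershed-based head, skull and brain segmentation
#'
#' Step 1 of the deidentification procedure. A marker-based priority-flood
#' watershed on the gradient-magnitude image (background markers on the
#' volume border, head markers from the eroded suprathreshold core) provides
#' the head basin; the head mask is the largest component of suprathreshold
#' voxels inside that basin, hole-filled, with the threshold estimated
#' robustly from the border background level. Inside the head, a
#' three-cluster intensity split (dark skull band, mid scalp, bright brain;
#' deterministic quantile-seeded k-means) recovers the skull band and the
#' brain as the bright component containing the conservative bright core.
#' Final masks are classified on raw intensities so they depend only on
#' local data; smoothing feeds the watershed gradient and cluster estimates.
#'
#' @param v A canonical [volume_grid()].
#' @param params See [segment_params()].
#' @return A `segmentation_result`: logical `head_mask`, `skull_mask`,
#'   `brain_mask` on the input grid, plus `thresholds` and `diagnostics`.
#' @export
segment_head <- function(v, params = segment_params()) {
  stopifnot(inherits(v, "volume_grid"))
  d <- dim(v$data)
  vs <- voxel_size(v)
  raw <- v$data
  sm <- gauss_smooth(raw, params$smooth_sd)

  # background level from the volume border (air in any head acquisition);
  # rough tissue threshold a robust offset above it, with a contrast floor
  border <- array(FALSE, dim = d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  bg_mu <- median(raw[border])
  bg_sd <- stats::mad(raw[border])
  rng <- max(raw) - bg_mu
  if (rng <= 0 || rng < params$min_contrast * max(diff(range(raw)),
                                                  .Machine$double.eps))
    stop_gd("geometry",
            "degenerate contrast: no tissue intensities above background")
  t_rough <- bg_mu + max(3 * bg_sd, 0.02 * rng)
  rough <- raw > t_rough
  if (!any(rough))
    stop_gd("geometry", "degenerate contrast: no suprathreshold voxels")

  # markers: border voxels at background (outside basin), eroded rough core
  # (head basin); flood the smoothed gradient magnitude
  markers <- array(0L, dim = d)
  markers[border & !rough] <- 1L
  core <- erode_mask(rough, params$marker_erosion)
  if (!any(core) || !any(markers == 1L))
    stop_gd("geometry",
            "degenerate contrast: empty watershed marker sets (head %d, bg %d)",
            sum(core), sum(markers == 1L))
  markers[core] <- 2L
  grad <- gradient_magnitude(sm, vs)
  ws <- array(.mc_watershed(as.double(grad), as.integer(markers), d), dim = d)
  head_basin <- dilate_mask(ws == 2L, 1.5)

  # head mask: suprathreshold voxels inside the watershed head basin,
  # largest component, cavities filled. Classification is on raw values so
  # the mask depends only on local data (not smoothing support), and the
  # threshold sits just above background so the dark skull band belongs to
  # the head directly — the mask's topology does not rely on hole-filling
  # through an intact scalp, which keeps it robust to defaced inputs.
  head <- fill_holes(largest_component(rough & head_basin))
  if (!any(head))
    stop_gd("geometry", "watershed produced an empty head mask")

  # three-cluster split of head-interior intensities (dark skull band, mid
  # scalp, bright brain); midpoint thresholds
  cc <- intensity_kmeans(raw[head], c(0.02, 0.35, 0.85))
  if (is.null(cc) || length(unique(round(cc, 9))) < 3)
    stop_gd("geometry", "head interior intensity clusters not separable")
  t_dark <- mean(cc[1:2])
  t_bright <- mean(cc[2:3])
  t_brain <- mean(cc[c(1, 3)])
  skull <- largest_component(head & raw < t_dark)
  if (!any(skull))
    stop_gd("geometry", "no dark skull band found inside head mask")
  # brain: the connected component at the wide dark/bright midpoint that
  # contains the conservative bright core (margin-maximizing classification)
  bright_core <- largest_component(head & raw >= t_bright)
  if (!any(bright_core))
    stop_gd("geometry", "no bright brain component found inside skull")
  mask_wide <- head & raw >= t_brain
  labs <- array(.mc_label_components(as.logical(mask_wide), d, 26L), dim = d)
  core_labels <- tabulate(labs[bright_core])
  brain <- fill_holes(array(labs == which.max(core_labels), dim = d))
  touches_exterior <- any(brain & dilate_mask(!head, 1.5))

  structure(list(
    head_mask = head, skull_mask = skull, brain_mask = brain,
    thresholds = c(rough = t_rough, dark = t_dark,
                   bright = t_bright, brain = t_brain),
    diagnostics = list(
      n_head = sum(head), n_skull = sum(skull), n_brain = sum(brain),
      n_bg_markers = sum(markers == 1L), n_head_markers = sum(core),
      brain_touches_exterior = touches_exterior,
      cluster_centres = cc)
  ), class = "segmentation_result")
}

#' Extract a triangulated surface from a binary mask
#'
#' Isosurface of the (optionally Gaussian-smoothed) mask at level 0.5 via
#' marching tetrahedra, mapped to world mm, reduced to its largest connected
#' component, Taubin-smoothed and oriented outward. The result is watertight
#' by construction; if an audit nevertheless finds defects the mesh is
#' returned with a warning and the defect recorded in its diagnostics (so
#' downstream usability screening can classify it), rather than erroring.
#'
#' @param mask Logical 3D array (single foreground component).
#' @param affine 4x4 voxel-to-world transform.
#' @param label Surface label.
#' @param smooth_iters Taubin smoothing iterations.
#' @param pre_smooth_sd Gaussian sd (voxels) applied to the mask before
#'   isosurfacing; reduces voxelization staircase bias in area/volume.
#' @return A [trimesh()] with a `diagnostics` audit attached.
#' @export
extract_surface <- function(mask, affine, label = "surface",
                            smooth_iters = 10, pre_smooth_sd = 1) {
  if (!any(mask)) stop_gd("geometry", "cannot extract surface of empty mask")
  field <- gauss_smooth(array(as.double(mask), dim = dim(mask)), pre_smooth_sd)
  mt <- .mc_marching_tets(as.double(field), dims3(mask), 0.5, 0)
  if (nrow(mt$vertices) == 0)
    stop_gd("geometry", "isosurface is empty for label '%s'", label)
  m <- trimesh(voxel_to_world(mt$vertices, affine), mt$faces + 1L, label)
  m <- mesh_largest_component(m)
  m <- taubin_smooth(m, smooth_iters)
  m <- mesh_orient_outward(m)
  audit <- mesh_audit(m)
  if (!audit$watertight)
    warn_gd("surface '%s' is not watertight after extraction (%d boundary, %d non-manifold edges)",
            label, audit$n_boundary_edges, audit$n_nonmanifold_edges)
  m$diagnostics <- audit
  m
}

#' Extract the four nested BEM surfaces
#'
#' Composes [segment_head()] and [extract_surface()] to produce the brain,
#' inner skull, outer skull and skin surfaces used for EEG/MEG forward
#' modelling. The inner-skull surface is placed a small margin outside the
#' brain mask (dilation clipped to the skull cavity), the convention used by
#' watershed BEM pipelines. Pairwise nesting is checked by voxel containment
#' and reported, not enforced: a nesting violation is an outcome the
#' usability screening is meant to measure.
#'
#' @param v A canonical [volume_grid()].
#' @param params See [segment_params()].
#' @param smooth_iters,pre_smooth_sd Passed to [extract_surface()].
#' @return List with `surfaces` (named list of four [trimesh()]), the
#'   `segmentation`, and a `nesting` report (logical `ok` + per-pair counts).
#' @export
extract_bem_set <- function(v, params = segment_params(), smooth_iters = 10,
                            pre_smooth_sd = 1) {
  seg <- segment_head(v, params)
  d <- dim(v$data)
  outer_region <- fill_holes(seg$skull_mask)
  inner_region <- dilate_mask(seg$brain_mask, params$inner_skull_margin)
  inner_region <- fill_holes(largest_component(inner_region & outer_region))
  surf <- function(mask, label)
    extract_surface(mask, v$affine, label, smooth_iters, pre_smooth_sd)
  surfaces <- list(
    brain = surf(seg$brain_mask, "brain"),
    inner_skull = surf(inner_region, "inner_skull"),
    outer_skull = surf(outer_region, "outer_skull"),
    skin = surf(seg$head_mask, "skin")
  )
  nesting <- check_nesting(surfaces, v$affine, d)
  if (!nesting$ok)
    warn_gd("BEM surfaces are not strictly nested (%s)",
            paste(nesting$violations, collapse = "; "))
  list(surfaces = surfaces, segmentation = seg, nesting = nesting)
}

# voxel-containment nesting check between consecutive surfaces
check_nesting <- function(surfaces, affine, dims) {
  order_ <- c("brain", "inner_skull", "outer_skull", "skin")
  masks <- lapply(surfaces[order_], voxelize_mesh, affine = affine,
                  dims = dims)
  violations <- character(0)
  counts <- integer(0)
  for (i in 1:3) {
    escaped <- sum(masks[[i]] & !masks[[i + 1]])
    counts[paste(order_[i], "outside", order_[i + 1])] <- escaped
    if (escaped > 0)
      violations <- c(violations, sprintf("%d voxels of %s outside %s",
                                          escaped, order_[i], order_[i + 1]))
  }
  list(ok = length(violations) == 0, violations = violations,
       counts = counts)
}
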