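#' Build the skull-to-skin shell mask
#'
#' Voxelizes the skin and outer-skull surfaces onto the volume grid and takes
#' the layer between them: voxels whose centres are inside the skin surface
#' but outside the outer skull — the scalp and facial soft tissue where
#' masking is allowed. The brain can never intersect this shell because the
#' outer skull surface strictly contains it.
#'
#' @param v A [volume_grid()] defining the grid.
#' @param skin,outer_skull Nested watertight [trimesh()] surfaces in subject
#'   world mm.
#' @return A `shell_mask`: logical `shell`, `inside_skin` (kept for exterior
#'   zeroing), `active` (NULL until [apply_influence()]), and the grid
#'   `affine`.
#' @export
build_shell <- function(v, skin, outer_skull) {
  stopifnot(inherits(v, "volume_grid"))
  d <- dim(v$data)
  inside_skin <- voxelize_mesh(skin, v$affine, d)
  inside_skull <- voxelize_mesh(outer_skull, v$affine, d)
  escaped <- sum(inside_skull & !inside_skin)
  if (escaped > 0.01 * sum(inside_skull))
    stop_gd("geometry",
            "outer skull surface is not nested inside the skin surface (%d voxels escape)",
            escaped)
  shell <- inside_skin & !inside_skull
  if (!any(shell))
    stop_gd("geometry", "skull-to-skin shell is empty (degenerate surfaces)")
  structure(list(shell = shell, inside_skin = inside_skin, active = NULL,
                 affine = v$affine),
            class = "shell_mask")
}

#' Restrict the shell to the control-point influence regions
#'
#' The active mask is the union of Euclidean balls (one per control point,
#' with the point's own radius) intersected with the shell. Operationalizes
#' masking "at the intersection of the control points and the skin and skull
#' surfaces" with a simple, manually extensible influence geometry.
#'
#' @param shell A `shell_mask` from [build_shell()].
#' @param cps Subject-space [control_point_set()].
#' @return The `shell_mask` with `active` populated.
#' @export
apply_influence <- function(shell, cps) {
  stopifnot(inherits(shell, "shell_mask"), inherits(cps, "control_point_set"))
  if (cps$space != "subject")
    stop_gd("validation", "apply_influence expects subject-space points")
  d <- dim(shell$shell)
  vs <- voxel_sizes(shell$affine)
  inv <- solve(shell$affine)
  influence <- array(FALSE, dim = d)
  p <- cps$points
  for (i in seq_len(nrow(p))) {
    ctr_idx <- (inv %*% c(p$x[i], p$y[i], p$z[i], 1))[1:3]
    r_idx <- p$radius[i] / vs
    lo <- pmax(1L, as.integer(floor(ctr_idx - r_idx)) + 1L)
    hi <- pmin(d, as.integer(ceiling(ctr_idx + r_idx)) + 1L)
    if (any(lo > hi)) next
    xs <- seq.int(lo[1], hi[1]); ys <- seq.int(lo[2], hi[2])
    zs <- seq.int(lo[3], hi[3])
    sub <- index_grid(c(length(xs), length(ys), length(zs)))
    sub[, 1] <- sub[, 1] + lo[1] - 1L
    sub[, 2] <- sub[, 2] + lo[2] - 1L
    sub[, 3] <- sub[, 3] + lo[3] - 1L
    w <- voxel_to_world(sub, shell$affine)
    inside <- (w[, 1] - p$x[i])^2 + (w[, 2] - p$y[i])^2 +
      (w[, 3] - p$z[i])^2 <= p$radius[i]^2
    influence[sub[inside, , drop = FALSE] + 1L] <- TRUE
  }
  shell$active <- shell$shell & influence
  if (!any(shell$active))
    warn_gd("control-point influence does not intersect the shell (0 active voxels)")
  shell
}

#' Empirical intensity distribution of the shell
#'
#' The fill model is the exact multiset of intensities observed in the
#' skull-to-skin shell; sampling draws from it with replacement, so
#' replacement values follow the shell's own distribution by construction.
#'
#' @param v The [volume_grid()] the shell was built on.
#' @param shell A `shell_mask`.
#' @return An `intensity_distribution` with `sample_pool` and `summary`.
#' @export
fit_distribution <- function(v, shell) {
  stopifnot(inherits(shell, "shell_mask"))
  pool <- as.double(v$data[shell$shell])
  if (length(pool) == 0)
    stop_gd("geometry", "shell is empty; cannot fit intensity distribution")
  structure(list(
    sample_pool = pool,
    summary = list(mean = mean(pool), sd = sd(pool),
                   quantiles = quantile(pool, c(0, .25, .5, .75, 1)))),
    class = "intensity_distribution")
}

#' @export
print.intensity_distribution <- function(x, ...) {
  cat(sprintf("<intensity_distribution> n=%d, mean=%.2f, sd=%.2f\n",
              length(x$sample_pool), x$summary$mean, x$summary$sd))
  invisible(x)
}

#' Deface a volume
#'
#' Applies the masking rule voxelwise: (i) voxels in the active mask receive
#' fresh draws from the shell intensity distribution; (ii) voxels strictly
#' outside the skin surface are set to zero (configurable); (iii) every other
#' voxel — brain, skull, unmasked scalp — is bitwise unchanged. Draws are
#' assigned in increasing linear voxel order under `set.seed(seed)`, so the
#' output is deterministic and independent of iteration order.
#'
#' @param v Input [volume_grid()].
#' @param mask `shell_mask` with `active` populated.
#' @param dist [fit_distribution()] result.
#' @param skin Skin [trimesh()] (used for exterior zeroing if the mask lacks
#'   a cached skin voxelization).
#' @param seed Integer RNG seed.
#' @param zero_exterior `"global"` zeroes everything outside the skin;
#'   `"off"` leaves the exterior untouched.
#' @return The defaced [volume_grid()].
#' @export
deface <- function(v, mask, dist, skin = NULL, seed = 1L,
                   zero_exterior = c("global", "off")) {
  zero_exterior <- match.arg(zero_exterior)
  stopifnot(inherits(v, "volume_grid"), inherits(mask, "shell_mask"),
            inherits(dist, "intensity_distribution"))
  if (!all(dim(v$data) == dim(mask$shell)))
    stop_gd("validation", "volume and mask grids do not match")
  if (is.null(mask$active))
    stop_gd("validation", "mask has no active region; run apply_influence()")
  inside_skin <- mask$inside_skin
  if (is.null(inside_skin)) {
    if (is.null(skin))
      stop_gd("validation", "need a skin mesh or a cached skin voxelization")
    inside_skin <- voxelize_mesh(skin, v$affine, dim(v$data))
  }
  out <- v$data
  active_idx <- which(mask$active)      # increasing linear order
  set.seed(as.integer(seed))
  if (length(active_idx) > 0)
    out[active_idx] <- sample(dist$sample_pool, length(active_idx),
                              replace = TRUE)
  if (zero_exterior == "global") out[!inside_skin] <- 0
  volume_grid(out, v$affine)
}

#' Default pipeline parameters for [anonymize()]
#'
#' @param segmentation See [segment_params()].
#' @param smooth_iters,pre_smooth_sd Surface extraction controls.
#' @param registration_mode `"affine"` or `"affine+demons"`.
#' @param max_projection Landmark projection flag threshold, mm.
#' @param zero_exterior `"global"` or `"off"`.
#' @return Named list of parameters with class `run_config`.
#' @export
anonymize_params <- function(segmentation = segment_params(),
                             smooth_iters = 10, pre_smooth_sd = 1,
                             registration_mode = "affine",
                             max_projection = 15,
                             zero_exterior = "global") {
  structure(list(segmentation = segmentation, smooth_iters = smooth_iters,
                 pre_smooth_sd = pre_smooth_sd,
                 registration_mode = registration_mode,
                 max_projection = max_projection,
                 zero_exterior = zero_exterior),
            class = "run_config")
}

#' Geometry-preserving deidentification of one volume
#'
#' Full pipeline: canonicalize, watershed segmentation, skin and outer-skull
#' surface extraction, control-point placement (template registration +
#' transfer, or supplied subject-space points projected onto the skin),
#' shell construction, influence restriction, shell-distribution fit, and
#' the deface rule. Returns the deidentified volume and a QA report that
#' records the resolved configuration, seed and per-stage diagnostics so any
#' run can be reproduced from its report alone.
#'
#' @param v Input [volume_grid()].
#' @param template_or_points A `template_bundle` (automatic mode) or a
#'   subject-space [control_point_set()] (manual mode).
#' @param params See [anonymize_params()].
#' @param seed Integer seed for the noise fill.
#' @param qa_dir Optional directory for QA renders (orthogonal slice PNGs,
#'   skin surface snapshot) and the JSON report.
#' @return List with `volume` (defaced [volume_grid()]) and `report`.
#' @export
anonymize <- function(v, template_or_points, params = anonymize_params(),
                      seed = 1L, qa_dir = NULL) {
  stopifnot(inherits(v, "volume_grid"))
  stage <- "canonicalize"
  report <- list(seed = as.integer(seed), config = unclass(params),
                 stages = list())
  res <- tryCatch({
    vc <- to_canonical(v)

    stage <- "segment"
    seg <- segment_head(vc, params$segmentation)
    report$stages$segment <- seg$diagnostics

    stage <- "surfaces"
    outer_region <- fill_holes(seg$skull_mask)
    skin <- extract_surface(seg$head_mask, vc$affine, "skin",
                            params$smooth_iters, params$pre_smooth_sd)
    outer_skull <- extract_surface(outer_region, vc$affine, "outer_skull",
                                   params$smooth_iters, params$pre_smooth_sd)
    report$stages$surfaces <- list(
      skin = skin$diagnostics[c("n_vertices", "n_faces", "volume")],
      outer_skull = outer_skull$diagnostics[c("n_vertices", "n_faces",
                                              "volume")])

    stage <- "landmarks"
    if (inherits(template_or_points, "template_bundle")) {
      tpl <- template_or_points
      transform <- register(vc, to_canonical(tpl$volume),
                            mode = params$registration_mode)
      cps <- transfer_points(tpl$control_points, transform, skin,
                             params$max_projection)
      report$stages$landmarks <- list(
        mode = "template", template = tpl$name,
        metric_history = as.list(transform$metric_history),
        projection_mm = attr(cps, "projection")$distance)
    } else if (inherits(template_or_points, "control_point_set")) {
      cps0 <- template_or_points
      if (cps0$space != "subject")
        stop_gd("validation",
                "manual control points must be in subject space")
      proj <- mesh_closest_point(cps_matrix(cps0), skin)
      pts <- cps0$points
      pts$x <- proj$point[, 1]; pts$y <- proj$point[, 2]
      pts$z <- proj$point[, 3]
      cps <- control_point_set(pts, "subject", complete = FALSE)
      report$stages$landmarks <- list(mode = "manual",
                                      projection_mm = proj$distance)
    } else {
      stop_gd("validation",
              "template_or_points must be a template_bundle or control_point_set")
    }

    stage <- "shell"
    shell <- build_shell(vc, skin, outer_skull)
    shell <- apply_influence(shell, cps)
    report$stages$shell <- list(n_shell = sum(shell$shell),
                                n_active = sum(shell$active),
                                n_outside = sum(!shell$inside_skin))

    stage <- "fill"
    dist <- fit_distribution(vc, shell)
    report$stages$fill <- dist$summary[c("mean", "sd")]
    out <- deface(vc, shell, dist, skin, seed = seed,
                  zero_exterior = params$zero_exterior)

    list(volume = out, skin = skin, outer_skull = outer_skull, shell = shell,
         cps = cps, segmentation = seg)
  }, gd_error = function(e) {
    stop_gd(sub("^gd_(.*)_error$", "\\1", class(e)[1]),
            "anonymize failed at stage '%s': %s", stage, conditionMessage(e))
  })
  report$n_voxels_replaced <- sum(res$shell$active)
  report$n_voxels_zeroed <- sum(!res$shell$inside_skin)
  if (!is.null(qa_dir)) {
    dir.create(qa_dir, recursive = TRUE, showWarnings = FALSE)
    write_qa_renders(res$volume, res$skin, qa_dir)
    jsonlite::write_json(report, file.path(qa_dir, "qa_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
  }
  list(volume = res$volume, report = report, skin = res$skin,
       outer_skull = res$outer_skull, shell = res$shell,
       control_points = res$cps)
}

# QA renders: orthogonal mid-slice triptych + a simple depth-shaded skin
# snapshot, written as plain grayscale PNGs (headless-safe, no device)
write_qa_renders <- function(v, skin, qa_dir) {
  d <- dim(v$data)
  norm01 <- function(m) {
    r <- range(m)
    if (diff(r) == 0) return(m * 0)
    (m - r[1]) / diff(r)
  }
  slices <- list(
    axial = v$data[, , ceiling(d[3] / 2)],
    coronal = v$data[, ceiling(d[2] / 2), ],
    sagittal = v$data[ceiling(d[1] / 2), , ]
  )
  for (nm in names(slices)) {
    img <- t(norm01(slices[[nm]]))[rev(seq_len(ncol(slices[[nm]]))), ,
                                   drop = FALSE]
    png::writePNG(img, file.path(qa_dir, paste0("slice_", nm, ".png")))
  }
  # depth-shaded orthographic snapshot of the skin mesh from the front (+y)
  V <- skin$vertices
  nx <- 256L; nz <- 256L
  rx <- range(V[, 1]); rz <- range(V[, 3])
  ix <- pmin(nx, pmax(1L, as.integer(ceiling((V[, 1] - rx[1]) /
                                               diff(rx) * (nx - 1)) + 1L)))
  iz <- pmin(nz, pmax(1L, as.integer(ceiling((V[, 3] - rz[1]) /
                                               diff(rz) * (nz - 1)) + 1L)))
  depth <- matrix(-Inf, nz, nx)
  for (i in seq_len(nrow(V))) {
    r <- nz - iz[i] + 1L
    if (V[i, 2] > depth[r, ix[i]]) depth[r, ix[i]] <- V[i, 2]
  }
  depth[!is.finite(depth)] <- min(V[, 2])
  png::writePNG(norm01(depth), file.path(qa_dir, "skin_snapshot.png"))
  invisible(NULL)
}
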