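#' Specification of a synthetic layered head phantom
#'
#' The phantom is four strictly nested ellipsoids (brain, inner skull, outer
#' skull, skin) on a regular grid, with T1-like contrast: bright scalp and
#' brain, dark skull and dark background. The space between inner skull and
#' brain stands in for CSF and shares the skull's (dark) intensity, as CSF is
#' dark on T1. A nose and two ears are rendered as scalp-intensity
#' half-ellipsoids protruding from the skin so the face mask has nontrivial
#' geometry to remove. Gaussian noise is added voxelwise.
#'
#' Defaults emulate an adult head at 1.5 mm isotropic resolution on a 128^3
#' grid; tissue means are separated by at least five noise standard
#' deviations so segmentation has a contrast guarantee.
#'
#' @param shape Grid dimensions (3 positive integers).
#' @param voxel_size Voxel edge lengths in mm.
#' @param brain_radii,inner_skull_radii,outer_skull_radii,skin_radii
#'   Ellipsoid semi-axes in mm, strictly increasing from brain to skin.
#' @param tissue_means Named intensities for `background`, `scalp`, `skull`,
#'   `brain`; background must be the minimum.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param nose,ears Logical feature toggles.
#' @param nose_size,ear_size Protrusion extent in mm.
#' @param head_centre World position of the ellipsoid centre (mm). The
#'   default sits slightly posterior so the nose protrusion fits inside the
#'   field of view.
#' @param seed RNG seed for the noise field.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(shape = c(128L, 128L, 128L),
                         voxel_size = c(1.5, 1.5, 1.5),
                         brain_radii = c(55, 69, 50),
                         inner_skull_radii = c(59, 73, 54),
                         outer_skull_radii = c(64, 78, 59),
                         skin_radii = c(70, 85, 65),
                         tissue_means = c(background = 10, scalp = 100,
                                          skull = 40, brain = 130),
                         noise_sd = 5,
                         nose = TRUE, ears = TRUE,
                         nose_size = 15, ear_size = 12,
                         head_centre = c(0, -8, 0),
                         seed = 42L) {
  spec <- list(shape = as.integer(shape), voxel_size = as.numeric(voxel_size),
               brain_radii = brain_radii, inner_skull_radii = inner_skull_radii,
               outer_skull_radii = outer_skull_radii, skin_radii = skin_radii,
               tissue_means = tissue_means, noise_sd = noise_sd,
               nose = nose, ears = ears, nose_size = nose_size,
               ear_size = ear_size, head_centre = as.numeric(head_centre),
               seed = as.integer(seed))
  radii <- rbind(brain_radii, inner_skull_radii, outer_skull_radii, skin_radii)
  if (any(radii <= 0) || any(diff(radii) <= 0))
    stop_gd("validation",
            "phantom radii must be positive and strictly nested per axis")
  need <- c("background", "scalp", "skull", "brain")
  if (!all(need %in% names(tissue_means)))
    stop_gd("validation", "tissue_means must name %s",
            paste(need, collapse = ", "))
  if (tissue_means["background"] != min(tissue_means))
    stop_gd("validation", "background mean must be the minimum tissue mean")
  gaps <- diff(sort(unique(tissue_means)))
  if (noise_sd > 0 && min(gaps) < 5 * noise_sd)
    stop_gd("validation",
            "tissue means must differ by at least 5 x noise_sd (min gap %.1f)",
            min(gaps))
  # everything (skin plus feature protrusions) must fit the field of view
  # with at least one voxel to spare
  half_fov <- (shape - 1) / 2 * voxel_size
  ext_lo <- head_centre - skin_radii
  ext_hi <- head_centre + skin_radii
  if (nose) ext_hi[2] <- max(ext_hi[2], head_centre[2] + skin_radii[2] +
                               nose_size)
  if (ears) {
    ext_lo[1] <- ext_lo[1] - ear_size
    ext_hi[1] <- ext_hi[1] + ear_size
  }
  if (any(ext_lo < -half_fov + voxel_size) ||
      any(ext_hi > half_fov - voxel_size))
    stop_gd("validation",
            "head (including features) does not fit the field of view with a one-voxel margin")
  class(spec) <- "phantom_spec"
  spec
}

# affine centring the grid on the world origin, RAS axis-aligned
phantom_affine <- function(spec) {
  aff <- diag(4)
  diag(aff)[1:3] <- spec$voxel_size
  aff[1:3, 4] <- -(spec$shape - 1) / 2 * spec$voxel_size
  aff
}

# quadratic ellipsoid form: < 1 inside
ell_q <- function(x, y, z, centre, radii) {
  ((x - centre[1]) / radii[1])^2 + ((y - centre[2]) / radii[2])^2 +
    ((z - centre[3]) / radii[3])^2
}

# feature ellipsoids (world mm): nose protrudes anteriorly, ears laterally
phantom_features <- function(spec) {
  ctr <- spec$head_centre
  f <- list()
  if (spec$nose) {
    f$nose <- list(centre = ctr + c(0, spec$skin_radii[2], -10),
                   radii = c(10, spec$nose_size, 12))
  }
  if (spec$ears) {
    f$ear_L <- list(centre = ctr + c(-spec$skin_radii[1], 0, 0),
                    radii = c(spec$ear_size, 14, 14))
    f$ear_R <- list(centre = ctr + c(spec$skin_radii[1], 0, 0),
                    radii = c(spec$ear_size, 14, 14))
  }
  f
}

#' Generate a synthetic head phantom with analytic ground truth
#'
#' Builds the intensity volume (per-compartment mean plus seeded Gaussian
#' noise) and a ground-truth bundle: analytic surfaces for brain, inner
#' skull, outer skull and skin (isosurfaces of the exact quadratic fields,
#' in world mm), face/ear control points lying exactly on the skin surface,
#' a compartment label volume, and masks of the nose/ear feature voxels.
#'
#' Labels are: 0 background, 1 scalp (skin shell plus features), 2 skull,
#' 3 CSF gap, 4 brain.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (a [volume_grid()]) and `truth` (surfaces,
#'   landmarks, labels, feature masks, the spec).
#' @examples
#' ph <- make_phantom(phantom_spec(shape = c(48, 48, 48),
#'                                 voxel_size = c(4, 4, 4)))
#' ph$volume
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  aff <- phantom_affine(spec)
  idx <- index_grid(d)
  x <- idx[, 1] * spec$voxel_size[1] + aff[1, 4]
  y <- idx[, 2] * spec$voxel_size[2] + aff[2, 4]
  z <- idx[, 3] * spec$voxel_size[3] + aff[3, 4]
  ctr <- spec$head_centre

  q_brain <- ell_q(x, y, z, ctr, spec$brain_radii)
  q_inner <- ell_q(x, y, z, ctr, spec$inner_skull_radii)
  q_outer <- ell_q(x, y, z, ctr, spec$outer_skull_radii)
  q_skin  <- ell_q(x, y, z, ctr, spec$skin_radii)

  feats <- phantom_features(spec)
  q_feat <- rep(Inf, length(x))
  feat_masks <- list()
  for (nm in names(feats)) {
    qf <- ell_q(x, y, z, feats[[nm]]$centre, feats[[nm]]$radii)
    feat_masks[[nm]] <- array(qf < 1 & q_skin >= 1, dim = d)
    q_feat <- pmin(q_feat, qf)
  }

  labels <- integer(length(x))            # 0 background
  labels[q_skin < 1 | q_feat < 1] <- 1L   # scalp incl. features
  labels[q_outer < 1] <- 2L               # skull
  labels[q_inner < 1] <- 3L               # CSF gap (dark, like skull, on T1)
  labels[q_brain < 1] <- 4L               # brain
  labels <- array(labels, dim = d)

  means <- spec$tissue_means
  lut <- c(means["background"], means["scalp"], means["skull"],
           means["skull"], means["brain"])
  vol <- array(lut[as.vector(labels) + 1L], dim = d)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    vol <- vol + array(rnorm(prod(d), 0, spec$noise_sd), dim = d)
  }

  # analytic truth surfaces: isosurface at 0 of (1 - q), q exact on the
  # grid. The field is smooth, so no mesh smoothing is applied (smoothing
  # can fold the sharp nose/ear union creases into self-intersections).
  iso_mesh <- function(q, label) {
    field <- array(1 - q, dim = d)
    mt <- .mc_marching_tets(as.double(field), d, 0, -1e6)
    m <- trimesh(voxel_to_world(mt$vertices, aff), mt$faces + 1L, label)
    mesh_orient_outward(mesh_largest_component(m))
  }
  surfaces <- list(
    brain = iso_mesh(q_brain, "brain"),
    inner_skull = iso_mesh(q_inner, "inner_skull"),
    outer_skull = iso_mesh(q_outer, "outer_skull"),
    skin = iso_mesh(pmin(q_skin, q_feat), "skin")
  )

  landmarks <- phantom_landmarks(spec)
  truth <- list(surfaces = surfaces, landmarks = landmarks, labels = labels,
                feature_masks = feat_masks, spec = spec, affine = aff)
  list(volume = volume_grid(vol, aff), truth = truth)
}

# exact on-surface landmarks: nose tip + anterior face patch + ear apices
phantom_landmarks <- function(spec) {
  ctr <- spec$head_centre
  a <- spec$skin_radii[1]; b <- spec$skin_radii[2]; c_ <- spec$skin_radii[3]
  skin_y <- function(x, z) b * sqrt(pmax(0, 1 - (x / a)^2 - (z / c_)^2))
  pts <- list()
  if (spec$nose) {
    f <- phantom_features(spec)$nose
    pts[[length(pts) + 1]] <- c("face", f$centre[1],
                                f$centre[2] + f$radii[2], f$centre[3])
  }
  for (p in list(c(-25, 15), c(25, 15), c(-25, -30), c(25, -30), c(0, 30))) {
    pts[[length(pts) + 1]] <- c("face", ctr[1] + p[1],
                                ctr[2] + skin_y(p[1], p[2]), ctr[3] + p[2])
  }
  if (spec$ears) {
    f <- phantom_features(spec)
    pts[[length(pts) + 1]] <- c("ear_L", f$ear_L$centre[1] - f$ear_L$radii[1],
                                ctr[2], ctr[3])
    pts[[length(pts) + 1]] <- c("ear_R", f$ear_R$centre[1] + f$ear_R$radii[1],
                                ctr[2], ctr[3])
  } else {
    pts[[length(pts) + 1]] <- c("ear_L", ctr[1] - a, ctr[2], ctr[3])
    pts[[length(pts) + 1]] <- c("ear_R", ctr[1] + a, ctr[2], ctr[3])
  }
  df <- do.call(rbind, lapply(pts, function(p)
    data.frame(label = p[1], x = as.numeric(p[2]), y = as.numeric(p[3]),
               z = as.numeric(p[4]))))
  df$radius <- ifelse(df$label == "face", 25, 20)
  control_point_set(df, space = "subject")
}

#' Degrade a phantom the way template-cut or blurring defacers would
#'
#' Produces surrogate "competitor-defaced" volumes used to exercise the
#' evaluation metrics: `blank-face` zeroes the facial surface tissue within
#' the face control-point regions (background and scalp compartments, skin
#' included, as template-cut defacing does); `blur-face` replaces the same
#' region with a Gaussian-smoothed copy (the full region, all tissue, as
#' in-place blurring tools do).
#'
#' @param v Phantom [volume_grid()].
#' @param truth Phantom truth bundle from [make_phantom()].
#' @param mode `"blank-face"` or `"blur-face"`.
#' @param blur_sd Smoothing sd in voxels for `blur-face`.
#' @return A degraded [volume_grid()].
#' @export
degrade_like <- function(v, truth, mode = c("blank-face", "blur-face"),
                         blur_sd = 3) {
  mode <- match.arg(mode)
  cps <- truth$landmarks
  face <- cps$points[cps$points$label == "face", , drop = FALSE]
  d <- dim(v$data)
  idx <- index_grid(d)
  w <- voxel_to_world(idx, v$affine)
  in_face <- rep(FALSE, nrow(w))
  for (i in seq_len(nrow(face))) {
    dx <- w[, 1] - face$x[i]; dy <- w[, 2] - face$y[i]; dz <- w[, 3] - face$z[i]
    in_face <- in_face | (dx^2 + dy^2 + dz^2 <= face$radius[i]^2)
  }
  out <- v$data
  if (mode == "blank-face") {
    # template-cut defacing removes facial surface tissue, not the brain
    cut <- in_face & (as.vector(truth$labels) <= 1L)
    out[cut] <- 0
  } else {
    if (blur_sd > 0) {
      sm <- gauss_smooth(v$data, blur_sd)
      out[in_face] <- sm[in_face]
    }
  }
  volume_grid(out, v$affine)
}
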