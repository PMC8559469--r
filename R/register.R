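# Intensity-based registration: multi-resolution staged affine
# (translation -> rigid+scale -> full affine) on a correlation metric, with
# an optional diffeomorphic-demons-style refinement on a coarsened grid.
# The transform maps template world coordinates to subject world coordinates.

# block-downsample by an integer factor (Gaussian prefilter, then decimate)
downsample_volume <- function(v, factor) {
  if (factor <= 1) return(v)
  sm <- gauss_smooth(v$data, factor / 2)
  d <- dim(v$data)
  nd <- pmax(2L, as.integer(ceiling(d / factor)))
  M <- diag(4) * factor; M[4, 4] <- 1
  out <- .mc_resample(as.double(sm), d, M, nd, NA_real_)
  aff <- v$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] * factor
  volume_grid(array(out, dim = nd), aff)
}

# negative mean correlation, over intensity and gradient-magnitude channels,
# between subject level and template level mapped through affine A
# (template world -> subject world); the gradient channel sharpens
# sensitivity to edge/feature alignment that smooth interiors cannot provide
reg_level <- function(v) {
  list(data = v$data, grad = gradient_magnitude(v$data, voxel_sizes(v$affine)),
       affine = v$affine)
}

reg_metric <- function(A, subj, tmpl) {
  M <- solve(tmpl$affine) %*% solve(A) %*% subj$affine
  acc <- 0
  for (ch in c("data", "grad")) {
    res <- .mc_resample(as.double(tmpl[[ch]]), dim(tmpl[[ch]]), M,
                        dim(subj[[ch]]), NA_real_)
    ok <- is.finite(res) & is.finite(as.double(subj[[ch]]))
    if (sum(ok) < 100)
      stop_gd("geometry", "registration overlap is (near) empty")
    acc <- acc - suppressWarnings(cor(res[ok], as.double(subj[[ch]])[ok]))
  }
  acc / 2
}

rot3 <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx); cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Rz %*% Ry %*% Rx
}

intensity_centroid <- function(v) {
  w <- as.double(v$data) - min(v$data)
  idx <- index_grid(dim(v$data))
  colSums(voxel_to_world(idx, v$affine) * w) / sum(w)
}

#' Register a subject volume to a template
#'
#' Estimates the transform mapping template world coordinates to subject
#' world coordinates: intensity-centroid initialization, then multi-
#' resolution Nelder-Mead over translation, rigid+scale and full affine
#' stages under a correlation metric; `"affine+demons"` adds a
#' demons-style dense displacement refinement on a coarsened template grid.
#' If no stage improves the metric a convergence warning is raised and the
#' best-effort transform returned (downstream skin projection absorbs
#' residual error).
#'
#' @param subject,template Canonical [volume_grid()] objects.
#' @param mode `"affine"` or `"affine+demons"`.
#' @param levels Downsampling factors for the coarse and fine stages.
#' @param maxit Nelder-Mead iteration budget per stage.
#' @return A `spatial_transform`: `affine` (4x4), optional `displacement`
#'   (template-grid field, mm), `metric_history`, `mode`.
#' @export
register <- function(subject, template, mode = c("affine", "affine+demons"),
                     levels = c(4, 2), maxit = 150) {
  mode <- match.arg(mode)
  stopifnot(inherits(subject, "volume_grid"), inherits(template, "volume_grid"))
  s_coarse <- reg_level(downsample_volume(subject, levels[1]))
  t_coarse <- reg_level(downsample_volume(template, levels[1]))
  s_fine <- reg_level(downsample_volume(subject, levels[2]))
  t_fine <- reg_level(downsample_volume(template, levels[2]))

  centre <- intensity_centroid(subject)
  t0 <- centre - intensity_centroid(template)
  history <- c(initial = reg_metric(affine_from(diag(3), t0), s_coarse,
                                    t_coarse))

  # Nelder-Mead with restarts (restarting from the incumbent rebuilds the
  # simplex and escapes premature collapse)
  nm <- function(par, fn, parscale, restarts = 2) {
    o <- optim(par, fn, method = "Nelder-Mead",
               control = list(maxit = maxit, parscale = parscale))
    for (r in seq_len(restarts)) {
      o2 <- optim(o$par, fn, method = "Nelder-Mead",
                  control = list(maxit = maxit, parscale = parscale))
      if (o2$value < o$value) o <- o2 else break
    }
    o
  }

  # stage 1: translation
  f1 <- function(p) reg_metric(affine_from(diag(3), t0 + p), s_coarse, t_coarse)
  o1 <- nm(c(0, 0, 0), f1, rep(2, 3))
  t1 <- t0 + o1$par
  history["translation"] <- o1$value

  # stage 2: translation + anisotropic scale (no rotation). Committing to
  # scale first matters on near-ellipsoidal heads: scale and rotation trade
  # off in a shallow valley, and admitting rotation too early strands the
  # optimizer in a spuriously rotated local optimum.
  f2 <- function(p) {
    A <- affine_about(diag(exp(p[1:3])), centre, t1 + p[4:6])
    reg_metric(A, s_coarse, t_coarse)
  }
  o2 <- nm(rep(0, 6), f2, c(rep(0.05, 3), rep(2, 3)), restarts = 3)
  S2 <- diag(exp(o2$par[1:3]))
  t2 <- t1 + o2$par[4:6]
  history["translation_scale"] <- o2$value

  # stage 3: rigid + scale, rotations starting at zero
  f3 <- function(p) {
    Rm <- rot3(p[1], p[2], p[3]) %*% diag(exp(p[4:6]))
    A <- affine_about(Rm, centre, t2 + p[7:9])
    reg_metric(A, s_coarse, t_coarse)
  }
  o3 <- nm(c(0, 0, 0, log(diag(S2)), 0, 0, 0), f3,
           c(rep(0.02, 3), rep(0.02, 3), rep(1, 3)), restarts = 3)
  R3 <- rot3(o3$par[1], o3$par[2], o3$par[3]) %*% diag(exp(o3$par[4:6]))
  A2 <- affine_about(R3, centre, t2 + o3$par[7:9])
  history["rigid_scale"] <- o3$value

  # stage 4: full affine refinement at the finer level. Refine from both the
  # rigid+scale result and the rotation-free translation+scale result: the
  # coarse level can alias toward a spuriously rotated optimum that the fine
  # level rejects, so both basins are offered to the fine metric.
  A2_norot <- affine_about(S2, centre, t2)
  refine4 <- function(base) {
    f4 <- function(p) {
      P <- diag(3) + matrix(p[1:9], 3, 3)
      A <- base %*% affine_about(P, centre, p[10:12])
      reg_metric(A, s_fine, t_fine)
    }
    o4 <- nm(rep(0, 12), f4, c(rep(0.01, 9), rep(0.5, 3)), restarts = 3)
    P4 <- diag(3) + matrix(o4$par[1:9], 3, 3)
    list(A = base %*% affine_about(P4, centre, o4$par[10:12]),
         value = o4$value)
  }
  cand <- list(refine4(A2), refine4(A2_norot))
  r4 <- cand[[which.min(vapply(cand, `[[`, 0, "value"))]]
  A3 <- r4$A
  history["affine"] <- r4$value

  if (min(history[2:4]) >= history[1] - 1e-9)
    warn_gd("registration metric did not improve over any level; returning best-effort transform")

  # keep the affine-stage result only if it beats its own starting point at
  # the fine level (coarse- and fine-level metric values are not comparable)
  A <- if (r4$value <= reg_metric(A2, s_fine, t_fine)) A3 else A2

  displacement <- NULL
  if (mode == "affine+demons") {
    # both members identically filtered (downsampled) so residuals reflect
    # anatomy, not resolution mismatch
    displacement <- demons_refine(s_fine, t_fine, A)
    history["demons"] <- attr(displacement, "final_metric")
  }
  structure(list(affine = A, displacement = displacement,
                 metric_history = history, mode = mode),
            class = "spatial_transform")
}

affine_from <- function(R, t) {
  A <- diag(4); A[1:3, 1:3] <- R; A[1:3, 4] <- t
  A
}

# linear map about a centre point plus translation
affine_about <- function(R, centre, t) {
  A <- diag(4)
  A[1:3, 1:3] <- R
  A[1:3, 4] <- centre - R %*% centre + t
  A
}

# demons-style displacement u(x) on the (coarsened) template grid such that
# subject(A(x + u(x))) ~ template(x); returned field is in mm
demons_refine <- function(subject, t_fine, A, iters = 25, step = 0.8,
                          smooth_sd = 2) {
  d <- dim(t_fine$data)
  Tdat <- t_fine$data
  vs <- voxel_size(t_fine)
  gT <- list()
  for (ax in 1:3) {
    n <- d[ax]
    hi <- c(2:n, n); lo <- c(1, 1:(n - 1))
    ih <- switch(ax, list(hi, TRUE, TRUE), list(TRUE, hi, TRUE),
                 list(TRUE, TRUE, hi))
    il <- switch(ax, list(lo, TRUE, TRUE), list(TRUE, lo, TRUE),
                 list(TRUE, TRUE, lo))
    gT[[ax]] <- (do.call(`[`, c(list(Tdat), ih)) -
                 do.call(`[`, c(list(Tdat), il))) / (2 * vs[ax])
  }
  idxg <- index_grid(d)
  Xw <- voxel_to_world(idxg, t_fine$affine)   # template world coords
  u <- array(0, dim = c(d, 3))
  S_inv <- solve(subject$affine)
  scale2 <- stats::var(as.double(Tdat))
  final <- NA_real_
  for (it in seq_len(iters)) {
    P <- Xw + matrix(u, ncol = 3)
    Pw <- t(A %*% rbind(t(P), 1))[, 1:3, drop = FALSE]
    Pi <- t(S_inv %*% rbind(t(Pw), 1))[, 1:3, drop = FALSE]
    sd_ <- dim(subject$data)
    for (k in 1:3)   # clamp to the grid: edge fill values destabilize demons
      Pi[, k] <- pmin(pmax(Pi[, k], 0), sd_[k] - 1)
    warped <- .mc_interp(as.double(subject$data), sd_, Pi,
                         min(subject$data))
    e <- warped - as.double(Tdat)
    g2 <- as.double(gT[[1]])^2 + as.double(gT[[2]])^2 + as.double(gT[[3]])^2
    denom <- g2 + e^2 / max(scale2, 1e-12)
    denom[denom < 1e-9] <- Inf
    for (k in 1:3) {
      upd <- array(-step * e * as.double(gT[[k]]) / denom, dim = d)
      u[, , , k] <- gauss_smooth(u[, , , k] + upd, smooth_sd)
    }
    final <- -suppressWarnings(cor(warped, as.double(Tdat)))
  }
  structure(list(field = u, dims = d, affine = t_fine$affine),
            final_metric = final)
}
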