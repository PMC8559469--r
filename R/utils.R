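# Internal array helpers shared across modules. All masks are logical 3D
# arrays; all voxel indices are 0-based when they touch C++ or affines.

dims3 <- function(x) as.integer(dim(x))

# world coordinates of 0-based voxel indices (n x 3 matrix)
voxel_to_world <- function(idx, affine) {
  idx <- rbind(t(idx), 1)
  t(affine %*% idx)[, 1:3, drop = FALSE]
}

world_to_voxel <- function(pts, affine) {
  pts <- rbind(t(pts), 1)
  t(solve(affine) %*% pts)[, 1:3, drop = FALSE]
}

voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

as_mask_array <- function(v, dims) {
  array(v, dim = dims)
}

gauss_smooth <- function(arr, sd_vox) {
  if (sd_vox <= 0) return(arr)
  array(.mc_gauss_smooth(as.double(arr), dims3(arr), sd_vox), dim = dim(arr))
}

# largest 26-connected component of a mask
largest_component <- function(mask, connectivity = 26L) {
  labs <- .mc_label_components(as.logical(mask), dims3(mask),
                               as.integer(connectivity))
  if (all(labs == 0L)) return(array(FALSE, dim = dim(mask)))
  tab <- tabulate(labs)
  array(labs == which.max(tab), dim = dim(mask))
}

# fill interior cavities: background components not touching the border
fill_holes <- function(mask) {
  inv <- !mask
  labs <- array(.mc_label_components(as.logical(inv), dims3(mask), 6L),
                dim = dim(mask))
  d <- dim(mask)
  border_labels <- unique(c(
    labs[c(1, d[1]), , ], labs[, c(1, d[2]), ], labs[, , c(1, d[3])]
  ))
  border_labels <- setdiff(border_labels, 0L)
  mask | (inv & !(labs %in% border_labels))
}

dilate_mask <- function(mask, radius) {
  array(.mc_binary_morph(as.logical(mask), dims3(mask), radius, TRUE),
        dim = dim(mask))
}

erode_mask <- function(mask, radius) {
  array(.mc_binary_morph(as.logical(mask), dims3(mask), radius, FALSE),
        dim = dim(mask))
}

# gradient magnitude by central differences, scaled to world mm
gradient_magnitude <- function(arr, voxel_size) {
  d <- dim(arr)
  g2 <- array(0, dim = d)
  for (ax in 1:3) {
    n <- d[ax]
    hi <- c(2:n, n)
    lo <- c(1, 1:(n - 1))
    idx_hi <- switch(ax, list(hi, TRUE, TRUE), list(TRUE, hi, TRUE),
                     list(TRUE, TRUE, hi))
    idx_lo <- switch(ax, list(lo, TRUE, TRUE), list(TRUE, lo, TRUE),
                     list(TRUE, TRUE, lo))
    df <- (do.call(`[`, c(list(arr), idx_hi)) -
           do.call(`[`, c(list(arr), idx_lo))) / (2 * voxel_size[ax])
    g2 <- g2 + df^2
  }
  sqrt(g2)
}

# grid of 0-based voxel index coordinates, one row per voxel in linear order
index_grid <- function(d) {
  cbind(
    rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
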