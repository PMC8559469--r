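# Shared fixtures, generated in code and cached for the duration of the run.
# "small" phantoms keep unit tests fast; the acceptance tests use the
# default full-size spec.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# default head geometry on a coarse 64^3 grid (3.2 mm): ~5 s per build
small_spec <- function(...) {
  phantom_spec(shape = rep(64L, 3), voxel_size = rep(3.2, 3), ...)
}

small_phantom <- function() cached("small", make_phantom(small_spec()))

small_phantom_noisefree <- function() {
  cached("small0", make_phantom(small_spec(noise_sd = 0)))
}

default_phantom <- function() cached("default", make_phantom(phantom_spec()))

# analytic sphere mesh of radius r (mm) on a cubic grid
sphere_mesh <- function(r, n = 100L, vox = 1) {
  aff <- diag(4)
  aff[1:3, 4] <- -(n - 1) / 2 * vox
  idx <- geodeface:::index_grid(rep(n, 3L))
  w <- geodeface:::voxel_to_world(idx, aff)
  field <- array(r - sqrt(rowSums(w^2)), dim = rep(n, 3L))
  mt <- geodeface:::.mc_marching_tets(as.double(field), rep(as.integer(n), 3L),
                                      0, -1e6)
  m <- trimesh(geodeface:::voxel_to_world(mt$vertices, aff), mt$faces + 1L,
               "sphere")
  geodeface:::mesh_orient_outward(geodeface:::mesh_largest_component(m))
}

# skin + outer-skull surfaces and shell for a phantom (cached per key)
phantom_shell <- function(ph, key) {
  cached(paste0("shell_", key), {
    seg <- segment_head(ph$volume)
    skin <- extract_surface(seg$head_mask, ph$volume$affine, "skin")
    osk <- extract_surface(geodeface:::fill_holes(seg$skull_mask),
                           ph$volume$affine, "outer_skull")
    list(seg = seg, skin = skin, outer_skull = osk,
         shell = build_shell(ph$volume, skin, osk))
  })
}
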