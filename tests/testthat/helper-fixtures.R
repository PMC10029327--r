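# Shared fixtures, built lazily and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# digitized ball mask: |v - center| <= r, on an n^3 grid
ball_mask <- function(r, n, center = c(0, 0, 0), voxel_size_um = 1) {
  ax <- (seq_len(n) - 1) - (n - 1) / 2
  rho2 <- outer(outer((ax - center[1])^2, (ax - center[2])^2, `+`),
                (ax - center[3])^2, `+`)
  binary_mask(array(rho2 <= r^2, c(n, n, n)), voxel_size_um)
}

# axial slab mask: z-slices z0..z1 (1-based), n^3 grid
slab_mask <- function(z0, z1, n, voxel_size_um = 1) {
  m <- array(FALSE, c(n, n, n))
  m[, , z0:z1] <- TRUE
  binary_mask(m, voxel_size_um)
}

# z-aligned cylinder through the full grid
cylinder_mask <- function(r, n, voxel_size_um = 1) {
  ax <- (seq_len(n) - 1) - (n - 1) / 2
  rho2 <- outer(ax^2, ax^2, `+`)
  binary_mask(array(rep(rho2 <= r^2, times = n), c(n, n, n)), voxel_size_um)
}

# small fast phantom for module-level tests (overridable defaults)
small_phantom_spec <- function(seed = 7, ...) {
  args <- list(grid_shape = c(96L, 96L, 64L), nerve_radius_um = 14,
               dura_radius_um = 34, trabecula_count = 5L,
               trabecula_radius_um_range = c(2.5, 3.5),
               septum_count = 0L, artifact_count = 2L,
               rng_seed = seed)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

# small truth-mask segment sets (fast separation/report checks)
small_truth_fixture <- function(count, seed = 7) {
  fixture(sprintf("smalltruth_n%d", count), function() {
    spec <- small_phantom_spec(seed, trabecula_count = count,
                               artifact_count = 0L)
    ph <- generate_phantom(spec)
    list(truth = ph$truth, segs = segments_from_truth(ph$truth))
  })
}

# full-pipeline fixture at a fixed trabecular radius (study conditions of
# the parameter-recovery check); cached per radius
pipeline_fixture <- function(r, seed = 11) {
  fixture(sprintf("pipeline_r%g", r), function() {
    spec <- phantom_spec(trabecula_radius_um_range = c(r, r),
                         trabecula_count = 10L, septum_count = 0L,
                         rng_seed = seed)
    ph <- generate_phantom(spec)
    enh <- enhance_volume(ph$volume)
    raw <- threshold_segment(enh)
    segs <- build_segments(raw, reference = ph$volume)
    list(phantom = ph, enhanced = enh, raw = raw, segs = segs)
  })
}

# truth-mask segment sets of trabecula-count variants (shared seed)
truth_segs_fixture <- function(count, seed = 21) {
  fixture(sprintf("truthsegs_n%d", count), function() {
    spec <- phantom_spec(trabecula_count = count, septum_count = 0L,
                         artifact_count = 0L, rng_seed = seed)
    ph <- generate_phantom(spec)
    list(truth = ph$truth, segs = segments_from_truth(ph$truth))
  })
}
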