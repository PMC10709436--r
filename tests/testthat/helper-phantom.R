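# Shared coarse phantom fixtures (built once per test run; 1.5 mm voxels keep
# the suite fast while the acceptance tests use the half-resolution 0.9 mm
# configuration).

coarse_spec <- function(...) {
  phantom_spec(voxel_spacing = 1.5, fov_mm = c(114, 114, 288), ...)
}

# memoised noise-free coarse rendering and its segmentation products
.fixtures <- new.env()

coarse_volume <- function() {
  if (is.null(.fixtures$vol)) {
    spec <- coarse_spec()
    geom <- build_geometry(spec)
    .fixtures$spec <- spec
    .fixtures$geom <- geom
    .fixtures$vol <- voxelize(geom, spec, noise_seed = 7L)
    attr(.fixtures$vol, "seed_points") <-
      ctmotion:::phantom_seed_points(geom)
  }
  .fixtures$vol
}

coarse_geometry <- function() {
  coarse_volume()
  .fixtures$geom
}

coarse_masks <- function() {
  if (is.null(.fixtures$masks)) {
    vol <- coarse_volume()
    seeds <- phantom_seeds(coarse_geometry())
    .fixtures$masks <- list(
      implant = region_grow(vol, seeds$implant, 3500),
      cortex = region_grow(vol, seeds$cortex, 1600))
  }
  .fixtures$masks
}

# memoised half-resolution (0.9 mm) noise-free rendering for the accuracy
# and acceptance tests
half_res_volume <- function() {
  if (is.null(.fixtures$hr_vol)) {
    spec <- phantom_spec(voxel_spacing = 0.9)
    geom <- build_geometry(spec)
    .fixtures$hr_spec <- spec
    .fixtures$hr_geom <- geom
    .fixtures$hr_vol <- voxelize(geom, spec, noise_seed = 42L)
    attr(.fixtures$hr_vol, "seed_points") <-
      ctmotion:::phantom_seed_points(geom)
  }
  .fixtures$hr_vol
}

half_res_geometry <- function() {
  half_res_volume()
  .fixtures$hr_geom
}

phantom_seeds <- function(geometry, pose = rigid_identity())
  ctmotion:::phantom_seed_points(geometry, pose)

random_rigid <- function(t_range = 10, r_range = 30)
  params_to_matrix(c(stats::runif(3, -t_range, t_range),
                     stats::runif(3, -r_range, r_range)))

expect_transform_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(unclass(a) - unclass(b))), tol)
}
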