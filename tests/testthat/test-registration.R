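# handcrafted 5-point double contour over a linear intensity field f = x
toy_contour <- function(ref_outer, ref_inner) {
  base <- cbind(c(1, 2, 3, 4, 5) * 2, 5, 5)
  structure(list(base_points = base,
                 outer_points = base, inner_points = base,
                 reference_grays = c(ref_outer, ref_inner), offset = 0.3),
            class = "double_contour")
}

linear_x_volume <- function() {
  co <- as.matrix(expand.grid(x = 0:15, y = 0:15, z = 0:15))
  ct_volume(array(co[, 1] * 1.0, c(16, 16, 16)), spacing = 1)
}

test_that("correlation metric matches closed-form toy values", {
  v <- linear_x_volume()  # sampled grays at the contour: 2,4,6,8,10
  expect_equal(as.numeric(correlation_metric(toy_contour(1:5, 1:5), v)), 1,
               tolerance = 1e-12)
  expect_equal(as.numeric(correlation_metric(toy_contour(5:1, 5:1), v)), -1,
               tolerance = 1e-12)
})

test_that("self-correlation is 1 and invariant to affine intensity maps", {
  vol <- coarse_volume()
  mesh <- extract_mesh_volume(vol, coarse_masks()$implant)
  ct <- build_double_contour(vol, mesh, max_points = 800)
  expect_equal(as.numeric(correlation_metric(ct, vol)), 1, tolerance = 1e-12)
  rescaled <- ct_volume(2.5 * vol$data + 100, vol$spacing, vol$origin)
  expect_equal(as.numeric(correlation_metric(ct, rescaled)), 1,
               tolerance = 1e-12)
})

test_that("degenerate metric inputs raise errors", {
  flat <- ct_volume(array(7.0, c(16, 16, 16)), spacing = 1)
  expect_error(correlation_metric(toy_contour(1:5, 1:5), flat), "variance")
  tiny <- toy_contour(1:5, 1:5)
  shift <- params_to_matrix(c(500, 0, 0, 0, 0, 0))
  expect_error(correlation_metric(tiny, linear_x_volume(), shift), "valid")
})

test_that("registering a volume onto itself recovers the identity", {
  vol <- coarse_volume()
  mesh <- extract_mesh_volume(vol, coarse_masks()$cortex)
  ct <- build_double_contour(vol, mesh, max_points = 1500)
  rr <- register(ct, vol)
  expect_lt(translation_norm(rr$transform), 0.01)
  expect_lt(rotation_angle(rr$transform), 0.01)
  expect_gt(rr$metric_value, 0.9999)
  expect_true(rr$converged)
})

test_that("a known rigid re-posing is recovered to sub-voxel accuracy", {
  vol <- coarse_volume()
  geom <- coarse_geometry()
  spec <- .fixtures$spec
  mesh <- extract_mesh_volume(vol, coarse_masks()$cortex)
  ct <- build_double_contour(vol, mesh, max_points = 1500)
  Tstar <- params_to_matrix(c(1.5, -1, 2, 1, -1.5, 0.8))
  v2 <- voxelize(geom, spec, pose = Tstar, noise_seed = 8L)
  rr <- register(ct, v2, control = registration_control(seed = 2))
  err <- rigid_compose(rigid_invert(Tstar), rr$transform)
  expect_lt(translation_norm(err), 0.1 * spec$voxel_spacing)
  expect_lt(rotation_angle(err), 0.1)
})

test_that("forward and backward registrations compose to the identity", {
  vol <- coarse_volume()
  geom <- coarse_geometry()
  spec <- .fixtures$spec
  Tstar <- params_to_matrix(c(-2, 1, 1.5, -1, 0.8, 1.2))
  v2 <- voxelize(geom, spec, pose = Tstar, noise_seed = 9L)
  ct1 <- build_double_contour(
    vol, extract_mesh_volume(vol, coarse_masks()$cortex), max_points = 1200)
  seeds2 <- phantom_seeds(geom, Tstar)
  m2 <- region_grow(v2, seeds2$cortex, 1600)
  ct2 <- build_double_contour(v2, extract_mesh_volume(v2, m2),
                              max_points = 1200)
  fwd <- register(ct1, v2, control = registration_control(seed = 3))
  bwd <- register(ct2, vol, control = registration_control(seed = 3))
  loopM <- rigid_compose(bwd$transform, fwd$transform)
  expect_lt(translation_norm(loopM), 2 * 0.1 * spec$voxel_spacing)
  expect_lt(rotation_angle(loopM), 2 * 0.1)
})

test_that("recovered-pose error grows with image noise", {
  geom <- coarse_geometry()
  Tstar <- params_to_matrix(c(1, -2, 1, 0.5, 1, -0.5))
  noise_levels <- c(0, 300, 900)
  errs <- vapply(noise_levels, function(ns) {
    spec <- coarse_spec(noise_sd = ns)
    v1 <- voxelize(geom, spec, noise_seed = 21L)
    v2 <- voxelize(geom, spec, pose = Tstar, noise_seed = 22L)
    seeds <- phantom_seeds(geom)
    m <- region_grow(v1, seeds$cortex, 1600)
    ct <- build_double_contour(v1, extract_mesh_volume(v1, m),
                               max_points = 1200)
    rr <- register(ct, v2, control = registration_control(seed = 4))
    err <- rigid_compose(rigid_invert(Tstar), rr$transform)
    translation_norm(err) + rotation_angle(err)
  }, numeric(1))
  expect_gt(cor(noise_levels, errs, method = "spearman"), 0)
  expect_gt(errs[3], errs[1])
})

test_that("coarse pre-alignment recovers large specimen repositioning", {
  vol <- coarse_volume()
  geom <- coarse_geometry()
  spec <- .fixtures$spec
  Tbig <- params_to_matrix(c(12, -10, 15, 6, -8, 7))
  v2 <- voxelize(geom, spec, pose = Tbig, noise_seed = 10L)
  ct <- build_double_contour(
    vol, extract_mesh_volume(vol, coarse_masks()$cortex), max_points = 1500)
  init <- coarse_prealign(ct, v2, 1600, source_volume = vol)
  ierr <- rigid_compose(rigid_invert(Tbig), init)
  expect_lt(translation_norm(ierr), 3)
  expect_lt(rotation_angle(ierr), 6)
  rr <- register(ct, v2, init = init, control = registration_control(seed = 5))
  err <- rigid_compose(rigid_invert(Tbig), rr$transform)
  expect_lt(translation_norm(err), 0.1 * spec$voxel_spacing)
  expect_lt(rotation_angle(err), 0.15)
})

test_that("hopeless initial poses are rejected", {
  vol <- coarse_volume()
  ct <- build_double_contour(
    vol, extract_mesh_volume(vol, coarse_masks()$implant), max_points = 500)
  far <- params_to_matrix(c(300, 300, 300, 0, 0, 0))
  expect_error(register(ct, vol, init = far), "50%")
})
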