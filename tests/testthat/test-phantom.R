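# small, fast configuration for structural tests
tiny_spec <- function(...) {
  phantom_spec(voxel_spacing = 3, fov_mm = c(90, 90, 240),
               bone_length = 150, ...)
}

test_that("spec invariants are enforced", {
  expect_s3_class(phantom_spec(), "phantom_spec")
  expect_error(phantom_spec(voxel_spacing = 0), "positive")
  expect_error(phantom_spec(intensity_cortex = 100), "intensities")
  expect_error(phantom_spec(plateau_halfwidth_ml = 5,
                            plateau_halfwidth_ap = 9), "ML halfwidth")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
})

test_that("point classification matches the constructed solids", {
  geom <- build_geometry(phantom_spec())
  spec <- geom$spec
  z1 <- spec$bone_length / 2
  # axis mid-shaft -> trabecular; mid-cortex -> cortex; stem -> implant
  r_mid <- spec$shaft_radius - spec$cortical_thickness / 2
  codes <- classify_points(geom, rbind(
    c(0, 0, 0),
    c(r_mid, 0, 0),
    c(0, 0, z1 - 5),
    c(0, 0, z1 + spec$plateau_thickness / 2),
    c(50, 50, 140)))
  expect_equal(codes, c(1L, 2L, 4L, 4L, 0L))
  # priority: the stem overrides the trabecular interior it sits in
  expect_equal(classify_points(geom, c(spec$stem_radius / 2, 0, z1 - 10)), 4L)
})

test_that("bending is exact per zone and mirrors with the sign", {
  spec <- tiny_spec()
  geom <- build_geometry(spec)
  g0 <- apply_bending(geom, 0)
  pts <- matrix(c(0, 0, 60, 3, -2, 0, 0, 0, -70), ncol = 3, byrow = TRUE)
  expect_equal(ctmotion:::bend_forward(g0, pts), pts, tolerance = 1e-12)

  th <- 2
  g <- apply_bending(geom, th)
  zd <- geom$z_distal_top; zp <- geom$z_prox_bottom
  # distal zone rigid (unmoved)
  expect_equal(drop(ctmotion:::bend_forward(g, c(4, 1, zd - 10))),
               c(4, 1, zd - 10), tolerance = 1e-12)
  # proximal end: exact rotation about the y-parallel axis through (0,0,zd)
  ptop <- c(0, 0, spec$bone_length / 2)
  a <- th * pi / 180
  expect_equal(drop(ctmotion:::bend_forward(g, ptop)),
               c(sin(a) * (ptop[3] - zd), 0, zd + cos(a) * (ptop[3] - zd)),
               tolerance = 1e-9)
  # mid-ramp point: closed-form rotation by the ramped angle
  zm <- (zd + zp) / 2
  am <- (th / 2) * pi / 180
  expect_equal(drop(ctmotion:::bend_forward(g, c(0, 5, zm))),
               c(sin(am) * (zm - zd), 5, zd + cos(am) * (zm - zd)),
               tolerance = 1e-9)
  # sign flip mirrors the lateral offset
  gm <- apply_bending(geom, -th)
  expect_equal(ctmotion:::bend_forward(gm, ptop)[1],
               -ctmotion:::bend_forward(g, ptop)[1], tolerance = 1e-12)
  # bend inverse undoes the forward map (fixed-point iteration)
  set.seed(21)
  q <- ctmotion:::bend_forward(g, cbind(runif(50, -8, 8), runif(50, -8, 8),
                                        runif(50, -70, 70)))
  expect_equal(ctmotion:::bend_forward(g, ctmotion:::bend_inverse(g, q)), q,
               tolerance = 1e-6)
  expect_error(apply_bending(geom, 11), "small-deformation")
})

test_that("voxelization reproduces class intensities and noise statistics", {
  spec <- tiny_spec(psf_sigma_voxels = 0)
  geom <- build_geometry(spec)
  vol <- voxelize(geom, spec)
  # deep cortex voxel carries the cortex intensity exactly (no noise, no PSF)
  idx <- round(world_to_index(vol, c(spec$shaft_radius -
                                       spec$cortical_thickness / 2, 0, 3))) + 1
  expect_equal(vol$data[idx[1], idx[2], idx[3]], spec$intensity_cortex)

  # Gaussian noise: background block mean within 4 sigma/sqrt(n)
  specn <- tiny_spec(noise_sd = 200, seed = 5L)
  voln <- voxelize(build_geometry(specn), specn)
  blk <- voln$data[1:10, 1:10, 1:10]
  expect_lt(abs(mean(blk) - specn$intensity_background),
            4 * 200 / sqrt(1000))
  # determinism: same seed gives bit-identical volumes
  voln2 <- voxelize(build_geometry(specn), specn)
  expect_identical(voln$data, voln2$data)
  # voxel budget guard
  expect_error(voxelize(geom, tiny_spec(max_voxels = 1000)), "max_voxels")
})

test_that("load-pair ground truth follows from the generating geometry", {
  spec <- tiny_spec()
  poses <- list(valgus = params_to_matrix(c(5, -3, 8, 4, -6, 3)),
                varus = params_to_matrix(c(-7, 2, -4, -5, 8, -2)))
  # no bend, fixed implant, arbitrary repositioning: all truths identity
  lp0 <- generate_load_pair(spec, 0, global_poses = poses)
  expect_transform_equal(lp0$truth$true_M_prox_distal, diag(4), 1e-9)
  expect_transform_equal(lp0$truth$true_M_implant_prox, diag(4), 1e-9)
  expect_transform_equal(lp0$truth$true_M_implant_whole, diag(4), 1e-9)
  expect_true(lp0$truth$implant_whole_exact)

  # loose implant: 0.5 mm x-translation survives conjugation in magnitude
  mimp <- params_to_matrix(c(0.5, 0, 0, 0, 0, 0))
  lp1 <- generate_load_pair(spec, 0, implant_motion = mimp,
                            global_poses = poses)
  expect_equal(translation_norm(lp1$truth$true_M_implant_prox), 0.5,
               tolerance = 1e-9)

  # per-state bend 0.32 deg -> net prox-vs-distal rotation 0.64 deg
  lp2 <- generate_load_pair(spec, 0.32, global_poses = poses)
  expect_equal(rotation_angle(lp2$truth$true_M_prox_distal), 0.64,
               tolerance = 1e-9)
  expect_false(lp2$truth$implant_whole_exact)
})

test_that("ground-truth invariants depend only on bend and implant motion", {
  # the global-frame matrices are conjugates across repositionings, so the
  # rotation angle is pose-invariant always, and the translation magnitude
  # is pose-invariant for pure-translation implant motion
  spec <- tiny_spec()
  mimp_rot <- params_to_matrix(c(0.3, -0.2, 0.1, 0.4, 0, -0.3))
  mimp_t <- params_to_matrix(c(0.3, -0.2, 0.1, 0, 0, 0))
  truths <- lapply(1:2, function(i) {
    set.seed(100 + i)
    poses <- list(valgus = random_rigid(15, 8), varus = random_rigid(15, 8))
    list(rot = generate_load_pair(spec, 0.4, implant_motion = mimp_rot,
                                  global_poses = poses)$truth,
         tr = generate_load_pair(spec, 0.4, implant_motion = mimp_t,
                                 global_poses = poses)$truth)
  })
  expect_equal(rotation_angle(truths[[1]]$rot$true_M_prox_distal),
               rotation_angle(truths[[2]]$rot$true_M_prox_distal),
               tolerance = 1e-9)
  expect_equal(rotation_angle(truths[[1]]$rot$true_M_prox_distal), 0.8,
               tolerance = 1e-9)
  expect_equal(rotation_angle(truths[[1]]$rot$true_M_implant_prox),
               rotation_angle(truths[[2]]$rot$true_M_implant_prox),
               tolerance = 1e-9)
  expect_equal(translation_norm(truths[[1]]$tr$true_M_implant_prox),
               translation_norm(truths[[2]]$tr$true_M_implant_prox),
               tolerance = 1e-9)
  expect_equal(translation_norm(truths[[1]]$tr$true_M_implant_prox),
               sqrt(sum(c(0.3, 0.2, 0.1)^2)), tolerance = 1e-9)
})

test_that("repeat scans reproduce the phantom under random poses", {
  spec <- tiny_spec()
  rs <- generate_repeat_scans(spec, n = 10, seed = 3)
  expect_length(rs$volumes, 10)
  expect_length(rs$poses, 10)
  # jitter- and noise-free repeats are identical volumes
  rs0 <- generate_repeat_scans(spec, n = 2,
                               pose_jitter = list(translation = 0,
                                                  rotation = 0), seed = 3)
  expect_identical(rs0$volumes[[1]]$data, rs0$volumes[[2]]$data)
  expect_error(generate_repeat_scans(spec, n = 1), "at least 2")
})

test_that("marching-cubes surfaces agree with the analytic meshes", {
  # geometric fidelity of voxelize + region_grow + extract_mesh: no scanner
  # PSF (pure partial-volume antialiasing), objects well separated, and
  # thresholds at the partial-volume midpoints
  spec <- phantom_spec(voxel_spacing = 1.2, psf_sigma_voxels = 0,
                       plateau_halfwidth_ml = 10, plateau_halfwidth_ap = 8)
  geom <- build_geometry(spec)
  vol <- voxelize(geom, spec)
  seeds <- phantom_seeds(geom)
  vx <- spec$voxel_spacing
  # surface-to-surface Hausdorff: vertex distances, with offenders refined
  # to point-to-triangle distances (vertex sampling alone overestimates)
  hausdorff_surf <- function(a, b) {
    one_way <- function(m1, m2) {
      d <- surface_distance(m1, m2)
      off <- d > 0.8 * vx
      if (any(off)) {
        sub <- surface_mesh(m1$vertices[off, , drop = FALSE],
                            matrix(integer(0), ncol = 3),
                            normals = m1$normals[off, , drop = FALSE])
        d[off] <- surface_distance(sub, m2, to_triangles = TRUE)
      }
      max(d)
    }
    max(one_way(a, b), one_way(b, a))
  }
  imp_thr <- (spec$intensity_trabecular + spec$intensity_implant) / 2
  imp <- region_grow(vol, seeds$implant, imp_thr)
  expect_lt(hausdorff_surf(extract_mesh_volume(vol, imp),
                           geom$meshes$implant), vx)
  cor_thr <- (spec$intensity_trabecular + spec$intensity_cortex) / 2
  cor_m <- region_grow(vol, seeds$cortex, cor_thr)
  expect_lt(hausdorff_surf(extract_mesh_volume(vol, cor_m),
                           geom$meshes$cortex), vx)
})
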