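test_that("region growing selects exactly the seeded connected component", {
  # two disjoint bright blobs: only the seeded one is returned
  a <- array(0, c(20, 20, 20))
  a[3:6, 3:6, 3:6] <- 2000
  a[14:17, 14:17, 14:17] <- 2000
  v <- ct_volume(a, spacing = 1)
  m <- region_grow(v, c(3, 3, 3), 1000)
  expect_equal(sum(m), 64)
  expect_true(all(which(m, arr.ind = TRUE) <= 6))
  expect_error(region_grow(v, c(9, 9, 9), 1000), "below the threshold")
  expect_error(region_grow(v, c(100, 0, 0), 1000), "outside")
})

test_that("threshold masks equal the phantom class masks without blur", {
  # no PSF, no supersampling: voxel values are exact class intensities
  spec <- phantom_spec(voxel_spacing = 1.5, fov_mm = c(114, 114, 288),
                       psf_sigma_voxels = 0)
  geom <- build_geometry(spec)
  vol <- voxelize(geom, spec, supersample = 1)
  seeds <- phantom_seeds(geom)
  dims <- dim(vol$data)
  grid <- index_to_world(vol, as.matrix(expand.grid(
    seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])) - 1))
  codes <- array(classify_points(geom, grid), dims)

  m_imp <- region_grow(vol, seeds$implant, 3500)
  expect_identical(unname(m_imp), codes == 4L)
  m_cor <- region_grow(vol, seeds$cortex, 1600)
  expect_identical(unname(m_cor), codes == 2L)   # shell, interior excluded
})

test_that("level-set refinement is near-identity on edge-aligned masks", {
  vol <- coarse_volume()
  masks <- coarse_masks()
  expect_identical(levelset_refine(vol, masks$implant, iterations = 0),
                   masks$implant)
  ref <- levelset_refine(vol, masks$implant, iterations = 10)
  expect_gt(dice(ref, masks$implant), 0.9)
  expect_error(levelset_refine(vol, array(FALSE, dim(vol$data))), "empty")
})

test_that("level-set refinement recovers an under-grown boundary", {
  vol <- half_res_volume()
  geom <- half_res_geometry()
  seeds <- phantom_seeds(geom)
  dims <- dim(vol$data)
  grid <- index_to_world(vol, as.matrix(expand.grid(
    seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])) - 1))
  truth <- array(classify_points(geom, grid) == 4L, dims)
  # threshold far above the edge midpoint under-grows the implant
  under <- region_grow(vol, seeds$implant, 5800)
  d0 <- dice(under, truth)
  ref <- levelset_refine(vol, under, iterations = 30, min_dice = 0.5)
  expect_gt(dice(ref, truth), d0)
  expect_gt(dice(ref, truth), 0.9)
})

test_that("segmentation pipeline recovers class masks with high Dice", {
  vol <- half_res_volume()
  geom <- half_res_geometry()
  seeds <- phantom_seeds(geom)
  dims <- dim(vol$data)
  grid <- index_to_world(vol, as.matrix(expand.grid(
    seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])) - 1))
  codes <- array(classify_points(geom, grid), dims)
  m_imp <- levelset_refine(vol, region_grow(vol, seeds$implant, 3500),
                           iterations = 10)
  m_cor <- levelset_refine(vol, region_grow(vol, seeds$cortex, 1600),
                           iterations = 10)
  expect_gt(dice(m_imp, codes == 4L), 0.95)
  expect_gt(dice(m_cor, codes == 2L), 0.95)
})

test_that("meshing a voxelized sphere recovers its radius", {
  r <- 10; sp <- 1
  co <- as.matrix(expand.grid(x = 1:25, y = 1:25, z = 1:25)) - 13
  mask <- array(sqrt(rowSums(co^2)) <= r, c(25, 25, 25))
  mesh <- extract_mesh(mask, spacing = sp, origin = -12 * c(1, 1, 1))
  rad <- sqrt(rowSums(mesh$vertices^2))
  expect_true(all(abs(rad - r) <= 0.5 * sp + 0.5))  # half-voxel + binary step
  expect_equal(euler_characteristic(mesh), 2)       # closed genus-0 surface
})

test_that("a single voxel meshes to a small closed surface", {
  mask <- array(FALSE, c(5, 5, 5)); mask[3, 3, 3] <- TRUE
  mesh <- extract_mesh(mask, spacing = 1)
  expect_equal(euler_characteristic(mesh), 2)
  expect_error(extract_mesh(array(FALSE, c(4, 4, 4))), "empty")
})

test_that("mesh normals point outward from bright objects", {
  masks <- coarse_masks()
  vol <- coarse_volume()
  mesh <- extract_mesh_volume(vol, masks$implant)
  ctr <- colMeans(mesh$vertices)
  # for the convex-ish plateau top, normals align with (vertex - centroid)
  top <- mesh$vertices[, 3] > max(mesh$vertices[, 3]) - 1
  outward <- rowSums(mesh$normals[top, ] *
                       sweep(mesh$vertices[top, ], 2, ctr))
  expect_gt(mean(outward > 0), 0.95)
})

test_that("double contours store exact offsets and ordered grays", {
  vol <- coarse_volume()
  mesh <- extract_mesh_volume(vol, coarse_masks()$implant)
  dc <- build_double_contour(vol, mesh, max_points = 500)
  expect_s3_class(dc, "double_contour")
  expect_equal(sqrt(rowSums((dc$outer_points - dc$base_points)^2)),
               rep(0.3, nrow(dc$base_points)), tolerance = 1e-6)
  expect_equal(sqrt(rowSums((dc$inner_points - dc$base_points)^2)),
               rep(0.3, nrow(dc$base_points)), tolerance = 1e-6)
  expect_length(dc$reference_grays, 2 * nrow(dc$base_points))
  expect_true(all(is.finite(dc$reference_grays)))
})

test_that("contour grays respect field structure", {
  # radial gradient: outer shell samples exceed inner shell samples
  co <- as.matrix(expand.grid(x = 1:41, y = 1:41, z = 1:41)) - 21
  v <- ct_volume(array(sqrt(rowSums(co^2)), c(41, 41, 41)),
                 spacing = 1, origin = -20 * c(1, 1, 1))
  mask <- array(sqrt(rowSums(co^2)) <= 12, c(41, 41, 41))
  mesh <- extract_mesh(mask, spacing = 1, origin = -20 * c(1, 1, 1))
  dc <- build_double_contour(v, mesh)
  n <- nrow(dc$base_points)
  expect_true(all(dc$reference_grays[1:n] > dc$reference_grays[n + 1:n]))

  # linear field: mean of the two shells equals the base-point value
  ab <- c(0.5, -0.25, 1)
  vlin <- ct_volume(array(co %*% ab + 50, c(41, 41, 41)),
                    spacing = 1, origin = -20 * c(1, 1, 1))
  dcl <- build_double_contour(vlin, mesh)
  base_vals <- trilinear_sample(vlin, dcl$base_points)$values
  expect_equal((dcl$reference_grays[1:n] + dcl$reference_grays[n + 1:n]) / 2,
               base_vals, tolerance = 1e-9)

  # meshes poking far outside the volume are rejected
  big <- transform_mesh(mesh, params_to_matrix(c(30, 0, 0, 0, 0, 0)))
  expect_error(build_double_contour(v, big), "outside")
})

test_that("clipping a straight tube yields the stated end segments", {
  th <- seq(0, 2 * pi, length.out = 49)[-49]
  zs <- seq(0, 300, by = 2)
  verts <- do.call(rbind, lapply(zs, function(z)
    cbind(10 * cos(th), 10 * sin(th), z)))
  id <- function(i, t) (i - 1) * 48 + t
  tn <- c(2:48, 1)
  faces <- do.call(rbind, lapply(seq_len(length(zs) - 1), function(i)
    rbind(cbind(id(i, 1:48), id(i, tn), id(i + 1, tn)),
          cbind(id(i, 1:48), id(i + 1, tn), id(i + 1, 1:48)))))
  tube <- surface_mesh(verts, faces)

  cl <- clip_segments(tube, fraction = 0.2)
  expect_equal(diff(range(cl$proximal$vertices[, 3])), 60, tolerance = 2)
  expect_equal(diff(range(cl$distal$vertices[, 3])), 60, tolerance = 2)
  expect_equal(cl$length, 300, tolerance = 1e-6)
  expect_identical(cl$whole$vertices, tube$vertices)

  # fraction 0.5 partitions the tube (no gap, no overlap beyond the plane)
  cl5 <- clip_segments(tube, fraction = 0.5)
  expect_equal(nrow(cl5$proximal$vertices) + nrow(cl5$distal$vertices),
               nrow(tube$vertices) + sum(abs(verts[, 3] - 150) < 1e-9))
  expect_error(clip_segments(tube, fraction = 0.6), "fraction")
  expect_error(clip_segments(tube, fraction = 0), "fraction")

  # clipping commutes with rigid motion
  M <- params_to_matrix(c(10, -5, 20, 15, -25, 40))
  clM <- clip_segments(transform_mesh(tube, M), fraction = 0.2)
  expect_equal(clM$proximal$vertices,
               apply_transform(M, cl$proximal$vertices), tolerance = 1e-6)
})

test_that("clipping a sphere-like mesh is rejected as non-elongated", {
  co <- as.matrix(expand.grid(x = 1:21, y = 1:21, z = 1:21)) - 11
  mask <- array(sqrt(rowSums(co^2)) <= 8, c(21, 21, 21))
  ball <- extract_mesh(mask, spacing = 1)
  expect_error(clip_segments(ball), "not elongated")
})

test_that("phantom clip planes sit at 20% of the plateau-to-end length", {
  vol <- coarse_volume()
  geom <- coarse_geometry()
  masks <- coarse_masks()
  imp_mesh <- extract_mesh_volume(vol, masks$implant)
  tib_mesh <- extract_mesh_volume(vol, masks$cortex)
  cl <- clip_segments(tib_mesh, fraction = 0.2, implant_mesh = imp_mesh)
  spec <- geom$spec
  plateau_top <- spec$bone_length / 2 + spec$plateau_thickness
  expect_equal(cl$plateau_level, plateau_top, tolerance = 1.5 * 1.5)
  cut <- cl$plateau_level - 0.2 * cl$length
  expect_true(all(cl$proximal$vertices[, 3] >= cut - 1.5))
  expect_true(all(tib_mesh$vertices[tib_mesh$vertices[, 3] > cut + 1.5, 3] %in%
                    cl$proximal$vertices[, 3]))
})
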