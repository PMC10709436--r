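# minimal stand-in for an analyze_pair output carrying given magnitudes
fake_analysis <- function(whole, prox) {
  mk <- function(v, pair) structure(
    list(pair = pair, dx = v, dy = 0, dz = 0, dphix = 0, dphiy = 0,
         dphiz = 0, translation_magnitude = v, rotation_magnitude = v / 10,
         mTRE = v, MTPM = 1.2 * v, gimbal = FALSE),
    class = "displacement_result")
  list(results = list(`prox-vs-distal` = mk(0.1, "prox-vs-distal"),
                      `implant-vs-whole` = mk(whole, "implant-vs-whole"),
                      `implant-vs-prox` = mk(prox, "implant-vs-prox")))
}

test_that("segmentation stage yields consistent objects and local CS", {
  vol <- coarse_volume()
  cfg <- experiment_config(levelset_iterations = 0,
                           contour_max_points = 1000)
  seg <- segment_objects(vol, cfg)
  expect_s3_class(seg$implant_mesh, "surface_mesh")
  expect_s3_class(seg$cs, "local_cs")
  # the tibia object must not contain implant surface: meshes are disjoint
  expect_gt(min(surface_distance(seg$implant_mesh, seg$tibia_mesh)), 0.5)
  # local CS origin sits on the plateau top within a voxel
  spec <- .fixtures$spec
  plateau_top <- spec$bone_length / 2 + spec$plateau_thickness
  expect_lt(abs(seg$cs$origin[3] - plateau_top), 1.5 * spec$voxel_spacing)
  expect_named(seg$contours, c("implant", "whole", "proximal", "distal"))
  expect_error(segment_objects(ct_volume(array(0, c(4, 4, 4))), cfg),
               "seed points")
})

test_that("a null load pair yields displacements at the noise floor", {
  spec <- coarse_spec()
  poses <- list(valgus = params_to_matrix(c(3, -2, 4, 2, -2, 3)),
                varus = params_to_matrix(c(-2, 3, -3, -2, 3, -2)))
  lp <- generate_load_pair(spec, bend_angle = 0,
                           global_poses = poses, noise_seeds = c(31L, 32L))
  cfg <- experiment_config(contour_max_points = 1200,
                           registration = registration_control(seed = 6))
  an <- analyze_pair(lp$valgus, lp$varus, cfg)
  for (r in an$results) {
    expect_s3_class(r, "displacement_result")
    expect_lt(r$translation_magnitude, 0.1)
    # implant roll is weakly constrained at this coarse test resolution
    # (the keel is thinner than a voxel), so rotations get a looser floor
    expect_lt(r$rotation_magnitude, 0.25)
  }
  # implant pairs carry the scalar migration metrics, deformation pair not
  expect_false(is.na(an$results[["implant-vs-prox"]]$mTRE))
  expect_true(is.na(an$results[["prox-vs-distal"]]$MTPM))
  expect_gte(an$results[["implant-vs-prox"]]$MTPM,
             an$results[["implant-vs-prox"]]$mTRE)
})

test_that("bend recovery is linear and matches the imposed deformation", {
  spec <- coarse_spec()
  cfg <- experiment_config(contour_max_points = 1200,
                           registration = registration_control(seed = 7))
  poses <- list(valgus = params_to_matrix(c(2, 1, -3, 1.5, -2, 1)),
                varus = params_to_matrix(c(-3, -1, 2, -1, 2, -1.5)))
  rots <- vapply(c(0.32, 0.64), function(b) {
    lp <- generate_load_pair(spec, bend_angle = b, global_poses = poses,
                             noise_seeds = c(41L, 42L))
    de <- deformation_experiment(list(lp), cfg)
    de$per_specimen$rotation_magnitude[1]
  }, numeric(1))
  expect_equal(rots[1], 0.64, tolerance = 0.1 / 0.64)  # net bend 2 x 0.32
  expect_equal(rots[2] / rots[1], 2, tolerance = 0.1)  # linear in the bend
})

test_that("methodological error counts n(n-1) apparent displacements", {
  spec <- coarse_spec()
  rs <- generate_repeat_scans(spec, n = 3, seed = 13)
  cfg <- experiment_config(levelset_iterations = 0, contour_max_points = 800,
                           registration = registration_control(seed = 8))
  me <- methodological_error(rs$volumes, cfg)
  expect_equal(me$n_apparent, 6)
  expect_equal(nrow(me$displacements), 6 * 3)   # three object pairs
  expect_setequal(unique(me$displacements$pair),
                  c("prox-vs-distal", "implant-vs-whole", "implant-vs-prox"))
  # zero ground truth: translations stay at the noise floor; rotations of
  # the implant pairs are coarse-resolution limited (sub-voxel keel)
  expect_lt(max(me$displacements$translation_magnitude), 0.15)
  expect_lt(max(me$displacements$rotation_magnitude), 1)
  summ <- me$summary
  expect_true(all(c("accuracy", "precision", "max_abs") %in% names(summ)))
  expect_error(methodological_error(rs$volumes[1], cfg), "at least 2")
})

test_that("fixed-vs-loose comparison counts overlaps and runs the tests", {
  fixed <- lapply(c(0.4, 0.45, 0.5, 0.42, 0.48),
                  function(w) fake_analysis(w, w - 0.2))
  loose_sep <- lapply(c(2.0, 2.2, 1.9, 2.1, 2.3),
                      function(w) fake_analysis(w, w - 0.2))
  cmp <- fixed_vs_loose_comparison(fixed, loose_sep)
  expect_true(all(cmp$overlap_cases == 0))
  expect_equal(nrow(cmp), 8)  # 4 metrics x 2 references

  # identical groups: full overlap, degenerate paired test
  cmp_id <- fixed_vs_loose_comparison(fixed, fixed)
  expect_true(all(cmp_id$overlap_cases == length(fixed)))
  # whole systematically exceeds prox in the fakes -> small paired p
  expect_lt(cmp$p_whole_vs_prox_fixed[1], 0.1)
  expect_error(fixed_vs_loose_comparison(fixed, loose_sep[1:3]), "paired")
})

test_that("displacement tables collect one row per specimen and pair", {
  tab <- displacement_table(list(fake_analysis(0.5, 0.3),
                                 fake_analysis(0.6, 0.4)))
  expect_equal(nrow(tab), 6)
  expect_true(all(c("specimen", "pair", "translation_magnitude") %in%
                    names(tab)))
})
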