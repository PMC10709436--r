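#' Specification of the synthetic tibia + implant CT phantom
#'
#' Describes a desk-scale digital phantom of a (reduced-size) tibia with a
#' tibial TKA component: a tubular bone with bright cortical shell, darker
#' trabecular interior and flared proximal metaphysis, carrying a very bright
#' implant consisting of an elliptical plateau (ML halfwidth > AP halfwidth,
#' so the plateau inertia axes are unambiguous) and a cylindrical stem, with
#' an optional cement layer. The shaft cross-section is tri-lobed
#' (roughly triangular, like a real tibia), which makes axial roll
#' identifiable. Intensities are CT-like arbitrary units chosen so that the
#' usual empirical thresholds (about 1600 for cortex, 3500 for the implant)
#' fall at the blurred edge midpoints of the respective objects, so
#' threshold masks sit on the true surfaces. The canonical specimen
#' frame has the bone axis along z, centred on the origin; distal end at
#' `-bone_length/2`, resected proximal end at `+bone_length/2` with the
#' plateau on top.
#'
#' @param bone_length bone length within the scan, mm.
#' @param shaft_radius,metaphysis_radius,flare_length outer-radius profile:
#'   shaft radius, proximal (metaphysis) radius and the axial length of the
#'   smoothstep flare between them, mm.
#' @param cortical_thickness cortical shell thickness, mm.
#' @param lobe_amplitude relative amplitude of the tri-lobed (roughly
#'   triangular, tibia-like) cross-section modulation of the outer radius;
#'   breaks the rotational symmetry of the shaft so that axial roll is
#'   identifiable by registration. 0 gives a circular shaft.
#' @param intensity_background,intensity_trabecular,intensity_cortex,intensity_cement,intensity_implant
#'   class intensities (must increase from background to implant).
#' @param plateau_halfwidth_ml,plateau_halfwidth_ap,plateau_thickness implant
#'   plateau halfwidths (medial-lateral along x, anterior-posterior along y)
#'   and thickness, mm; ML must exceed AP.
#' @param plateau_posterior_cut posterior flat cut of the plateau: the tray
#'   is truncated at `y = -plateau_posterior_cut * plateau_halfwidth_ap`
#'   (posterior side), like the posterior cutout of a real tibial tray;
#'   breaks the rotational near-symmetry of the plateau. 1 disables.
#' @param stem_length,stem_radius implant stem dimensions, mm.
#' @param keel_halfwidth,keel_halfthickness,keel_depth medial-lateral keel
#'   (fin plate) through the stem: half-extent along x, half-thickness along
#'   y, and axial depth below the resection; a sharp azimuthal feature that
#'   makes implant roll well-determined, as on real keeled tibial stems.
#'   `keel_halfwidth = 0` disables.
#' @param cement_thickness optional cement mantle thickness under the plateau
#'   and around the stem, mm (0 disables).
#' @param voxel_spacing isotropic voxel spacing, mm.
#' @param fov_mm field of view, mm (3-vector), centred on the phantom.
#' @param psf_sigma_voxels Gaussian point-spread sigma of the simulated
#'   scanner, in voxel units (reconstruction-kernel blur matched to the
#'   sampling resolution; 0 disables).
#' @param noise_sd additive Gaussian noise standard deviation, intensity
#'   units (added after the point-spread blur, like reconstruction noise).
#' @param seed integer seed used for noise generation.
#' @param max_voxels guard against accidentally huge voxelizations.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(bone_length = 180,
                         shaft_radius = 12,
                         metaphysis_radius = 20,
                         flare_length = 30,
                         cortical_thickness = 4,
                         lobe_amplitude = 0.12,
                         intensity_background = 0,
                         intensity_trabecular = 300,
                         intensity_cortex = 2900,
                         intensity_cement = 2400,
                         intensity_implant = 7000,
                         plateau_halfwidth_ml = 12,
                         plateau_halfwidth_ap = 9.5,
                         plateau_thickness = 4,
                         plateau_posterior_cut = 0.5,
                         stem_length = 20,
                         stem_radius = 4.5,
                         keel_halfwidth = 8,
                         keel_halfthickness = 1.25,
                         keel_depth = 12,
                         cement_thickness = 0,
                         voxel_spacing = 0.45,
                         fov_mm = c(115.2, 115.2, 288),
                         psf_sigma_voxels = 1,
                         noise_sd = 0,
                         seed = 1L,
                         max_voxels = 6e7) {
  geom <- c(bone_length, shaft_radius, metaphysis_radius, flare_length,
            cortical_thickness, plateau_halfwidth_ml, plateau_halfwidth_ap,
            plateau_thickness, stem_length, stem_radius, voxel_spacing,
            fov_mm)
  if (any(!is.finite(geom)) || any(geom <= 0))
    stop("all geometric dimensions and the voxel spacing must be positive")
  if (!(intensity_implant > intensity_cortex &&
        intensity_cortex > intensity_trabecular &&
        intensity_trabecular > intensity_background))
    stop("intensities must satisfy implant > cortex > trabecular > background")
  if (plateau_halfwidth_ml <= plateau_halfwidth_ap)
    stop("plateau ML halfwidth must exceed AP halfwidth")
  if (plateau_posterior_cut <= 0 || plateau_posterior_cut > 1)
    stop("plateau_posterior_cut must be in (0, 1]")
  if (cortical_thickness >= shaft_radius)
    stop("cortical thickness must be smaller than the shaft radius")
  if (stem_length >= flare_length + plateau_thickness)
    stop("stem must end within the flared metaphysis (narrow-shaft clearance)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (lobe_amplitude < 0 || lobe_amplitude > 0.3)
    stop("lobe_amplitude must be in [0, 0.3]")
  if (psf_sigma_voxels < 0) stop("psf_sigma_voxels must be non-negative")
  structure(list(
    bone_length = bone_length, shaft_radius = shaft_radius,
    metaphysis_radius = metaphysis_radius, flare_length = flare_length,
    cortical_thickness = cortical_thickness,
    lobe_amplitude = lobe_amplitude,
    intensity_background = intensity_background,
    intensity_trabecular = intensity_trabecular,
    intensity_cortex = intensity_cortex,
    intensity_cement = intensity_cement,
    intensity_implant = intensity_implant,
    plateau_halfwidth_ml = plateau_halfwidth_ml,
    plateau_halfwidth_ap = plateau_halfwidth_ap,
    plateau_thickness = plateau_thickness,
    plateau_posterior_cut = plateau_posterior_cut,
    stem_length = stem_length, stem_radius = stem_radius,
    keel_halfwidth = keel_halfwidth,
    keel_halfthickness = keel_halfthickness, keel_depth = keel_depth,
    cement_thickness = cement_thickness,
    voxel_spacing = voxel_spacing, fov_mm = fov_mm,
    psf_sigma_voxels = psf_sigma_voxels,
    noise_sd = noise_sd, seed = as.integer(seed),
    max_voxels = max_voxels), class = "phantom_spec")
}

# smoothstep outer-radius profile r(z): shaft -> flared metaphysis; the
# optional azimuthal term modulates the radius tri-lobed (tibia-like
# triangular cross-section), with lobes placed off the ML/AP axes
outer_radius_profile <- function(spec, z, theta = NULL) {
  z1 <- spec$bone_length / 2
  u <- (z - (z1 - spec$flare_length)) / spec$flare_length
  u <- pmin(pmax(u, 0), 1)
  r <- spec$shaft_radius +
    (spec$metaphysis_radius - spec$shaft_radius) * (3 * u^2 - 2 * u^3)
  if (!is.null(theta) && spec$lobe_amplitude > 0)
    r <- r * (1 - spec$lobe_amplitude * sin(3 * theta))
  r
}

#' Build the analytic phantom geometry
#'
#' Returns a closed-form point classifier (implicit solids, priority
#' implant > cement > cortex > trabecular) together with exact analytic
#' surface meshes for the implant, the cortical shell, and its proximal and
#' distal 20% segments, all in the canonical specimen frame.
#'
#' @param spec a `phantom_spec`.
#' @param clip_fraction end-segment fraction used for the analytic
#'   proximal/distal segment meshes (and for the bending zones).
#' @return an object of class `phantom_geometry`.
#' @export
build_geometry <- function(spec, clip_fraction = 0.2) {
  stopifnot(inherits(spec, "phantom_spec"))
  L <- spec$bone_length
  z0 <- -L / 2; z1 <- L / 2
  geom <- list(
    spec = spec, z0 = z0, z1 = z1,
    z_distal_top = z0 + clip_fraction * L,
    z_prox_bottom = z1 - clip_fraction * L,
    bend = NULL,                  # set by apply_bending
    implant_extra = rigid_identity(),  # loose-implant motion (varus state)
    M_rigid_prox = rigid_identity()    # exact rigid motion of prox zone + implant
  )
  geom$meshes <- phantom_meshes(spec, z0, z1, geom$z_distal_top,
                                geom$z_prox_bottom)
  class(geom) <- "phantom_geometry"
  geom
}

# classify canonical bone-frame points into 0 bg / 1 trab / 2 cortex / 3 cement
classify_bone <- function(spec, pts) {
  pts <- rbind_points(pts)
  z0 <- -spec$bone_length / 2; z1 <- spec$bone_length / 2
  t <- spec$cortical_thickness
  r2 <- pts[, 1]^2 + pts[, 2]^2
  z <- pts[, 3]
  theta <- atan2(pts[, 2], pts[, 1])
  rout <- outer_radius_profile(spec, z, theta)
  inbone <- z >= z0 & z <= z1 & r2 <= rout^2
  cortex <- inbone & (r2 >= (rout - t)^2 | z <= z0 + t)
  code <- integer(nrow(pts))
  code[inbone] <- 1L
  code[cortex] <- 2L
  ct <- spec$cement_thickness
  if (ct > 0) {
    a <- spec$plateau_halfwidth_ml; b <- spec$plateau_halfwidth_ap
    mantle <- (z <= z1 & z >= z1 - ct &
                 (pts[, 1] / a)^2 + (pts[, 2] / b)^2 <= 1 &
                 pts[, 2] >= -spec$plateau_posterior_cut * b) |
      (z < z1 & z >= z1 - spec$stem_length &
         r2 <= (spec$stem_radius + ct)^2)
    code[mantle] <- 3L
  }
  code
}

# classify canonical implant-frame points: 0 / 4 implant
classify_implant <- function(spec, pts) {
  pts <- rbind_points(pts)
  z1 <- spec$bone_length / 2
  z <- pts[, 3]
  plat <- z >= z1 & z <= z1 + spec$plateau_thickness &
    (pts[, 1] / spec$plateau_halfwidth_ml)^2 +
    (pts[, 2] / spec$plateau_halfwidth_ap)^2 <= 1 &
    pts[, 2] >= -spec$plateau_posterior_cut * spec$plateau_halfwidth_ap
  stem <- z < z1 & z >= z1 - spec$stem_length &
    pts[, 1]^2 + pts[, 2]^2 <= spec$stem_radius^2
  keel <- spec$keel_halfwidth > 0 &
    z < z1 - 2 & z >= z1 - spec$keel_depth &
    abs(pts[, 2]) <= spec$keel_halfthickness &
    abs(pts[, 1]) <= spec$keel_halfwidth
  ifelse(plat | stem | keel, 4L, 0L)
}

#' Classify world points of a (possibly bent, possibly posed) phantom
#'
#' @param geometry a `phantom_geometry`.
#' @param pts n x 3 world points (mm).
#' @param pose global rigid pose of the specimen (canonical -> world).
#' @return integer class codes: 0 background, 1 trabecular, 2 cortex,
#'   3 cement, 4 implant.
#' @export
classify_points <- function(geometry, pts, pose = rigid_identity()) {
  pts <- rbind_points(pts)
  q <- apply_transform(rigid_invert(pose), pts)
  p_bone <- bend_inverse(geometry, q)
  code <- classify_bone(geometry$spec, p_bone)
  # implant moves rigidly: prox-zone bend rotation plus any extra motion
  M_imp <- rigid_compose(geometry$M_rigid_prox, geometry$implant_extra)
  p_imp <- apply_transform(rigid_invert(M_imp), q)
  imp <- classify_implant(geometry$spec, p_imp)
  ifelse(imp > 0L, 4L, code)
}

# --- bending -----------------------------------------------------------------

# rotation about a y-parallel axis through `origin` by angle deg (coronal
# x-z plane bending)
bend_rotation <- function(angle_deg, origin) {
  rigid_compose(
    params_to_matrix(c(origin, 0, 0, 0)),
    params_to_matrix(c(0, 0, 0, 0, angle_deg, 0)),
    params_to_matrix(c(-origin, 0, 0, 0)))
}

# per-point bend angle: zero over the distal segment, linear ramp over the
# mid-shaft, constant (rigid) over the proximal segment and implant
bend_angle_at <- function(bend, z) {
  u <- (z - bend$z_ramp0) / (bend$z_ramp1 - bend$z_ramp0)
  bend$angle * pmin(pmax(u, 0), 1)
}

bend_forward <- function(geometry, pts) {
  if (is.null(geometry$bend)) return(rbind_points(pts))
  pts <- rbind_points(pts)
  a <- bend_angle_at(geometry$bend, pts[, 3]) * pi / 180
  o <- geometry$bend$origin
  ca <- cos(a); sa <- sin(a)
  dx <- pts[, 1] - o[1]; dz <- pts[, 3] - o[3]
  cbind(o[1] + ca * dx + sa * dz, pts[, 2], o[3] - sa * dx + ca * dz)
}

bend_inverse <- function(geometry, pts) {
  if (is.null(geometry$bend)) return(rbind_points(pts))
  pts <- rbind_points(pts)
  o <- geometry$bend$origin
  p <- pts
  for (it in 1:8) {   # fixed point: the bend angle depends on the pre-image z
    a <- bend_angle_at(geometry$bend, p[, 3]) * pi / 180
    ca <- cos(a); sa <- sin(a)
    dx <- pts[, 1] - o[1]; dz <- pts[, 3] - o[3]
    p <- cbind(o[1] + ca * dx - sa * dz, pts[, 2], o[3] + sa * dx + ca * dz)
  }
  p
}

#' Impose coronal-plane bending on the phantom
#'
#' Bends the bone about a y-parallel axis: the distal 20% segment stays
#' rigid (unmoved), the rotation angle ramps linearly over the mid-shaft,
#' and the proximal 20% segment - together with the implant, which rides
#' with the proximal bone - moves by the exact rigid rotation `bend_angle`.
#' Positive angles displace the proximal end towards +x (lateral).
#'
#' @param geometry a `phantom_geometry` (unbent).
#' @param bend_angle signed bend angle in degrees; |angle| must be <= 10
#'   (small-deformation regime).
#' @param bend_axis_origin point on the bending axis, mm; defaults to the
#'   bone axis at the top of the distal segment.
#' @param implant_motion extra rigid motion of the implant relative to the
#'   proximal bone (identity = well-fixed implant).
#' @return the deformed `phantom_geometry`; meshes are mapped through the
#'   bend, `M_rigid_prox` records the exact rigid motion of the proximal
#'   zone and implant.
#' @export
apply_bending <- function(geometry, bend_angle, bend_axis_origin = NULL,
                          implant_motion = rigid_identity()) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  if (!is.null(geometry$bend)) stop("geometry is already bent")
  if (abs(bend_angle) > 10)
    stop("|bend_angle| > 10 degrees is outside the small-deformation regime")
  assert_rigid(implant_motion)
  if (is.null(bend_axis_origin))
    bend_axis_origin <- c(0, 0, geometry$z_distal_top)
  g <- geometry
  g$bend <- list(angle = bend_angle, origin = bend_axis_origin,
                 z_ramp0 = geometry$z_distal_top,
                 z_ramp1 = geometry$z_prox_bottom)
  g$M_rigid_prox <- bend_rotation(bend_angle, bend_axis_origin)
  g$implant_extra <- implant_motion
  if (bend_angle != 0) {
    M_imp <- rigid_compose(g$M_rigid_prox, implant_motion)
    g$meshes$implant <- transform_mesh(geometry$meshes$implant, M_imp)
    for (nm in c("cortex", "proximal", "distal")) {
      m <- geometry$meshes[[nm]]
      g$meshes[[nm]] <- surface_mesh(bend_forward(g, m$vertices), m$faces,
                                     normals = m$normals)
    }
  } else if (!isTRUE(all.equal(unclass(implant_motion), diag(4)))) {
    g$meshes$implant <- transform_mesh(geometry$meshes$implant, implant_motion)
  }
  g
}

# --- voxelization ------------------------------------------------------------

class_intensities <- function(spec) {
  c(spec$intensity_background, spec$intensity_trabecular,
    spec$intensity_cortex, spec$intensity_cement, spec$intensity_implant)
}

#' Voxelize a phantom geometry into a CT-like volume
#'
#' Each voxel receives its class intensity; voxels at class boundaries are
#' supersampled 3x3x3 for partial-volume realism (the registration metric
#' relies on the resulting gray-level gradient at the cortex edge). Gaussian
#' noise of `spec$noise_sd` is added using `noise_seed`, so a fixed seed
#' gives bit-identical volumes.
#'
#' @param geometry a `phantom_geometry`.
#' @param spec the `phantom_spec` (carries spacing, FOV, intensities, noise).
#' @param pose global rigid pose of the specimen inside the scanner.
#' @param noise_seed seed for the additive noise; defaults to `spec$seed`.
#' @param supersample supersampling factor per axis at boundaries.
#' @return a `ct_volume`.
#' @export
voxelize <- function(geometry, spec = geometry$spec, pose = rigid_identity(),
                     noise_seed = spec$seed, supersample = 5) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  assert_rigid(pose)
  sp <- spec$voxel_spacing
  dims <- pmax(2L, as.integer(round(spec$fov_mm / sp)))
  if (prod(dims) > spec$max_voxels)
    stop("voxelization of ", paste(dims, collapse = "x"),
         " voxels exceeds max_voxels; increase spacing or the budget")
  origin <- -spec$fov_mm / 2 + sp / 2
  xs <- origin[1] + sp * (seq_len(dims[1]) - 1)
  ys <- origin[2] + sp * (seq_len(dims[2]) - 1)
  zs <- origin[3] + sp * (seq_len(dims[3]) - 1)
  pts <- cbind(rep(xs, times = dims[2] * dims[3]),
               rep(rep(ys, each = dims[1]), times = dims[3]),
               rep(zs, each = dims[1] * dims[2]))
  code <- classify_points(geometry, pts, pose)
  dim(code) <- dims
  intens <- class_intensities(spec)
  vals <- intens[code + 1L]
  dim(vals) <- dims

  if (supersample > 1) {
    b <- array(FALSE, dims)
    for (ax in 1:3) {
      d <- dims[ax]
      lo <- slice_index(dims, ax, 1:(d - 1))
      hi <- slice_index(dims, ax, 2:d)
      diffm <- code[lo] != code[hi]
      bl <- b[lo]; b[lo] <- bl | diffm
      bh <- b[hi]; b[hi] <- bh | diffm
    }
    bid <- which(b)
    if (length(bid) > 0) {
      centers <- pts[bid, , drop = FALSE]
      off1 <- sp * (seq_len(supersample) - (supersample + 1) / 2) / supersample
      offs <- as.matrix(expand.grid(x = off1, y = off1, z = off1))
      acc <- numeric(length(bid))
      for (o in seq_len(nrow(offs))) {
        sub <- sweep(centers, 2, offs[o, ], `+`)
        acc <- acc + intens[classify_points(geometry, sub, pose) + 1L]
      }
      vals[bid] <- acc / nrow(offs)
    }
  }

  if (spec$psf_sigma_voxels > 0)
    vals <- cpp_gaussian_blur(vals, dims, spec$psf_sigma_voxels)
  if (spec$noise_sd > 0) {
    vals <- vals + with_local_seed(noise_seed,
      array(stats::rnorm(prod(dims), 0, spec$noise_sd), dims))
  }
  ct_volume(vals, spacing = sp, origin = origin)
}

# logical index selecting slices `idx` along axis `ax` of an array of dims
slice_index <- function(dims, ax, idx) {
  args <- list(TRUE, TRUE, TRUE)
  args[[ax]] <- idx
  do.call(`[`, c(list(array(seq_len(prod(dims)), dims)), args,
                 list(drop = FALSE)))
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# --- load pairs and repeat scans --------------------------------------------

#' Ground truth of a valgus/varus load pair
#'
#' Records the generating poses and the exact relative-displacement matrices
#' implied by the construction: the proximal-vs-distal matrix (tibia
#' deformation) and the implant-vs-proximal matrix (implant fixation).
#' `implant_whole_exact` flags whether the implant-vs-whole truth is exact
#' (it is only when no bending is imposed, since the whole tibia is not a
#' rigid body under bending).
#'
#' @param ... fields; see `generate_load_pair`.
#' @keywords internal
load_pair_ground_truth <- function(...) {
  structure(list(...), class = "load_pair_ground_truth")
}

#' Generate a valgus/varus CT volume pair with known ground truth
#'
#' The valgus state is bent by `+bend_angle`, the varus state by
#' `-bend_angle` (net relative bend `2 * bend_angle`), emulating the
#' geometric effect of the valgus/varus load moments. Each state is
#' additionally posed by an arbitrary global rigid transform (specimen
#' repositioning between acquisitions). An extra rigid `implant_motion`
#' relative to the proximal bone in the varus state emulates a loose
#' implant.
#'
#' @param spec a `phantom_spec`.
#' @param bend_angle per-state bend angle, degrees.
#' @param implant_motion rigid transform of the implant relative to the
#'   proximal bone between the states (identity = fixed implant).
#' @param global_poses list with rigid `valgus` and `varus` specimen poses.
#' @param noise_seeds length-2 integer seeds for the two volumes' noise.
#' @return list with `valgus` and `varus` (`ct_volume`s, each carrying a
#'   `seed_points` attribute with implant/cortex seed positions), `truth`
#'   (a `load_pair_ground_truth`), and the two geometries.
#' @export
generate_load_pair <- function(spec, bend_angle,
                               implant_motion = rigid_identity(),
                               global_poses = list(valgus = rigid_identity(),
                                                   varus = rigid_identity()),
                               noise_seeds = spec$seed + c(0L, 1L)) {
  stopifnot(inherits(spec, "phantom_spec"))
  G_val <- global_poses$valgus
  G_var <- global_poses$varus
  assert_rigid(G_val); assert_rigid(G_var)
  base <- build_geometry(spec)
  geom_val <- apply_bending(base, +bend_angle)
  geom_var <- apply_bending(base, -bend_angle, implant_motion = implant_motion)
  vol_val <- voxelize(geom_val, spec, pose = G_val, noise_seed = noise_seeds[1])
  vol_var <- voxelize(geom_var, spec, pose = G_var, noise_seed = noise_seeds[2])
  attr(vol_val, "seed_points") <- phantom_seed_points(geom_val, G_val)
  attr(vol_var, "seed_points") <- phantom_seed_points(geom_var, G_var)

  B_val <- geom_val$M_rigid_prox
  B_var <- geom_var$M_rigid_prox
  M_distal <- rigid_compose(G_var, rigid_invert(G_val))
  M_prox <- rigid_compose(G_var, B_var, rigid_invert(B_val),
                          rigid_invert(G_val))
  M_impl <- rigid_compose(G_var, B_var, implant_motion, rigid_invert(B_val),
                          rigid_invert(G_val))
  truth <- load_pair_ground_truth(
    global_pose_valgus = G_val, global_pose_varus = G_var,
    bend_angle = bend_angle, bend_axis_origin = geom_val$bend$origin,
    implant_motion = implant_motion,
    true_M_prox_distal = rigid_compose(rigid_invert(M_distal), M_prox),
    true_M_implant_prox = rigid_compose(rigid_invert(M_prox), M_impl),
    true_M_implant_whole = rigid_compose(rigid_invert(M_distal), M_impl),
    implant_whole_exact = (bend_angle == 0))
  list(valgus = vol_val, varus = vol_var, truth = truth,
       geometry_valgus = geom_val, geometry_varus = geom_var)
}

#' Generate repeat scans of the undeformed phantom
#'
#' Renders `n` scans of the identical (undeformed, fixed-implant) phantom
#' under random global poses and independent noise, emulating repeated
#' scanning of a specimen in different positions and orientations without
#' external loading. Any displacement measured between them is
#' methodological error.
#'
#' @param spec a `phantom_spec`.
#' @param n number of scans (>= 2).
#' @param pose_jitter list with `translation` (mm) and `rotation` (degrees)
#'   half-ranges of the uniform pose perturbations.
#' @param seed integer seed for the poses (noise uses `seed + scan index`).
#' @return list with `volumes` (each with a `seed_points` attribute),
#'   `poses`, and the geometry.
#' @export
generate_repeat_scans <- function(spec, n,
                                  pose_jitter = list(translation = 20,
                                                     rotation = 10),
                                  seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n < 2) stop("need at least 2 repeat scans")
  geom <- build_geometry(spec)
  poses <- with_local_seed(seed, lapply(seq_len(n), function(i) {
    params_to_matrix(c(stats::runif(3, -pose_jitter$translation,
                                    pose_jitter$translation),
                       stats::runif(3, -pose_jitter$rotation,
                                    pose_jitter$rotation)))
  }))
  volumes <- lapply(seq_len(n), function(i) {
    v <- voxelize(geom, spec, pose = poses[[i]],
                  noise_seed = as.integer(seed + i))
    attr(v, "seed_points") <- phantom_seed_points(geom, poses[[i]])
    v
  })
  list(volumes = volumes, poses = poses, geometry = geom)
}

# world seed points inside the implant and the cortex for region growing
phantom_seed_points <- function(geometry, pose = rigid_identity()) {
  spec <- geometry$spec
  z1 <- spec$bone_length / 2
  p_imp <- c(0, 0, z1 + spec$plateau_thickness / 2)
  M_imp <- rigid_compose(pose, geometry$M_rigid_prox, geometry$implant_extra)
  mid_r <- outer_radius_profile(spec, 0) - spec$cortical_thickness / 2
  p_cor <- c(mid_r, 0, 0)
  list(implant = drop(apply_transform(M_imp, p_imp)),
       cortex = drop(apply_transform(pose, bend_forward(geometry, p_cor))))
}

# --- analytic meshes ---------------------------------------------------------

# triangulate a parametric surface f(u, v) -> xyz over a grid
param_grid_mesh <- function(f, us, vs, wrap_u = FALSE) {
  nu <- length(us); nv <- length(vs)
  uu <- rep(us, times = nv); vv <- rep(vs, each = nu)
  verts <- f(uu, vv)
  id <- function(i, j) (j - 1) * nu + i
  i <- seq_len(if (wrap_u) nu else nu - 1)
  i2 <- if (wrap_u) c(seq_len(nu)[-1], 1L) else i + 1L
  faces <- NULL
  for (j in seq_len(nv - 1)) {
    a <- id(i, j); b <- id(i2, j); c2 <- id(i2, j + 1); d <- id(i, j + 1)
    faces <- rbind(faces, cbind(a, b, c2), cbind(a, c2, d))
  }
  list(vertices = verts, faces = faces)
}

# axis-aligned closed box between corners lo and hi, faces subdivided ~2 mm
box_mesh <- function(lo, hi) {
  gr <- function(d) seq(lo[d], hi[d], length.out = max(
    2, ceiling((hi[d] - lo[d]) / 2) + 1))
  face <- function(fixed_dim, at, d1, d2) {
    param_grid_mesh(function(u, v) {
      out <- matrix(0, length(u), 3)
      out[, fixed_dim] <- at; out[, d1] <- u; out[, d2] <- v
      out
    }, gr(d1), gr(d2))
  }
  parts <- list(face(1, lo[1], 2, 3), face(1, hi[1], 2, 3),
                face(2, lo[2], 1, 3), face(2, hi[2], 1, 3),
                face(3, lo[3], 1, 2), face(3, hi[3], 1, 2))
  offs <- cumsum(c(0, vapply(parts, function(p) nrow(p$vertices),
                             numeric(1))))
  list(vertices = do.call(rbind, lapply(parts, `[[`, "vertices")),
       faces = do.call(rbind, Map(function(p, o) p$faces + o, parts,
                                  offs[1:6])))
}

# closed "generalised revolution" surface: a cyclic sequence of profile
# rows, each giving a radius as a function of theta, swept about the z axis
sweep_mesh <- function(radius_funs, zs, n_theta = 96) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  np <- length(radius_funs)
  pts <- do.call(rbind, lapply(seq_len(np), function(i) {
    r <- pmax(radius_funs[[i]](th), 1e-6)
    cbind(r * cos(th), r * sin(th), zs[i])
  }))
  id <- function(i, t) (i - 1) * n_theta + t
  tnext <- c(seq_len(n_theta)[-1], 1L)
  faces <- NULL
  for (i in seq_len(np)) {       # closed in the profile direction too
    i2 <- if (i == np) 1L else i + 1L
    a <- id(i, seq_len(n_theta)); b <- id(i, tnext)
    c2 <- id(i2, tnext); d <- id(i2, seq_len(n_theta))
    faces <- rbind(faces, cbind(a, b, c2), cbind(a, c2, d))
  }
  surface_mesh(pts, faces)
}

# analytic meshes of implant, cortical shell, and its end segments
phantom_meshes <- function(spec, z0, z1, z_distal_top, z_prox_bottom) {
  t <- spec$cortical_thickness
  zs_up <- seq(z0, z1, by = 1.5)
  if (zs_up[length(zs_up)] < z1) zs_up <- c(zs_up, z1)
  zs_dn <- rev(zs_up[zs_up >= z0 + t])
  if (zs_dn[length(zs_dn)] > z0 + t) zs_dn <- c(zs_dn, z0 + t)
  outer_r <- function(z) function(th) outer_radius_profile(spec, z, th)
  inner_r <- function(z) function(th) outer_radius_profile(spec, z, th) - t
  frac_r <- function(f, z, inner = FALSE) function(th) {
    rb <- outer_radius_profile(spec, z, th)
    f * (if (inner) rb - t else rb)
  }
  qs <- seq(0, 1, length.out = 8)
  funs <- c(lapply(qs[-1], frac_r, z = z0),                 # bottom face
            lapply(zs_up[-1], outer_r),                     # outer wall
            lapply(seq(0.75, 0.25, by = -0.25), function(q) # top annulus
              function(th) outer_radius_profile(spec, z1, th) - (1 - q) * t),
            lapply(zs_dn, inner_r),                         # inner wall
            lapply(rev(qs[-length(qs)]), frac_r, z = z0 + t, inner = TRUE),
            list(function(th) rep(1e-6, length(th))))       # close on axis
  zs_all <- c(rep(z0, length(qs) - 1), zs_up[-1],
              rep(z1, 3), zs_dn, rep(z0 + t, length(qs) - 1), z0)
  cortex <- sweep_mesh(funs, zs_all, n_theta = 144)

  a <- spec$plateau_halfwidth_ml; b <- spec$plateau_halfwidth_ap
  pt <- spec$plateau_thickness; sr <- spec$stem_radius
  sl <- spec$stem_length
  cut <- spec$plateau_posterior_cut * b
  rho <- function(u) {
    re <- a * b / sqrt((b * cos(u))^2 + (a * sin(u))^2)
    chord <- ifelse(sin(u) < -1e-9, cut / (-sin(u)), Inf)
    pmin(re, chord)
  }
  th <- seq(0, 2 * pi, length.out = 145)
  wall <- param_grid_mesh(function(u, v) cbind(rho(u) * cos(u),
                                               rho(u) * sin(u), v),
                          th[-145], seq(z1, z1 + pt, length.out = 5),
                          wrap_u = TRUE)
  top <- param_grid_mesh(function(u, v) cbind(v * rho(u) * cos(u),
                                              v * rho(u) * sin(u), z1 + pt),
                         th[-145], seq(1e-4, 1, length.out = 6),
                         wrap_u = TRUE)
  bottom <- param_grid_mesh(function(u, v) {
    r <- (1 - v) * sr + v * rho(u)
    cbind(r * cos(u), r * sin(u), z1)
  }, th[-145], seq(0, 1, length.out = 5), wrap_u = TRUE)
  th2 <- seq(0, 2 * pi, length.out = 49)
  stem <- param_grid_mesh(function(u, v) cbind(sr * cos(u), sr * sin(u), v),
                          th2[-49], seq(z1 - sl, z1, length.out = 12),
                          wrap_u = TRUE)
  stem_cap <- param_grid_mesh(function(u, v) cbind(v * sr * cos(u),
                                                   v * sr * sin(u), z1 - sl),
                              th2[-49], seq(1e-4, 1, length.out = 4),
                              wrap_u = TRUE)
  parts <- list(wall, top, bottom, stem, stem_cap)
  if (spec$keel_halfwidth > 0) {
    kb <- function(x0, x1) box_mesh(c(x0, -spec$keel_halfthickness,
                                      z1 - spec$keel_depth),
                                    c(x1, spec$keel_halfthickness, z1 - 2))
    parts <- c(parts, list(kb(sr * 0.98, spec$keel_halfwidth),
                           kb(-spec$keel_halfwidth, -sr * 0.98)))
  }
  offs <- cumsum(c(0, vapply(parts, function(p) nrow(p$vertices),
                             numeric(1))))
  implant <- surface_mesh(
    do.call(rbind, lapply(parts, `[[`, "vertices")),
    do.call(rbind, Map(function(p, o) p$faces + o, parts,
                       offs[seq_along(parts)])))
  if (spec$keel_halfwidth > 0) {
    # stem-wall vertices buried inside the keel plate are interior points,
    # not surface; drop them so the mesh is a faithful surface sample
    v <- implant$vertices
    eps <- 1e-6
    interior <- abs(v[, 2]) < spec$keel_halfthickness - eps &
      abs(v[, 1]) < spec$keel_halfwidth - eps &
      v[, 3] > z1 - spec$keel_depth + eps & v[, 3] < z1 - 2 - eps
    implant <- mesh_subset(implant, !interior)
  }

  list(implant = implant, cortex = cortex,
       proximal = mesh_subset(cortex, cortex$vertices[, 3] >= z_prox_bottom),
       distal = mesh_subset(cortex, cortex$vertices[, 3] <= z_distal_top))
}
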