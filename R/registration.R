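#' Gray-value correlation metric of a double contour under a transform
#'
#' Pearson correlation between the reference gray values stored in the
#' double contour (sampled from the segmentation image) and the target image
#' sampled at the transformed contour points. Only points whose transformed
#' position lies inside the target volume contribute; outer and inner shell
#' points are used (base points carry no grays).
#'
#' @param contour a `double_contour`.
#' @param target the target `ct_volume` (e.g. the varus image).
#' @param M rigid transform applied to the contour points.
#' @return correlation coefficient in `[-1, 1]` with attribute
#'   `fraction_valid`.
#' @export
correlation_metric <- function(contour, target, M = rigid_identity()) {
  stopifnot(inherits(contour, "double_contour"), inherits(target, "ct_volume"))
  assert_rigid(M)
  pts <- rbind(contour$outer_points, contour$inner_points)
  s <- trilinear_sample(target, apply_transform(M, pts))
  ok <- s$valid
  if (sum(ok) < 10) stop("fewer than 10 valid transformed sample points")
  ref <- contour$reference_grays[ok]
  tgt <- s$values[ok]
  if (stats::sd(ref) == 0 || stats::sd(tgt) == 0)
    stop("zero variance in gray values: correlation undefined")
  structure(stats::cor(ref, tgt), fraction_valid = mean(ok))
}

# optimizer-internal metric: penalise instead of erroring so Nelder-Mead can
# back out of degenerate poses
metric_safe <- function(contour, target, M) {
  pts <- rbind(contour$outer_points, contour$inner_points)
  s <- trilinear_sample(target, apply_transform(M, pts))
  ok <- s$valid
  frac <- mean(ok)
  if (sum(ok) < 10) return(structure(-1, fraction_valid = frac))
  ref <- contour$reference_grays[ok]
  tgt <- s$values[ok]
  if (stats::sd(ref) == 0 || stats::sd(tgt) == 0)
    return(structure(-1, fraction_valid = frac))
  # soft penalty for poses that push the contour out of the volume
  structure(stats::cor(ref, tgt) * min(1, frac / 0.5),
            fraction_valid = frac)
}

#' Registration control settings
#'
#' @param max_evaluations Nelder-Mead function-evaluation budget per start.
#' @param step_mm,step_deg initial simplex step sizes (translations mm,
#'   rotations degrees).
#' @param reltol relative convergence tolerance on the metric.
#' @param restarts maximum number of seeded random restarts.
#' @param restart_threshold restarts trigger only while the best correlation
#'   is below this value (successful registrations are not re-run; deformed
#'   objects legitimately settle near 0.95, capture failures far lower).
#' @param restart_scale perturbation half-range of restart initial poses
#'   (mm / degrees).
#' @param seed RNG seed for the restarts.
#' @export
registration_control <- function(max_evaluations = 2000, step_mm = 1,
                                 step_deg = 1, reltol = 1e-10, restarts = 3,
                                 restart_threshold = 0.9, restart_scale = 1,
                                 seed = 0L) {
  list(max_evaluations = max_evaluations, step_mm = step_mm,
       step_deg = step_deg, reltol = reltol, restarts = restarts,
       restart_threshold = restart_threshold, restart_scale = restart_scale,
       seed = as.integer(seed))
}

#' Rigidly register a double contour into a target image
#'
#' Nelder-Mead downhill-simplex maximisation of the gray-value correlation
#' over the 6-parameter rigid search space (tx, ty, tz, phix, phiy, phiz;
#' Euler sequence y, x, z). The optimizer works in degrees so translation
#' and rotation steps are comparably scaled, and parameterises the rotation
#' about the contour centroid to reduce translation-rotation coupling; the
#' returned matrix is centre-independent. The result is the absolute
#' displacement of the object between the segmentation image and the target
#' image.
#'
#' @param contour a `double_contour` built from the segmentation image.
#' @param target the target `ct_volume`.
#' @param init initial rigid transform (e.g. from `coarse_prealign`);
#'   at least 50% of the contour points must land inside the target.
#' @param control a `registration_control` list.
#' @return a `registration_result`: `transform`, `metric_value`,
#'   `iterations`, `converged`, `fraction_valid_samples`.
#' @export
register <- function(contour, target, init = rigid_identity(),
                     control = registration_control()) {
  stopifnot(inherits(contour, "double_contour"), inherits(target, "ct_volume"))
  assert_rigid(init)
  m0 <- metric_safe(contour, target, init)
  if (attr(m0, "fraction_valid") < 0.5)
    stop("initial pose places less than 50% of the contour inside the target")

  centroid <- colMeans(apply_transform(init, contour$base_points))
  Tc <- params_to_matrix(c(centroid, 0, 0, 0))
  Tci <- rigid_invert(Tc)
  make_M <- function(p)
    rigid_compose(Tc, params_to_matrix(p), Tci, init)
  neg_metric <- function(p)
    -as.numeric(metric_safe(contour, target, make_M(p)))

  run_from <- function(p0, scale = 1) {
    stats::optim(p0, neg_metric, method = "Nelder-Mead",
                 control = list(
                   maxit = control$max_evaluations,
                   reltol = control$reltol,
                   parscale = scale * 10 * c(rep(control$step_mm, 3),
                                             rep(control$step_deg, 3))))
  }
  best <- run_from(rep(0, 6))
  evals <- best$counts[1]
  n_restarts <- 0
  if (control$restarts > 0 && -best$value < control$restart_threshold) {
    perturbations <- with_local_seed(control$seed,
      replicate(control$restarts,
                stats::runif(6, -control$restart_scale,
                             control$restart_scale)))
    for (r in seq_len(control$restarts)) {
      if (-best$value >= control$restart_threshold) break
      cand <- run_from(perturbations[, r])
      evals <- evals + cand$counts[1]
      n_restarts <- n_restarts + 1
      if (cand$value < best$value) best <- cand
    }
  }
  # second-stage polish: restart the simplex at a tenth of the step size
  polish <- run_from(best$par, scale = 0.1)
  evals <- evals + polish$counts[1]
  if (polish$value < best$value) best <- polish
  M <- make_M(best$par)
  final <- metric_safe(contour, target, M)
  structure(list(transform = M,
                 metric_value = as.numeric(final),
                 iterations = as.integer(evals),
                 converged = best$convergence == 0,
                 restarts_used = n_restarts,
                 fraction_valid_samples = attr(final, "fraction_valid")),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  p <- matrix_to_params(x$transform)
  cat(sprintf(paste0("<registration_result> r = %.6f, %s, %d evaluations\n",
                     "  t = (%.3f, %.3f, %.3f) mm, ",
                     "phi = (%.3f, %.3f, %.3f) deg\n"),
              x$metric_value,
              if (x$converged) "converged" else "NOT converged",
              x$iterations, p[1], p[2], p[3], p[4], p[5], p[6]))
  invisible(x)
}

#' Coarse pre-alignment of a contour to a target image
#'
#' Specimens may be arbitrarily repositioned between acquisitions, which can
#' exceed the capture range of the correlation metric from an identity
#' start. This builds an initial pose from the supra-threshold voxel cloud
#' of the target: centroids are matched and the minimal rotation carrying
#' the contour's long principal axis onto the target's is applied; the
#' residual roll about the long axis is resolved by scoring a small set of
#' candidate roll angles with the correlation metric.
#'
#' @param contour a `double_contour` of the object to register (scores the
#'   roll candidates).
#' @param target the target `ct_volume`.
#' @param threshold intensity threshold defining the specimen voxel cloud
#'   (use the cortex threshold to capture bone plus implant).
#' @param source_volume the segmentation-image `ct_volume`; when given, the
#'   source cloud is its own supra-threshold voxel set, so source and
#'   target centroids refer to identical objects. Falls back to the contour
#'   base points otherwise (adequate only for closed dense contours).
#' @param roll_range,roll_step half-range and step (degrees) of the roll
#'   candidates about the long axis.
#' @return a rigid transform suitable as `init` for `register`.
#' @export
coarse_prealign <- function(contour, target, threshold, source_volume = NULL,
                            roll_range = 20, roll_step = 5) {
  stopifnot(inherits(contour, "double_contour"), inherits(target, "ct_volume"))
  cloud <- function(vol) {
    idx <- which(vol$data >= threshold, arr.ind = TRUE)
    if (nrow(idx) < 100) stop("too few supra-threshold voxels")
    index_to_world(vol, idx - 1)
  }
  pa_t <- principal_axes(cloud(target))
  pa_s <- if (!is.null(source_volume)) principal_axes(cloud(source_volume))
          else principal_axes(contour$base_points)
  a_s <- pa_s$axes[, 1]; a_t <- pa_t$axes[, 1]
  if (sum(a_s * a_t) < 0) a_t <- -a_t
  R <- rotation_between(a_s, a_t)
  M0 <- rigid_compose(
    params_to_matrix(c(pa_t$center, 0, 0, 0)),
    as_rigid(R),
    params_to_matrix(c(-pa_s$center, 0, 0, 0)))
  rolls <- seq(-roll_range, roll_range, by = roll_step)
  scores <- vapply(rolls, function(phi) {
    M <- rigid_compose(roll_about_axis(phi, a_t, pa_t$center), M0)
    as.numeric(metric_safe(contour, target, M))
  }, numeric(1))
  best <- rolls[which.max(scores)]
  rigid_compose(roll_about_axis(best, a_t, pa_t$center), M0)
}

# minimal rotation matrix carrying unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c0 <- sum(a * b)
  if (c0 < -1 + 1e-12) return(-diag(3))  # antipodal; unused in practice
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c0)
}

as_rigid <- function(R) {
  M <- diag(4); M[1:3, 1:3] <- R
  class(M) <- c("rigid_transform", "matrix", "array")
  M
}

# rotation by `deg` about unit `axis` through `center`
roll_about_axis <- function(deg, axis, center) {
  a <- deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  R <- diag(3) + sin(a) * ux + (1 - cos(a)) * ux %*% ux
  rigid_compose(params_to_matrix(c(center, 0, 0, 0)), as_rigid(R),
                params_to_matrix(c(-center, 0, 0, 0)))
}
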