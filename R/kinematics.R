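#' Relative displacement of two objects
#'
#' From the absolute displacement matrices `Mi` (object i) and `Mj`
#' (object j) between the two images, the relative displacement of object i
#' with respect to object j in the global (CT) coordinate system is
#' `M(i,j) = Mj^-1 Mi`. Applying one extra rigid transform to both absolute
#' motions leaves `M(i,j)` unchanged, which is why the measurement tolerates
#' arbitrary specimen repositioning between scans.
#'
#' @param Mi,Mj rigid 4x4 absolute displacement matrices.
#' @return the rigid relative displacement matrix.
#' @export
relative_displacement <- function(Mi, Mj) {
  assert_rigid(Mi); assert_rigid(Mj)
  M <- rigid_compose(rigid_invert(Mj), Mi)
  # numerical cleanup only; composition of rigids is rigid
  M[4, ] <- c(0, 0, 0, 1)
  M
}

#' Automatic implant local coordinate system
#'
#' Casts a regular axial grid of rays from above the implant mesh; the
#' first intersections form the plateau point set. The origin is the
#' centroid of these points; the inertia tensor of the point set about the
#' centroid gives the axes: the largest-eigenvalue eigenvector is the
#' plateau normal (z, oriented proximally), the smallest-eigenvalue
#' eigenvector is the medial-lateral axis (x, signed toward the lateral
#' side according to `side`), and y = z x x (posterior-anterior). `M_CS`
#' transforms the global CS to the local CS (its columns are the axes, its
#' translation the origin).
#'
#' @param implant_mesh `surface_mesh` of the implant, with an upward-facing
#'   plateau.
#' @param side `"left"` or `"right"` leg; resolves the lateral sign of the
#'   x-axis (lateral has positive global-x component for a right leg,
#'   negative for a left leg).
#' @param grid_spacing ray-grid spacing in mm (defaults to the CT voxel
#'   spacing scale, 0.45 mm at full resolution).
#' @param min_hits minimum number of plateau ray hits.
#' @return an object of class `local_cs`: `M_CS`, `origin`, `axes`
#'   (columns x, y, z), `plateau_points`.
#' @export
build_local_cs <- function(implant_mesh, side = c("right", "left"),
                           grid_spacing = 0.9, min_hits = 50) {
  side <- match.arg(side)
  stopifnot(inherits(implant_mesh, "surface_mesh"))
  hits <- plateau_raycast(implant_mesh, grid_spacing)
  if (nrow(hits) < min_hits)
    stop("fewer than ", min_hits, " plateau ray hits")
  origin <- colMeans(hits)
  cc <- sweep(hits, 2, origin)
  # inertia tensor of a unit-mass point set about the centroid
  I3 <- diag(3) * sum(cc^2) - crossprod(cc)
  ev <- eigen(I3, symmetric = TRUE)  # values descending
  if (ev$values[3] / ev$values[2] > 0.95)
    stop("ambiguous plateau axes: in-plane inertia eigenvalues nearly equal")
  zax <- ev$vectors[, 1]
  if (zax[3] < 0) zax <- -zax        # proximal = +axial
  xax <- ev$vectors[, 3]
  xax <- xax - sum(xax * zax) * zax  # in-plane
  xax <- xax / sqrt(sum(xax^2))
  lateral_sign <- if (side == "right") 1 else -1
  if (sign(xax[1]) != lateral_sign) xax <- -xax
  yax <- c(zax[2] * xax[3] - zax[3] * xax[2],
           zax[3] * xax[1] - zax[1] * xax[3],
           zax[1] * xax[2] - zax[2] * xax[1])
  M <- diag(4)
  M[1:3, 1:3] <- cbind(xax, yax, zax)
  M[1:3, 4] <- origin
  class(M) <- c("rigid_transform", "matrix", "array")
  structure(list(M_CS = M, origin = origin,
                 axes = cbind(x = xax, y = yax, z = zax),
                 plateau_points = hits),
            class = "local_cs")
}

#' @export
print.local_cs <- function(x, ...) {
  cat(sprintf("<local_cs> origin (%s) mm, %d plateau points\n",
              paste(signif(x$origin, 4), collapse = ", "),
              nrow(x$plateau_points)))
  invisible(x)
}

# first intersections of downward axial rays with the mesh: per upward-facing
# triangle, rasterize the contained (x, y) grid nodes and keep the highest z
plateau_raycast <- function(mesh, grid_spacing) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  ce <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- ce - a
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]  # z of face normal (pre-orient)
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3], nz)
  # faces within ~72 deg of horizontal; winding-agnostic since the
  # highest intersection per ray wins anyway
  up <- which(abs(nz) > 1e-9 & abs(fn[, 3]) / sqrt(rowSums(fn^2)) > 0.3)
  gx <- seq(min(v[, 1]), max(v[, 1]), by = grid_spacing)
  gy <- seq(min(v[, 2]), max(v[, 2]), by = grid_spacing)
  zbuf <- matrix(-Inf, length(gx), length(gy))
  for (t in up) {
    xi <- which(gx >= min(a[t, 1], b[t, 1], ce[t, 1]) &
                  gx <= max(a[t, 1], b[t, 1], ce[t, 1]))
    yi <- which(gy >= min(a[t, 2], b[t, 2], ce[t, 2]) &
                  gy <= max(a[t, 2], b[t, 2], ce[t, 2]))
    if (!length(xi) || !length(yi)) next
    px <- rep(gx[xi], times = length(yi)) - a[t, 1]
    py <- rep(gy[yi], each = length(xi)) - a[t, 2]
    d <- nz[t]
    u <- (px * e2[t, 2] - py * e2[t, 1]) / d
    w <- (py * e1[t, 1] - px * e1[t, 2]) / d
    inside <- u >= -1e-9 & w >= -1e-9 & u + w <= 1 + 1e-9
    if (!any(inside)) next
    z <- a[t, 3] + u * e1[t, 3] + w * e2[t, 3]
    sel <- cbind(rep(xi, times = length(yi)),
                 rep(yi, each = length(xi)))[inside, , drop = FALSE]
    zin <- z[inside]
    cur <- zbuf[sel]
    upd <- zin > cur
    zbuf[sel[upd, , drop = FALSE]] <- zin[upd]
  }
  hit <- which(is.finite(zbuf), arr.ind = TRUE)
  cbind(gx[hit[, 1]], gy[hit[, 2]], zbuf[hit])
}

#' Express a relative displacement in the implant local coordinate system
#'
#' `M_local = M_CS^-1 M M_CS`: exact conjugation of the global relative
#' displacement into the local frame. Conjugation preserves the rotation
#' angle and the translation magnitude.
#'
#' @param M rigid relative displacement in the global CS.
#' @param cs a `local_cs`.
#' @return the rigid transform expressed in the local CS.
#' @export
to_local <- function(M, cs) {
  assert_rigid(M)
  stopifnot(inherits(cs, "local_cs"))
  rigid_compose(rigid_invert(cs$M_CS), M, cs$M_CS)
}

#' Decompose a local-frame displacement into parameters and magnitudes
#'
#' Derives the three translation parameters (dx, dy, dz, mm) along and the
#' three rotation parameters (dphix, dphiy, dphiz, degrees) about the local
#' axes (Euler sequence y, x, z), plus the root-sum-square translation and
#' rotation magnitudes. When implant points are supplied, also computes the
#' mean target registration error (mTRE, the mean per-point displacement)
#' and the maximum total point motion (MTPM, the largest per-point
#' displacement) under the corresponding global-frame displacement.
#'
#' @param M_local rigid displacement expressed in the local CS.
#' @param pair label of the object pair (e.g. `"implant-vs-prox"`).
#' @param points optional n x 3 implant points (global frame, mm) for
#'   mTRE/MTPM.
#' @param M_global the global-frame displacement corresponding to `M_local`
#'   (required with `points`).
#' @return an object of class `displacement_result`.
#' @export
decompose <- function(M_local, pair = NA_character_, points = NULL,
                      M_global = NULL) {
  p <- matrix_to_params(M_local)
  res <- list(
    pair = pair,
    dx = p[["tx"]], dy = p[["ty"]], dz = p[["tz"]],
    dphix = p[["phix"]], dphiy = p[["phiy"]], dphiz = p[["phiz"]],
    translation_magnitude = sqrt(sum(p[1:3]^2)),
    rotation_magnitude = sqrt(sum(p[4:6]^2)),
    mTRE = NA_real_, MTPM = NA_real_,
    gimbal = isTRUE(attr(p, "gimbal")))
  if (!is.null(points)) {
    if (is.null(M_global))
      stop("points given without the matching global-frame displacement")
    res$mTRE <- mtre(points, M_global)
    res$MTPM <- mtpm(points, M_global)
  }
  structure(res, class = "displacement_result")
}

#' @export
print.displacement_result <- function(x, ...) {
  cat(sprintf(paste0("<displacement_result> %s\n",
                     "  t = (%.3f, %.3f, %.3f) mm  |t| = %.3f mm\n",
                     "  phi = (%.3f, %.3f, %.3f) deg  |phi| = %.3f deg\n"),
              x$pair, x$dx, x$dy, x$dz, x$translation_magnitude,
              x$dphix, x$dphiy, x$dphiz, x$rotation_magnitude))
  if (!is.na(x$mTRE))
    cat(sprintf("  mTRE = %.3f mm, MTPM = %.3f mm\n", x$mTRE, x$MTPM))
  invisible(x)
}

#' @export
as.data.frame.displacement_result <- function(x, ...) {
  data.frame(pair = x$pair, dx = x$dx, dy = x$dy, dz = x$dz,
             dphix = x$dphix, dphiy = x$dphiy, dphiz = x$dphiz,
             translation_magnitude = x$translation_magnitude,
             rotation_magnitude = x$rotation_magnitude,
             mTRE = x$mTRE, MTPM = x$MTPM)
}
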