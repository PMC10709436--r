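#' Threshold-connected region growing
#'
#' Extracts the 26-connected component of supra-threshold voxels containing
#' the seed. Empirically chosen thresholds of about 1600 (tibia cortex) and
#' 3500 (implant) separate the objects in CT-like intensity units.
#'
#' @param volume a `ct_volume`.
#' @param seed_point world (mm) position of a voxel inside the object.
#' @param threshold inclusion threshold (voxels with intensity >= threshold).
#' @return logical mask array with the volume's dimensions.
#' @export
region_grow <- function(volume, seed_point, threshold) {
  stopifnot(inherits(volume, "ct_volume"))
  idx <- round(world_to_index(volume, seed_point)) + 1
  idx <- as.integer(idx)
  dims <- dim(volume$data)
  if (any(idx < 1) || any(idx > dims)) stop("seed point outside the volume")
  if (volume$data[idx[1], idx[2], idx[3]] < threshold)
    stop("seed voxel intensity is below the threshold")
  mask <- volume$data >= threshold
  cpp_flood_fill(mask, dims, idx)
}

#' Laplacian level-set refinement of a segmentation
#'
#' Evolves the mask boundary towards zero crossings of the (smoothed) image
#' Laplacian - i.e. towards intensity edges - under mean-curvature
#' regularisation. Intended to refine a region-growing result whose boundary
#' already lies within a voxel or two of the true edge. The output must
#' overlap the input (Dice > `min_dice`) as a sanity bound.
#'
#' @param volume a `ct_volume`.
#' @param mask logical array, the initial segmentation (non-empty).
#' @param iterations number of evolution steps; 0 returns the mask unchanged.
#' @param curvature_weight weight of the curvature regulariser.
#' @param propagation_weight weight of the Laplacian edge term.
#' @param smoothing_passes binomial pre-smoothing passes applied to the image
#'   before taking its Laplacian.
#' @param dt time step (voxel units; keep <= 0.25 for stability).
#' @param min_dice sanity lower bound on Dice(output, input).
#' @return refined logical mask.
#' @export
levelset_refine <- function(volume, mask, iterations = 50,
                            curvature_weight = 0.2, propagation_weight = 1,
                            smoothing_passes = 1, dt = 0.2, min_dice = 0.8) {
  stopifnot(inherits(volume, "ct_volume"), is.logical(mask),
            all(dim(mask) == dim(volume$data)))
  if (!any(mask)) stop("initial mask is empty")
  if (iterations == 0) return(mask)
  # evolve on the mask bounding box only: the narrow band cannot leave it
  bb <- mask_bbox(mask, margin = iterations + 5)
  sub_img <- volume$data[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  sub_mask <- mask[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  phi <- cpp_levelset_evolve(sub_img, sub_mask, dim(sub_mask),
                             as.integer(iterations), curvature_weight,
                             propagation_weight, as.integer(smoothing_passes),
                             dt)
  out <- array(FALSE, dim(mask))
  out[bb[[1]], bb[[2]], bb[[3]]] <- phi < 0
  if (!any(out)) stop("level set collapsed to the empty set")
  d <- dice(out, mask)
  if (d < min_dice)
    stop(sprintf("refined mask diverged from input (Dice %.2f < %.2f)",
                 d, min_dice))
  out
}

#' Dice overlap of two masks
#' @param a,b logical arrays of equal dimension.
#' @export
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# index ranges of the mask bounding box, padded by `margin` voxels
mask_bbox <- function(mask, margin = 0) {
  idx <- which(mask, arr.ind = TRUE)
  d <- dim(mask)
  lapply(1:3, function(ax)
    max(1, min(idx[, ax]) - margin):min(d[ax], max(idx[, ax]) + margin))
}

#' Extract a surface mesh from a binary mask
#'
#' Marching-cubes style iso-surfacing of the mask at level 0.5, using a
#' tetrahedral cell decomposition (watertight, no ambiguous cases). The mask
#' is padded with background so objects touching the grid boundary still
#' yield closed surfaces. Vertices are in world mm; per-vertex normals are
#' area-weighted face normals, oriented outward.
#'
#' @param mask logical (or numeric) 3D array.
#' @param spacing voxel spacing (mm), scalar or length 3.
#' @param origin world position of the first voxel centre.
#' @param level iso-level (0.5 for binary masks).
#' @return a `surface_mesh`.
#' @export
extract_mesh <- function(mask, spacing = 1, origin = c(0, 0, 0), level = 0.5) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  field <- mask * 1.0
  if (!any(field > level)) stop("mask is empty: no surface to extract")
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  d <- dim(field)
  padded <- array(0, d + 2)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- field
  res <- cpp_isosurface(padded, dim(padded), level)
  # padded index -> original 0-based index -> world
  verts <- sweep(res$vertices, 2, c(1, 1, 1))
  verts <- sweep(sweep(verts, 2, spacing, `*`), 2, origin, `+`)
  surface_mesh(verts, res$faces)
}

#' @rdname extract_mesh
#' @param volume a `ct_volume` whose mask is meshed in its world frame.
#' @export
extract_mesh_volume <- function(volume, mask, level = 0.5) {
  if (!any(mask)) stop("mask is empty: no surface to extract")
  bb <- mask_bbox(mask, margin = 1)
  extract_mesh(mask[bb[[1]], bb[[2]], bb[[3]], drop = FALSE],
               spacing = volume$spacing,
               origin = volume$origin +
                 (vapply(bb, min, 1) - 1) * volume$spacing,
               level = level)
}

#' Build the double-contour registration feature
#'
#' Samples the (valgus) gray-level image at +0.3 mm and -0.3 mm along the
#' surface normal of each mesh vertex; the resulting paired offset point
#' sets with their stored reference gray values are the feature that is
#' matched into the second image by correlation.
#'
#' @param volume the segmentation-image `ct_volume`.
#' @param mesh the object's `surface_mesh` (in the same world frame).
#' @param offset normal offset in mm.
#' @param max_points optional cap on the number of mesh vertices used
#'   (deterministic even subsampling); `Inf` keeps all.
#' @param max_invalid_fraction error threshold on out-of-volume samples.
#' @return an object of class `double_contour` with `base_points`,
#'   `outer_points`, `inner_points` and `reference_grays` (outer then inner).
#' @export
build_double_contour <- function(volume, mesh, offset = 0.3,
                                 max_points = Inf,
                                 max_invalid_fraction = 0.05) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mesh, "surface_mesh"))
  v <- mesh$vertices; n <- mesh$normals
  if (is.finite(max_points) && nrow(v) > max_points) {
    keep <- unique(round(seq(1, nrow(v), length.out = max_points)))
    v <- v[keep, , drop = FALSE]; n <- n[keep, , drop = FALSE]
  }
  outer <- v + offset * n
  inner <- v - offset * n
  so <- trilinear_sample(volume, outer)
  si <- trilinear_sample(volume, inner)
  ok <- so$valid & si$valid
  if (mean(!ok) > max_invalid_fraction)
    stop(sprintf("%.1f%% of contour samples fall outside the volume",
                 100 * mean(!ok)))
  structure(list(base_points = v[ok, , drop = FALSE],
                 outer_points = outer[ok, , drop = FALSE],
                 inner_points = inner[ok, , drop = FALSE],
                 reference_grays = c(so$values[ok], si$values[ok]),
                 offset = offset),
            class = "double_contour")
}

#' @export
print.double_contour <- function(x, ...) {
  cat(sprintf("<double_contour> %d base points (+/- %.2f mm offsets)\n",
              nrow(x$base_points), x$offset))
  invisible(x)
}

#' Clip a tibia mesh into proximal and distal segments
#'
#' The long axis is the principal axis of the vertex distribution. Tibia
#' length is measured from the implant-plateau level (the maximal axial
#' position of the implant mesh when supplied, otherwise the most proximal
#' vertex) down to the most distal vertex. The proximal segment collects
#' vertices within the top `fraction` of that length, the distal segment the
#' bottom `fraction`; cut planes are perpendicular to the long axis. The
#' whole tibia (everything below the plateau) is returned unchanged.
#'
#' @param mesh the tibia `surface_mesh`.
#' @param fraction end-segment fraction of the length, in (0, 0.5].
#' @param implant_mesh optional implant `surface_mesh` defining the plateau
#'   level.
#' @return list with `proximal`, `distal`, `whole` (`surface_mesh`es),
#'   `axis`, `length` and `plateau_level` (axial coordinate).
#' @export
clip_segments <- function(mesh, fraction = 0.20, implant_mesh = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (fraction <= 0 || fraction > 0.5)
    stop("fraction must be in (0, 0.5]")
  pa <- principal_axes(mesh$vertices)
  if (pa$sdev[1] < 2 * pa$sdev[2])
    stop("mesh is not elongated: longest principal extent < 2x the next")
  axis <- pa$axes[, 1]
  if (sum(axis * c(0, 0, 1)) < 0) axis <- -axis  # axial = +z-ish
  proj <- drop(mesh$vertices %*% axis)
  top <- if (!is.null(implant_mesh))
    max(implant_mesh$vertices %*% axis) else max(proj)
  bottom <- min(proj)
  len <- top - bottom
  eps <- 1e-9 * max(1, abs(len))  # cut-plane tolerance
  list(proximal = mesh_subset(mesh, proj >= top - fraction * len - eps),
       distal = mesh_subset(mesh, proj <= bottom + fraction * len + eps),
       whole = mesh, axis = axis, length = len, plateau_level = top)
}
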