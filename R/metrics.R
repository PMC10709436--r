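#' Maximum total point motion (MTPM)
#'
#' The motion in millimetres of the point that migrates the most: the
#' maximum over the points of `|M p - p|`. A standard scalar migration
#' measure in RSA studies; it scales with object size under pure rotation.
#'
#' @param points n x 3 matrix of object points (mm), n >= 1.
#' @param M rigid displacement.
#' @return MTPM in mm.
#' @export
mtpm <- function(points, M) {
  d <- point_displacements(points, M)
  max(d)
}

#' Mean target registration error (mTRE)
#'
#' The mean distance between the initial (segmented) and displaced
#' positions of the object points: the average absolute translation of the
#' points under `M`. Always `mtre <= mtpm`, with equality under pure
#' translation.
#'
#' @inheritParams mtpm
#' @return mTRE in mm.
#' @export
mtre <- function(points, M) {
  d <- point_displacements(points, M)
  mean(d)
}

point_displacements <- function(points, M) {
  points <- rbind_points(points)
  if (nrow(points) < 1) stop("need at least one point")
  assert_rigid(M)
  sqrt(rowSums((apply_transform(M, points) - points)^2))
}

#' Nearest-neighbour surface distance (heatmap values)
#'
#' For each vertex of `mesh_a`, the Euclidean distance to the nearest
#' vertex of `mesh_b` - the per-vertex scalar rendered as a deformation
#' heatmap (e.g. between the valgus and varus tibia segmentations after
#' aligning their distal segments). Vertex-to-vertex by default;
#' `to_triangles = TRUE` refines each distance to the nearest point on the
#' triangles incident to the nearest vertex.
#'
#' @param mesh_a,mesh_b `surface_mesh`es.
#' @param to_triangles refine to point-to-triangle distances.
#' @return numeric vector, one distance (mm) per vertex of `mesh_a`.
#' @export
surface_distance <- function(mesh_a, mesh_b, to_triangles = FALSE) {
  stopifnot(inherits(mesh_a, "surface_mesh"), inherits(mesh_b, "surface_mesh"))
  nn <- RANN::nn2(mesh_b$vertices, mesh_a$vertices, k = 1)
  d <- nn$nn.dists[, 1]
  if (to_triangles) {
    f <- mesh_b$faces
    inc <- split(rep(seq_len(nrow(f)), 3), as.vector(f))
    for (i in seq_len(nrow(mesh_a$vertices))) {
      tris <- inc[[as.character(nn$nn.idx[i, 1])]]
      for (t in tris) {
        dt <- point_triangle_distance(mesh_a$vertices[i, ],
                                      mesh_b$vertices[f[t, 1], ],
                                      mesh_b$vertices[f[t, 2], ],
                                      mesh_b$vertices[f[t, 3], ])
        if (dt < d[i]) d[i] <- dt
      }
    }
  }
  d
}

# distance from point p to triangle (a, b, c) by projection + edge clamping
point_triangle_distance <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum(ap^2)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum(bp^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(sqrt(sum((p - (a + v * ab))^2)))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum(cp^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6)
    return(sqrt(sum((p - (a + w * ac))^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - (b + w * (c - b)))^2)))
  }
  denom <- 1 / (va + vb + vc)
  v <- vb * denom; w <- vc * denom
  sqrt(sum((p - (a + v * ab + w * ac))^2))
}

#' Symmetric Hausdorff distance between two vertex clouds
#' @param mesh_a,mesh_b `surface_mesh`es.
#' @export
hausdorff_distance <- function(mesh_a, mesh_b) {
  max(max(surface_distance(mesh_a, mesh_b)),
      max(surface_distance(mesh_b, mesh_a)))
}
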