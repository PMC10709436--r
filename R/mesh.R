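#' Triangulated surface mesh
#'
#' Vertices are world coordinates in mm; faces index vertices (1-based,
#' consistent outward winding); per-vertex normals are unit vectors obtained
#' by area-weighted averaging of incident face normals.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of vertex indices.
#' @param normals optional n x 3 matrix of unit vertex normals; computed from
#'   the faces when omitted.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- rbind_points(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("faces index vertices out of range")
  if (is.null(normals)) normals <- vertex_normals(vertices, faces)
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Area-weighted per-vertex normals (unit length). Face winding determines
# orientation; marching-cubes faces are wound outward.
vertex_normals <- function(vertices, faces) {
  n <- matrix(0, nrow(vertices), 3)
  if (nrow(faces) > 0) {
    a <- vertices[faces[, 1], , drop = FALSE]
    e1 <- vertices[faces[, 2], , drop = FALSE] - a
    e2 <- vertices[faces[, 3], , drop = FALSE] - a
    fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # 2*area weighted
    for (c in 1:3) {
      for (d in 1:3) {
        acc <- rowsum(fn[, d], faces[, c])
        ids <- as.integer(rownames(acc))
        n[ids, d] <- n[ids, d] + acc
      }
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Rigidly transform a mesh
#'
#' @param mesh a `surface_mesh`.
#' @param M rigid 4x4 transform.
#' @return the transformed `surface_mesh` (normals rotated).
#' @export
transform_mesh <- function(mesh, M) {
  assert_rigid(M)
  surface_mesh(apply_transform(M, mesh$vertices), mesh$faces,
               normals = mesh$normals %*% t(M[1:3, 1:3]))
}

#' Mesh Euler characteristic (V - E + F)
#'
#' Edges are counted once per unordered vertex pair. A closed surface of
#' genus 0 has Euler characteristic 2.
#' @param mesh a `surface_mesh`.
#' @export
euler_characteristic <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ne <- nrow(unique(e))
  nrow(mesh$vertices) - ne + nrow(f)
}

#' Write / read a mesh as ASCII PLY
#'
#' Optionally stores one per-vertex scalar (e.g. a surface-distance heatmap)
#' as a `quality` property.
#' @param mesh a `surface_mesh`.
#' @param path file path.
#' @param scalar optional numeric per-vertex attribute.
#' @export
write_ply <- function(mesh, path, scalar = NULL) {
  nv <- nrow(mesh$vertices)
  has_s <- !is.null(scalar)
  if (has_s) stopifnot(length(scalar) == nv)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           "property float nx", "property float ny", "property float nz",
           if (has_s) "property float quality",
           sprintf("element face %d", nrow(mesh$faces)),
           "property list uchar int vertex_indices",
           "end_header")
  vmat <- cbind(mesh$vertices, mesh$normals, if (has_s) scalar)
  vlines <- apply(format(vmat, trim = TRUE, digits = 9), 1, paste,
                  collapse = " ")
  flines <- paste(3, mesh$faces[, 1] - 1, mesh$faces[, 2] - 1,
                  mesh$faces[, 3] - 1)
  writeLines(c(hdr, vlines, flines), path)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  stopifnot(lines[1] == "ply")
  end <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vprops <- grep("^property float", lines[1:end], value = TRUE)
  vrows <- do.call(rbind, lapply(strsplit(lines[(end + 1):(end + nv)], " "),
                                 as.numeric))
  frows <- do.call(rbind, lapply(strsplit(lines[(end + nv + 1):(end + nv + nf)],
                                          " "), as.integer))
  mesh <- surface_mesh(vrows[, 1:3, drop = FALSE],
                       frows[, 2:4, drop = FALSE] + 1L,
                       normals = if (length(vprops) >= 6)
                         vrows[, 4:6, drop = FALSE])
  if (length(vprops) >= 7) attr(mesh, "scalar") <- vrows[, 7]
  mesh
}

#' Write a mesh as ASCII STL
#' @param mesh a `surface_mesh`.
#' @param path file path.
#' @param name solid name in the STL header.
#' @export
write_stl <- function(mesh, path, name = "surface") {
  f <- mesh$faces
  a <- mesh$vertices[f[, 1], , drop = FALSE]
  b <- mesh$vertices[f[, 2], , drop = FALSE]
  ce <- mesh$vertices[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- ce - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  fn <- fn / pmax(sqrt(rowSums(fn^2)), 1e-12)
  fmt <- function(m) apply(format(m, trim = TRUE, digits = 9), 1, paste,
                           collapse = " ")
  out <- c(sprintf("solid %s", name),
           as.vector(rbind(paste("facet normal", fmt(fn)),
                           "  outer loop",
                           paste("    vertex", fmt(a)),
                           paste("    vertex", fmt(b)),
                           paste("    vertex", fmt(ce)),
                           "  endloop",
                           "endfacet")),
           sprintf("endsolid %s", name))
  writeLines(out, path)
  invisible(path)
}

#' Subset a mesh to a vertex set
#'
#' Keeps the flagged vertices and the faces whose three corners survive;
#' vertex indices are remapped and per-vertex normals carried over.
#' @param mesh a `surface_mesh`.
#' @param keep logical vector over vertices.
#' @export
mesh_subset <- function(mesh, keep) {
  idx <- which(keep)
  remap <- match(seq_len(nrow(mesh$vertices)), idx)
  f <- mesh$faces
  ok <- keep[f[, 1]] & keep[f[, 2]] & keep[f[, 3]]
  surface_mesh(mesh$vertices[idx, , drop = FALSE],
               cbind(remap[f[ok, 1]], remap[f[ok, 2]], remap[f[ok, 3]]),
               normals = mesh$normals[idx, , drop = FALSE])
}

#' Principal axes of a vertex cloud
#'
#' Eigen-decomposition of the vertex covariance; the first axis is the
#' direction of largest extent (the long axis of an elongated bone).
#' @param pts n x 3 matrix.
#' @return list with `center`, `axes` (columns, descending extent) and
#'   `sdev` (square roots of the eigenvalues).
#' @keywords internal
#' @export
principal_axes <- function(pts) {
  pts <- rbind_points(pts)
  ctr <- colMeans(pts)
  cc <- sweep(pts, 2, ctr)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  list(center = ctr, axes = ev$vectors, sdev = sqrt(pmax(ev$values, 0)))
}
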