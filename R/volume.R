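#' CT volume container
#'
#' A `ct_volume` is a 3D scalar intensity grid with physical voxel spacing
#' and world origin (both mm). World coordinates of voxel `(i, j, k)`
#' (1-based) are `origin + (c(i, j, k) - 1) * spacing`: the affine
#' world-to-index map is diagonal and invertible. The internal world frame
#' is right-handed with the axial (distoproximal) direction along +z.
#'
#' @param data 3D numeric array of intensities (finite).
#' @param spacing voxel spacing in mm, scalar (isotropic) or length 3.
#' @param origin world position (mm) of the first voxel centre, length 3.
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing = 0.45, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(length(spacing) == 3, all(spacing > 0), length(origin) == 3,
            all(is.finite(origin)))
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, origin (%s) mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' Convert between world (mm) and continuous 0-based index coordinates
#'
#' @param volume a `ct_volume`.
#' @param pts n x 3 matrix (or 3-vector) of points.
#' @return n x 3 matrix.
#' @keywords internal
#' @export
world_to_index <- function(volume, pts) {
  pts <- rbind_points(pts)
  sweep(sweep(pts, 2, volume$origin, `-`), 2, volume$spacing, `/`)
}

#' @rdname world_to_index
#' @export
index_to_world <- function(volume, pts) {
  pts <- rbind_points(pts)
  sweep(sweep(pts, 2, volume$spacing, `*`), 2, volume$origin, `+`)
}

#' Read / write a CT volume (NIfTI or MetaImage)
#'
#' Formats are selected by extension: `.nii` / `.nii.gz` (NIfTI, via RNifti)
#' or `.mha` (MetaImage, uncompressed, local raw data). World coordinates
#' (spacing + origin) survive a round trip. Non-isotropic spacing triggers a
#' warning since the downstream pipeline assumes near-isotropic voxels.
#'
#' @param path file path.
#' @return a `ct_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::readNifti(path)
    aff <- RNifti::xform(img)
    vol <- ct_volume(as.array(img) * 1.0,
                     spacing = RNifti::pixdim(img)[1:3],
                     origin = aff[1:3, 4])
  } else if (grepl("\\.mha$", lp)) {
    vol <- read_mha(path)
  } else {
    stop("unknown volume format (expect .nii, .nii.gz or .mha): ", path)
  }
  if (max(vol$spacing) / min(vol$spacing) > 1.001)
    warning("anisotropic voxel spacing: ", paste(vol$spacing, collapse = " x "))
  vol
}

#' @rdname read_volume
#' @param volume a `ct_volume`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::asNifti(volume$data)
    RNifti::pixdim(img) <- volume$spacing
    aff <- diag(4)
    diag(aff)[1:3] <- volume$spacing
    aff[1:3, 4] <- volume$origin
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.mha$", lp)) {
    write_mha(volume, path)
  } else {
    stop("unknown volume format (expect .nii, .nii.gz or .mha): ", path)
  }
  invisible(path)
}

# Minimal MetaImage (.mha) I/O: ASCII header + local uncompressed raw.
read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("truncated MetaImage header")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("only LOCAL MetaImage data supported")
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]])
  origin <- if (!is.null(hdr[["Offset"]]))
    as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]]) else c(0, 0, 0)
  type <- hdr[["ElementType"]]
  n <- prod(dims)
  vals <- switch(type,
    MET_DOUBLE = readBin(con, "double", n, size = 8, endian = "little"),
    MET_FLOAT = readBin(con, "double", n, size = 4, endian = "little"),
    MET_SHORT = readBin(con, "integer", n, size = 2, signed = TRUE,
                        endian = "little"),
    stop("unsupported ElementType: ", type))
  ct_volume(array(as.numeric(vals), dim = dims), spacing, origin)
}

write_mha <- function(volume, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %s", paste(dim(volume$data), collapse = " ")),
    sprintf("ElementSpacing = %s", paste(volume$spacing, collapse = " ")),
    sprintf("Offset = %s", paste(volume$origin, collapse = " ")),
    "ElementType = MET_DOUBLE",
    "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  writeBin(as.vector(volume$data), con, size = 8, endian = "little")
  invisible(path)
}

#' Trilinear interpolation of a volume at world points
#'
#' Samples the gray-level image at arbitrary world (mm) positions by
#' trilinear interpolation. Points whose 8-neighbourhood is not fully inside
#' the grid are flagged invalid (value `NA`) rather than extrapolated or
#' clamped, so boundary poses do not bias downstream metrics.
#'
#' @param volume a `ct_volume`.
#' @param points n x 3 matrix of world coordinates (mm).
#' @return list with `values` (numeric, `NA` where invalid) and `valid`
#'   (logical).
#' @export
trilinear_sample <- function(volume, points) {
  stopifnot(inherits(volume, "ct_volume"))
  idx <- world_to_index(volume, points)
  cpp_trilinear(volume$data, dim(volume$data), idx)
}
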