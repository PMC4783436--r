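# CT-like scalar volumes on a regular grid, with NIfTI and raw+JSON I/O.

#' Voxel volume (regular scalar grid)
#'
#' A scalar intensity field on a regular, axis-aligned 3D grid. The world
#' coordinate of voxel index `(i, j, k)` (0-based, node-centered) is
#' `origin + (i, j, k) * spacing`.
#'
#' @param intensities 3D numeric array.
#' @param origin world coordinate (mm) of voxel (0, 0, 0).
#' @param spacing voxel spacing (mm), strictly positive per axis.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(intensities, origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3) {
    os_abort("intensities must be a 3D array", "invalid_argument")
  }
  stopifnot_finite(origin, "origin")
  stopifnot_finite(spacing, "spacing")
  if (length(origin) != 3 || length(spacing) != 3 || any(spacing <= 0)) {
    os_abort("origin/spacing must be length-3 with spacing > 0", "invalid_argument")
  }
  structure(list(intensities = intensities, origin = as.numeric(origin),
                 spacing = as.numeric(spacing)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<voxel_volume> %d x %d x %d, spacing %.3g/%.3g/%.3g mm, origin (%.3g, %.3g, %.3g)\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' World coordinates of voxel indices
#' @param vol a `voxel_volume`.
#' @param idx N x 3 matrix of 0-based voxel indices.
#' @return N x 3 matrix of world coordinates (mm).
#' @export
voxel_to_world <- function(vol, idx) {
  stopifnot(inherits(vol, "voxel_volume"))
  idx <- as.matrix(idx)
  sweep(sweep(idx, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

# coordinate vectors along each axis
axis_coords <- function(vol) {
  d <- dim(vol$intensities)
  lapply(1:3, function(a) vol$origin[a] + (0:(d[a] - 1L)) * vol$spacing[a])
}

#' Write / read a voxel volume
#'
#' Two on-disk formats are supported, chosen by extension: NIfTI
#' (`.nii` / `.nii.gz`, spacing and origin carried in the sform) and raw
#' little-endian float32 (`.raw`) with a JSON sidecar (`<stem>.json`)
#' recording shape, spacing, origin and storage order.
#'
#' @param vol a `voxel_volume`.
#' @param path output path ending in `.nii`, `.nii.gz` or `.raw`.
#' @return `write_volume`: the path, invisibly; `read_volume`: a
#'   `voxel_volume`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    im <- RNifti::asNifti(vol$intensities, datatype = "float")
    m <- diag(c(vol$spacing, 1))
    m[1:3, 4] <- vol$origin
    im <- RNifti::`sform<-`(im, structure(m, code = 2L))
    RNifti::writeNifti(im, path)
  } else if (grepl("\\.raw$", path)) {
    con <- file(path, "wb")
    writeBin(as.numeric(vol$intensities), con, size = 4, endian = "little")
    close(con)
    meta <- list(shape = dim(vol$intensities), spacing = vol$spacing,
                 origin = vol$origin, dtype = "float32",
                 order = "column-major (i fastest)")
    jsonlite::write_json(meta, sub("\\.raw$", ".json", path), digits = NA,
                         auto_unbox = TRUE)
  } else {
    os_abort("unsupported volume extension (use .nii, .nii.gz or .raw)",
             "invalid_argument")
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    im <- RNifti::readNifti(path)
    m <- RNifti::xform(im)
    arr <- as.array(im)
    voxel_volume(arr, origin = m[1:3, 4], spacing = diag(m)[1:3])
  } else if (grepl("\\.raw$", path)) {
    meta <- jsonlite::fromJSON(sub("\\.raw$", ".json", path))
    n <- prod(meta$shape)
    con <- file(path, "rb")
    x <- readBin(con, "double", n = n, size = 4, endian = "little")
    close(con)
    voxel_volume(array(x, dim = meta$shape), origin = meta$origin,
                 spacing = meta$spacing)
  } else {
    os_abort("unsupported volume extension (use .nii, .nii.gz or .raw)",
             "invalid_argument")
  }
}
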