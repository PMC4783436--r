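# Virtual cephalometric image: perspective projection of the 3D model with
# explicit X-ray source, head (ear-rod axis) and film geometry, as in a
# conventional cephalostat.

#' Projection geometry for the virtual cephalogram
#'
#' Describes the cephalostat: X-ray point source, film plane (point,
#' normal, two in-plane axes) and the ear-rod axis through the head. In the
#' standard lateral setup the central ray runs along the ear-rod axis, so
#' the axis is parallel to the film normal; the film origin is placed where
#' the central ray (source through ear-rod midpoint) meets the film.
#'
#' Defaults use conventional cephalostat values: source-to-ear-rod
#' 1500 mm and ear-rod-to-film 150 mm, with a lateral (left-to-right,
#' along world X) beam.
#'
#' @param source_position X-ray source (mm).
#' @param film_point a point on the film plane (mm).
#' @param film_normal film plane normal (unitized; must not be
#'   perpendicular to the source-film direction).
#' @param film_axes 3x2 matrix of in-plane film axes; `NULL` builds an
#'   orthonormal pair automatically (second axis toward world +Z).
#' @param ear_rod_point,ear_rod_direction the ear-rod axis (mm); the
#'   midpoint used for the central ray is `ear_rod_point`.
#' @return An object of class `projection_geometry` with derived fields
#'   `source_to_film_distance` and `source_to_object_distance` (both mm).
#' @export
projection_geometry <- function(source_position = c(-1650, 0, 0),
                                film_point = c(0, 0, 0) + c(0, 0, 0),
                                film_normal = c(1, 0, 0),
                                film_axes = NULL,
                                ear_rod_point = c(-150, 0, 0),
                                ear_rod_direction = c(1, 0, 0)) {
  # default film plane sits 150 mm beyond the ear rod along the beam
  if (missing(film_point)) film_point <- c(0, 0, 0)
  nrm <- unitize(film_normal)
  dir <- unitize(ear_rod_direction)
  if (abs(sum(dir * nrm)) < 1 - 1e-6) {
    os_abort("ear-rod axis must be parallel to the film normal (lateral cephalometric setup)",
             "invalid_argument")
  }
  src_off <- sum((film_point - source_position) * nrm)
  if (abs(src_off) < 1e-9) {
    os_abort("source lies on the film plane", "invalid_argument")
  }
  stf <- abs(src_off)
  sto <- abs(sum((ear_rod_point - source_position) * nrm))
  if (!(stf > sto && sto > 0)) {
    os_abort("need source_to_film > source_to_object > 0", "invalid_argument")
  }
  if (is.null(film_axes)) {
    up <- c(0, 0, 1)
    if (abs(sum(up * nrm)) > 1 - 1e-6) up <- c(0, 1, 0)
    u2 <- unitize(up - sum(up * nrm) * nrm)
    u1 <- cross3(u2, nrm)
    film_axes <- cbind(u1, u2)
  }
  # film origin: central ray (source -> ear-rod point) meets the film
  d <- ear_rod_point - source_position
  lam <- sum((film_point - source_position) * nrm) / sum(d * nrm)
  film_origin <- source_position + lam * d
  structure(list(source_position = as.numeric(source_position),
                 film_point = as.numeric(film_point),
                 film_normal = nrm, film_axes = film_axes,
                 film_origin = film_origin,
                 ear_rod_point = as.numeric(ear_rod_point),
                 ear_rod_direction = dir,
                 source_to_film_distance = stf,
                 source_to_object_distance = sto),
            class = "projection_geometry")
}

#' @export
print.projection_geometry <- function(x, ...) {
  cat(sprintf("<projection_geometry> source-film %.0f mm, source-object %.0f mm (magnification %.3f)\n",
              x$source_to_film_distance, x$source_to_object_distance,
              x$source_to_film_distance / x$source_to_object_distance))
  invisible(x)
}

#' Project a 3D point onto the film
#'
#' Intersects the ray from the source through `p` with the film plane and
#' expresses the intersection in the film's 2D axes, with the central ray
#' (through the ear-rod point) at the origin. A point in the object plane
#' at offset `d` from the central ray lands at
#' `d * source_to_film / source_to_object` -- the similar-triangles
#' magnification.
#'
#' @param geom a [projection_geometry()].
#' @param p length-3 point or N x 3 matrix (mm).
#' @return Length-2 film coordinates (mm) or N x 2 matrix.
#' @export
project_point <- function(geom, p) {
  stopifnot(inherits(geom, "projection_geometry"))
  single <- is.null(dim(p))
  pts <- if (single) matrix(p, 1, 3) else as_points(p)
  d <- sweep(pts, 2, geom$source_position)
  denom <- as.numeric(d %*% geom$film_normal)
  if (any(abs(denom) < 1e-12)) {
    os_abort("ray parallel to the film plane: no intersection", "no_intersection")
  }
  lam <- sum((geom$film_point - geom$source_position) * geom$film_normal) / denom
  if (any(lam <= 0)) {
    os_abort("point projects away from the film (behind the source)",
             "no_intersection")
  }
  hit <- sweep(d * lam, 2, geom$source_position, "+")
  rel <- sweep(hit, 2, geom$film_origin)
  uv <- rel %*% geom$film_axes
  if (single) as.numeric(uv) else uv
}

# trilinear interpolation of a voxel volume at world points; zero outside
interp_volume <- function(vol, pts) {
  d <- dim(vol$intensities)
  g <- sweep(sweep(pts, 2, vol$origin), 2, vol$spacing, "/")
  i0 <- floor(g[, 1]); j0 <- floor(g[, 2]); k0 <- floor(g[, 3])
  fx <- g[, 1] - i0; fy <- g[, 2] - j0; fz <- g[, 3] - k0
  out <- numeric(nrow(pts))
  inside <- i0 >= 0 & i0 <= d[1] - 2 & j0 >= 0 & j0 <= d[2] - 2 &
    k0 >= 0 & k0 <= d[3] - 2
  if (!any(inside)) return(out)
  i0 <- i0[inside]; j0 <- j0[inside]; k0 <- k0[inside]
  fx <- fx[inside]; fy <- fy[inside]; fz <- fz[inside]
  at <- function(di, dj, dk) {
    vol$intensities[cbind(i0 + di + 1L, j0 + dj + 1L, k0 + dk + 1L)]
  }
  val <-
    at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    at(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    at(1, 1, 0) * fx * fy * (1 - fz) +
    at(1, 0, 1) * fx * (1 - fy) * fz +
    at(0, 1, 1) * (1 - fx) * fy * fz +
    at(1, 1, 1) * fx * fy * fz
  out[inside] <- val
  out
}

#' Render the virtual cephalometric image
#'
#' For a [voxel_volume()], each pixel is the line integral of intensity
#' along the ray from the source through the pixel (uniform sampling step,
#' default half the minimum voxel spacing, trilinear interpolation) -- a
#' geometric radiograph without Beer-Lambert attenuation, intended for
#' tracing, not dosimetry. For a [triangle_mesh()], a silhouette image:
#' each pixel counts the surface crossings of its ray.
#'
#' @param geom a [projection_geometry()].
#' @param model a `voxel_volume` or `triangle_mesh`.
#' @param mm_per_px film resolution (mm per pixel).
#' @param film_size_mm length-2 physical film extent `(width, height)` in
#'   mm, centered on the film origin.
#' @param step_mm ray sampling step for volumes; `NULL` uses half the
#'   minimum voxel spacing.
#' @return An object of class `vci_image`: list with `pixels` (matrix,
#'   width x height), `mm_per_px`, `extent_mm`, `geometry`.
#' @export
render_vci <- function(geom, model, mm_per_px = 0.5,
                       film_size_mm = c(120, 120), step_mm = NULL) {
  stopifnot(inherits(geom, "projection_geometry"))
  if (mm_per_px <= 0) os_abort("mm_per_px must be > 0", "invalid_argument")
  nu <- max(2L, round(film_size_mm[1] / mm_per_px))
  nv <- max(2L, round(film_size_mm[2] / mm_per_px))
  us <- (seq_len(nu) - (nu + 1) / 2) * mm_per_px
  vs <- (seq_len(nv) - (nv + 1) / 2) * mm_per_px
  img <- matrix(0, nu, nv)
  if (inherits(model, "voxel_volume")) {
    if (is.null(step_mm)) step_mm <- min(model$spacing) / 2
    # bounding sphere of the volume limits the sampled ray span
    d <- dim(model$intensities)
    corners <- as.matrix(expand.grid(x = c(0, d[1] - 1), y = c(0, d[2] - 1),
                                     z = c(0, d[3] - 1)))
    wc <- voxel_to_world(model, corners)
    ctr <- colMeans(wc)
    rad <- sqrt(max(rowSums(sweep(wc, 2, ctr)^2)))
    t_ctr <- vnorm(ctr - geom$source_position)
    t_lo <- max(t_ctr - rad, 1)
    t_hi <- t_ctr + rad
    ts <- seq(t_lo, t_hi, by = step_mm)
    for (col in seq_len(nv)) {
      film_pts <- sweep(outer(us, geom$film_axes[, 1]) +
                          outer(rep(vs[col], nu), geom$film_axes[, 2]),
                        2, geom$film_origin, "+")
      dirs <- sweep(film_pts, 2, geom$source_position)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      # sample all rays of this film column at once
      pts <- dirs[rep(seq_len(nu), each = length(ts)), , drop = FALSE] *
        rep(ts, times = nu) +
        matrix(geom$source_position, nu * length(ts), 3, byrow = TRUE)
      vals <- interp_volume(model, pts)
      img[, col] <- colSums(matrix(vals, length(ts), nu)) * step_mm
    }
  } else if (inherits(model, "triangle_mesh")) {
    # perspective rasterization: a ray crosses a triangle iff the projected
    # 2D triangle contains the pixel's film point
    tri2 <- project_point(geom, model$vertices)
    tr <- model$triangles
    px_of <- function(x) (x / mm_per_px) + (nu + 1) / 2
    py_of <- function(y) (y / mm_per_px) + (nv + 1) / 2
    for (i in seq_len(nrow(tr))) {
      a <- tri2[tr[i, 1], ]; b <- tri2[tr[i, 2], ]; cc <- tri2[tr[i, 3], ]
      iu <- max(1L, floor(px_of(min(a[1], b[1], cc[1])))):
        min(nu, ceiling(px_of(max(a[1], b[1], cc[1]))))
      iv <- max(1L, floor(py_of(min(a[2], b[2], cc[2])))):
        min(nv, ceiling(py_of(max(a[2], b[2], cc[2]))))
      if (length(iu) == 0 || length(iv) == 0) next
      gu <- us[iu]; gv <- vs[iv]
      det0 <- (b[1] - a[1]) * (cc[2] - a[2]) - (cc[1] - a[1]) * (b[2] - a[2])
      if (abs(det0) < 1e-12) next
      pu <- rep(gu, times = length(gv)); pv <- rep(gv, each = length(gu))
      w1 <- ((pu - a[1]) * (cc[2] - a[2]) - (cc[1] - a[1]) * (pv - a[2])) / det0
      w2 <- ((b[1] - a[1]) * (pv - a[2]) - (pu - a[1]) * (b[2] - a[2])) / det0
      insid <- w1 >= 0 & w2 >= 0 & (w1 + w2) <= 1
      if (any(insid)) {
        idx <- cbind(rep(iu, times = length(iv))[insid],
                     rep(iv, each = length(iu))[insid])
        img[idx] <- img[idx] + 1
      }
    }
  } else {
    os_abort("model must be a voxel_volume or a triangle_mesh", "invalid_argument")
  }
  structure(list(pixels = img, mm_per_px = mm_per_px,
                 extent_mm = c(nu, nv) * mm_per_px, geometry = geom),
            class = "vci_image")
}

#' @export
print.vci_image <- function(x, ...) {
  cat(sprintf("<vci_image> %d x %d px at %.3g mm/px, max %.4g\n",
              nrow(x$pixels), ncol(x$pixels), x$mm_per_px, max(x$pixels)))
  invisible(x)
}

#' Write a rendered cephalogram as 16-bit grayscale PGM with a mapping JSON
#'
#' The image is scaled to the full 16-bit range and written as a portable
#' graymap (P2, plain text); a sidecar JSON records the world-to-film
#' mapping (film origin, axes, mm per pixel, intensity scale).
#'
#' @param image a `vci_image`.
#' @param path output `.pgm` path.
#' @return The path, invisibly.
#' @export
write_vci_pgm <- function(image, path) {
  px <- image$pixels
  mx <- max(px)
  scaled <- if (mx > 0) round(px / mx * 65535) else px
  # PGM raster is row-major from the top row; film v axis points up
  rast <- t(scaled[, rev(seq_len(ncol(scaled))), drop = FALSE])
  lines <- c("P2", paste(nrow(px), ncol(px)), "65535",
             apply(rast, 1, paste, collapse = " "))
  writeLines(lines, path)
  g <- image$geometry
  meta <- list(mm_per_px = image$mm_per_px,
               film_origin_mm = g$film_origin,
               film_axes = list(u = g$film_axes[, 1], v = g$film_axes[, 2]),
               source_position_mm = g$source_position,
               intensity_scale = if (mx > 0) 65535 / mx else 1)
  jsonlite::write_json(meta, sub("\\.pgm$", ".json", path), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}
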