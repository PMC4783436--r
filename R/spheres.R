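# Reference-sphere detection: threshold the CT-like volume, label connected
# components in 3D (26-neighborhood), filter candidates by size and shape,
# and name the three surviving fiducial spheres by splint geometry.

#' Label connected components above a threshold
#'
#' Components are maximal sets of above-threshold voxels under full 3D
#' (26-neighborhood) connectivity. Centroids are intensity-weighted mean
#' world coordinates; component volume is voxel count times voxel volume.
#'
#' @param volume a [voxel_volume()].
#' @param threshold intensity threshold (voxels strictly above it are kept).
#' @param connectivity `26` (full 3D connectivity, the default) or `6`
#'   (face neighbors only).
#' @return A list of components, each a list with `id`, `voxel_indices`
#'   (0-based N x 3), `centroid` (mm), `voxel_count`, `volume_mm3`,
#'   `bbox_extent_mm`. An empty list if nothing is above threshold.
#' @export
label_components <- function(volume, threshold, connectivity = 26L) {
  stopifnot(inherits(volume, "voxel_volume"))
  stopifnot_finite(threshold, "threshold")
  if (!connectivity %in% c(6L, 26L)) {
    os_abort("connectivity must be 6 or 26", "invalid_argument")
  }
  d <- dim(volume$intensities)
  sel <- which(volume$intensities > threshold)
  if (length(sel) == 0) return(list())
  # voxel (i, j, k) 0-based from linear index
  lin0 <- sel - 1L
  i <- lin0 %% d[1]
  j <- (lin0 %/% d[1]) %% d[2]
  k <- lin0 %/% (d[1] * d[2])
  # map full-grid linear index -> compact id among selected voxels
  comp_id <- integer(prod(d))
  comp_id[sel] <- seq_along(sel)
  # positive half of the neighbor offsets (13 for 26-conn, 3 for 6-conn)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
            (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]
  if (connectivity == 6L) {
    offs <- offs[rowSums(abs(offs)) == 1L, , drop = FALSE]
  }
  edges <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    di <- offs[o, 1]; dj <- offs[o, 2]; dk <- offs[o, 3]
    ok <- i + di >= 0L & i + di < d[1] & j + dj >= 0L & j + dj < d[2] &
      k + dk >= 0L & k + dk < d[3]
    nb <- (i[ok] + di) + (j[ok] + dj) * d[1] + (k[ok] + dk) * d[1] * d[2] + 1L
    hit <- comp_id[nb] > 0L
    if (any(hit)) {
      edges[[o]] <- cbind(comp_id[sel[ok]][hit], comp_id[nb][hit])
    }
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(sel), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  membership <- igraph::components(g)$membership
  vox_vol <- prod(volume$spacing)
  idx0 <- cbind(i, j, k)
  world <- voxel_to_world(volume, idx0)
  w <- volume$intensities[sel]
  out <- lapply(sort(unique(membership)), function(m) {
    rows <- which(membership == m)
    ww <- w[rows]
    ctr <- colSums(world[rows, , drop = FALSE] * ww) / sum(ww)
    ext <- apply(world[rows, , drop = FALSE], 2, function(x) diff(range(x))) +
      volume$spacing
    list(id = m, voxel_indices = idx0[rows, , drop = FALSE],
         centroid = as.numeric(ctr), voxel_count = length(rows),
         volume_mm3 = length(rows) * vox_vol,
         bbox_extent_mm = as.numeric(ext))
  })
  out
}

# default threshold: Otsu on the above-bone tail. A first Otsu pass splits
# soft tissue from dense material; a second pass on the dense tail splits
# bone from metal, and the midpoint-style Otsu cut is returned.
default_sphere_threshold <- function(volume) {
  x <- as.numeric(volume$intensities)
  t1 <- otsu_threshold(x)
  tail1 <- x[x > t1]
  if (length(tail1) < 2 || diff(range(tail1)) == 0) return(t1)
  otsu_threshold(tail1)
}

#' Detect the three titanium reference spheres
#'
#' Thresholds the volume (by default with an Otsu cut on the above-bone
#' intensity tail), labels connected components, keeps components whose
#' volume lies within `[0.4, 2.5]` times the expected sphere volume and
#' whose bounding-box aspect ratio is at most 1.5, and requires exactly
#' three survivors. Survivors are named by splint geometry: the center with
#' the smallest sum of distances to the other two is `incisal`; of the
#' remaining two, the one with the smaller +X (anatomical left) coordinate
#' is `right_molar`.
#'
#' @param volume a [voxel_volume()].
#' @param expected_diameter_mm expected sphere diameter (default 6.0 mm).
#' @param threshold intensity threshold; `NULL` uses the Otsu tail default.
#' @return An object of class `detected_spheres`: list with `centers`
#'   (3 x 3 named matrix, mm), `voxel_count`, `radius_estimate_mm`,
#'   `threshold`.
#' @export
detect_reference_spheres <- function(volume, expected_diameter_mm = 6,
                                     threshold = NULL) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (expected_diameter_mm / max(volume$spacing) < 3) {
    warning("voxel spacing coarser than diameter/3: sphere resolution is marginal")
  }
  if (is.null(threshold)) threshold <- default_sphere_threshold(volume)
  comps <- label_components(volume, threshold)
  vexp <- 4 / 3 * pi * (expected_diameter_mm / 2)^3
  keep <- Filter(function(cmp) {
    ratio <- cmp$volume_mm3 / vexp
    aspect <- max(cmp$bbox_extent_mm) / min(cmp$bbox_extent_mm)
    ratio >= 0.4 && ratio <= 2.5 && aspect <= 1.5
  }, comps)
  if (length(keep) != 3) {
    os_abort(sprintf("expected 3 reference spheres, found %d surviving components (of %d above threshold %.4g)",
                     length(keep), length(comps), threshold),
             "detection_count_error",
             survivors = lapply(keep, function(cmp) cmp$centroid))
  }
  ctrs <- t(vapply(keep, function(cmp) cmp$centroid, numeric(3)))
  dmat <- as.matrix(dist(ctrs))
  inc <- which.min(rowSums(dmat))
  rest <- setdiff(1:3, inc)
  rm_idx <- rest[which.min(ctrs[rest, 1])]
  lm_idx <- setdiff(rest, rm_idx)
  ord <- c(inc, rm_idx, lm_idx)
  centers <- ctrs[ord, , drop = FALSE]
  rownames(centers) <- c("incisal", "right_molar", "left_molar")
  if (any(dist(centers) <= 10)) {
    os_abort("detected sphere centers closer than 10 mm: not a plausible splint",
             "detection_count_error")
  }
  structure(list(
    centers = centers,
    voxel_count = setNames(vapply(keep, `[[`, numeric(1), "voxel_count")[ord],
                           rownames(centers)),
    radius_estimate_mm = setNames(
      vapply(keep, function(cmp) (3 * cmp$volume_mm3 / (4 * pi))^(1 / 3), numeric(1))[ord],
      rownames(centers)),
    threshold = threshold
  ), class = "detected_spheres")
}

#' @export
print.detected_spheres <- function(x, ...) {
  cat("<detected_spheres> threshold", format(x$threshold, digits = 5), "\n")
  for (nm in rownames(x$centers)) {
    cat(sprintf("  %-12s (%8.3f, %8.3f, %8.3f) mm, %d voxels, r ~ %.2f mm\n",
                nm, x$centers[nm, 1], x$centers[nm, 2], x$centers[nm, 3],
                x$voxel_count[nm], x$radius_estimate_mm[nm]))
  }
  invisible(x)
}

#' Write detected sphere centers as JSON
#' @param spheres a `detected_spheres` object.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_spheres_json <- function(spheres, path) {
  obj <- list(centers_mm = apply(spheres$centers, 1, identity, simplify = FALSE),
              voxel_count = as.list(spheres$voxel_count),
              radius_estimate_mm = as.list(spheres$radius_estimate_mm),
              threshold = spheres$threshold)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
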