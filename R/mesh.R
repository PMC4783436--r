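# Triangle meshes: the container for dental casts, CT surfaces and bone
# segments, plus STL input/output with a JSON sidecar for the per-vertex
# data STL cannot carry (region labels, artifact flags, landmarks).

REGION_LABELS <- c("dental", "body", "orbita_left", "orbita_right",
                   "lower_border", "ramus_left", "ramus_right",
                   "condyle_left", "condyle_right", "from_ct", "from_scan",
                   "other")

#' Triangle mesh with optional per-vertex annotations
#'
#' @param vertices N x 3 matrix of vertex coordinates (mm).
#' @param triangles M x 3 integer matrix of 1-based vertex indices.
#' @param region_labels optional character vector of length N giving an
#'   anatomical region per vertex (e.g. `"dental"`, `"ramus_left"`,
#'   `"condyle_right"`, `"lower_border"`).
#' @param artifact_free optional logical vector of length N; `FALSE` marks
#'   vertices in (or corresponding to) metal-artifact-corrupted areas. Kept
#'   separate from `region_labels` because a vertex is typically both dental
#'   and artifact-free.
#' @param landmarks optional named list of length-3 points (mm) attached to
#'   the mesh (e.g. `incisor`, `right_molar`, `left_molar`).
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, triangles, region_labels = NULL,
                          artifact_free = NULL, landmarks = NULL) {
  vertices <- as_points(vertices, "vertices")
  triangles <- as.matrix(triangles)
  if (ncol(triangles) != 3) os_abort("triangles must be M x 3", "invalid_argument")
  storage.mode(triangles) <- "integer"
  n <- nrow(vertices)
  if (nrow(triangles) > 0 && (min(triangles) < 1L || max(triangles) > n)) {
    os_abort("triangle indices out of range", "invalid_argument")
  }
  if (!is.null(region_labels)) {
    region_labels <- as.character(region_labels)
    if (length(region_labels) != n) {
      os_abort("region_labels must have one entry per vertex", "invalid_argument")
    }
  }
  if (!is.null(artifact_free)) {
    artifact_free <- as.logical(artifact_free)
    if (length(artifact_free) != n) {
      os_abort("artifact_free must have one entry per vertex", "invalid_argument")
    }
  }
  structure(list(vertices = vertices, triangles = triangles,
                 region_labels = region_labels, artifact_free = artifact_free,
                 landmarks = landmarks),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  if (!is.null(x$region_labels)) {
    tb <- table(x$region_labels)
    cat("  regions:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  if (!is.null(x$landmarks)) {
    cat("  landmarks:", paste(names(x$landmarks), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Transform all vertices (and landmarks) of a mesh
#' @param mesh a `triangle_mesh`.
#' @param tf a `rigid_transform`.
#' @return The transformed `triangle_mesh`.
#' @export
transform_mesh <- function(mesh, tf) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  mesh$vertices <- apply_transform(tf, mesh$vertices)
  if (!is.null(mesh$landmarks)) {
    mesh$landmarks <- lapply(mesh$landmarks, function(p) apply_transform(tf, p))
  }
  mesh
}

# Concatenate meshes into a labeled union (no stitching; vertex order is
# preserved, first mesh first).
#' Union of meshes without stitching
#' @param ... `triangle_mesh` objects.
#' @return A `triangle_mesh` whose vertices/triangles are the concatenation.
#' @export
concat_meshes <- function(...) {
  ms <- list(...)
  offs <- 0L
  verts <- list(); tris <- list(); labs <- list(); af <- list(); lms <- list()
  any_lab <- any(vapply(ms, function(m) !is.null(m$region_labels), logical(1)))
  any_af <- any(vapply(ms, function(m) !is.null(m$artifact_free), logical(1)))
  for (m in ms) {
    stopifnot(inherits(m, "triangle_mesh"))
    n <- nrow(m$vertices)
    verts[[length(verts) + 1L]] <- m$vertices
    tris[[length(tris) + 1L]] <- m$triangles + offs
    if (any_lab) labs[[length(labs) + 1L]] <- m$region_labels %||% rep("other", n)
    if (any_af) af[[length(af) + 1L]] <- m$artifact_free %||% rep(TRUE, n)
    if (!is.null(m$landmarks)) lms <- c(lms, m$landmarks)
    offs <- offs + n
  }
  triangle_mesh(do.call(rbind, verts), do.call(rbind, tris),
                region_labels = if (any_lab) unlist(labs) else NULL,
                artifact_free = if (any_af) unlist(af) else NULL,
                landmarks = if (length(lms)) lms else NULL)
}

# area-weighted per-vertex unit normals (zero-normal vertices get arbitrary z)
vertex_normals <- function(mesh) {
  na <- triangle_normals_areas(mesh)
  n <- matrix(0, nrow(mesh$vertices), 3)
  for (c3 in 1:3) {
    for (axis in 1:3) {
      acc <- tapply(na$normals[, axis], mesh$triangles[, c3], sum)
      rows <- as.integer(names(acc))
      n[rows, axis] <- n[rows, axis] + as.numeric(acc)
    }
  }
  len <- sqrt(rowSums(n^2))
  deg <- len < 1e-12
  n[deg, ] <- matrix(rep(c(0, 0, 1), sum(deg)), ncol = 3, byrow = TRUE)
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

triangle_normals_areas <- function(mesh) {
  v <- mesh$vertices
  t1 <- v[mesh$triangles[, 1], , drop = FALSE]
  e1 <- v[mesh$triangles[, 2], , drop = FALSE] - t1
  e2 <- v[mesh$triangles[, 3], , drop = FALSE] - t1
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nrm <- cbind(nx, ny, nz)
  area <- 0.5 * sqrt(rowSums(nrm^2))
  list(normals = nrm, areas = area)
}

#' Write / read a triangle mesh as STL
#'
#' `write_stl` writes ASCII (default) or binary STL. Because STL carries no
#' per-vertex data, `write_mesh` also writes a JSON sidecar
#' (`<stem>.labels.json`) holding region labels, artifact flags and
#' landmarks, which `read_mesh` restores. STL stores one vertex triple per
#' facet; `read_stl` merges exactly coincident vertices.
#'
#' @param mesh a `triangle_mesh`.
#' @param path output `.stl` path.
#' @param binary write binary STL instead of ASCII.
#' @return `write_stl`/`write_mesh`: the path, invisibly. `read_stl`/
#'   `read_mesh`: a `triangle_mesh`.
#' @export
write_stl <- function(mesh, path, binary = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  na <- triangle_normals_areas(mesh)
  nrm <- na$normals / pmax(2 * na$areas, 1e-300)
  v <- mesh$vertices
  tr <- mesh$triangles
  m <- nrow(tr)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(m), con, size = 4, endian = "little")
    # facet records: normal, 3 vertices (float32), attribute count (uint16)
    block <- matrix(0, nrow = 12, ncol = m)
    block[1:3, ] <- t(nrm)
    block[4:6, ] <- t(v[tr[, 1], , drop = FALSE])
    block[7:9, ] <- t(v[tr[, 2], , drop = FALSE])
    block[10:12, ] <- t(v[tr[, 3], , drop = FALSE])
    for (i in seq_len(m)) {
      writeBin(block[, i], con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    fmt <- function(p) sprintf("%.9g %.9g %.9g", p[1], p[2], p[3])
    lines <- character(7L * m + 2L)
    lines[1] <- "solid orthosim"
    k <- 2L
    for (i in seq_len(m)) {
      lines[k] <- paste("  facet normal", fmt(nrm[i, ]))
      lines[k + 1L] <- "    outer loop"
      lines[k + 2L] <- paste("      vertex", fmt(v[tr[i, 1], ]))
      lines[k + 3L] <- paste("      vertex", fmt(v[tr[i, 2], ]))
      lines[k + 4L] <- paste("      vertex", fmt(v[tr[i, 3], ]))
      lines[k + 5L] <- "    endloop"
      lines[k + 6L] <- "  endfacet"
      k <- k + 7L
    }
    lines[k] <- "endsolid orthosim"
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  hdr <- readBin(con, "raw", 84L)
  close(con)
  ntri_bin <- if (length(hdr) == 84L) {
    readBin(hdr[81:84], "integer", size = 4, endian = "little")
  } else -1L
  is_binary <- length(hdr) == 84L && sz == 84 + 50 * ntri_bin
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 84L)
    tri_pts <- matrix(0, ntri_bin * 3L, 3)
    for (i in seq_len(ntri_bin)) {
      rec <- readBin(con, "double", n = 12, size = 4, endian = "little")
      readBin(con, "integer", n = 1, size = 2, endian = "little")
      tri_pts[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
  } else {
    txt <- readLines(path)
    vlines <- grep("^\\s*vertex\\s", txt, value = TRUE)
    nums <- lapply(strsplit(trimws(vlines), "\\s+"), function(p) as.numeric(p[2:4]))
    tri_pts <- do.call(rbind, nums)
  }
  key <- apply(tri_pts, 1, function(p) paste(sprintf("%.9g", p), collapse = "_"))
  uidx <- !duplicated(key)
  verts <- tri_pts[uidx, , drop = FALSE]
  map <- match(key, key[uidx])
  tris <- matrix(map, ncol = 3, byrow = TRUE)
  triangle_mesh(verts, tris)
}

sidecar_path <- function(path) sub("\\.stl$", ".labels.json", path, ignore.case = TRUE)

#' @rdname write_stl
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  write_stl(mesh, path, binary = binary)
  # STL loses the vertex array: on read, vertices come back in order of first
  # appearance in the facet stream. Store per-vertex data in that order so
  # read_mesh can reattach it (vertices never referenced by a facet are lost).
  ord <- unique(as.vector(t(mesh$triangles)))
  side <- list(
    region_labels = mesh$region_labels[ord],
    artifact_free = mesh$artifact_free[ord],
    landmarks = mesh$landmarks,
    vertex_order = "first appearance in facet stream"
  )
  jsonlite::write_json(side, sidecar_path(path), digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_stl
#' @export
read_mesh <- function(path) {
  mesh <- read_stl(path)
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    side <- jsonlite::fromJSON(sp)
    if (!is.null(side$region_labels)) mesh$region_labels <- side$region_labels
    if (!is.null(side$artifact_free)) mesh$artifact_free <- side$artifact_free
    if (!is.null(side$landmarks) && length(side$landmarks)) {
      mesh$landmarks <- lapply(side$landmarks, as.numeric)
    }
  }
  mesh
}
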