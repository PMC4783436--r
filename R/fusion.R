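# Dental fusion: trimmed iterative closest point registration of the clean
# scanned arch onto the artifact-corrupted CT dentition, restricted to
# artifact-free areas, followed by replacement of the CT dental region.

#' Trimmed iterative closest point registration
#'
#' Registers `source` onto `target` by iterating closest-point
#' correspondence and a rigid Kabsch fit, discarding the worst
#' `trim_fraction` of pairs each iteration to resist residual artifact
#' contamination. Correspondence is point-to-nearest-surface-point, run in
#' two phases within one iteration budget: a coarse phase matching nearest
#' target vertices (fast, finds the basin), then a refinement phase
#' matching the closest point on the target triangles incident to the
#' nearest vertex (removes the spurious minima the mesh sampling lattice
#' induces on pure vertex matching; triangle-free targets stay on vertex
#' matching). The best pose seen so far is retained throughout; a phase is
#' declared settled once ten consecutive iterations fail to improve the
#' trimmed RMS residual by `tolerance_mm`, and `converged` reports whether
#' the refinement phase settled (or the residual reached zero) before the
#' `max_iterations` budget ran out.
#'
#' @param source,target [triangle_mesh()] objects; target triangles, when
#'   present, define the surface that source points are matched against.
#' @param source_mask which source vertices participate: `"artifact_free"`
#'   (default; uses the mesh's artifact-free flags), a region label string,
#'   a logical vector, or `NULL` for all vertices.
#' @param max_iterations total iteration cap (default 100; large initial
#'   misalignments may need more to settle).
#' @param tolerance_mm improvement below which an iteration counts as
#'   stalled (default 1e-6 mm).
#' @param trim_fraction fraction of worst pairs discarded per iteration
#'   (default 0.1).
#' @param initial_transform starting `rigid_transform`; `NULL` (default)
#'   initializes with the translation aligning the masked-source centroid to
#'   the target centroid, the usual ICP warm start.
#' @return An object of class `icp_result`: `transform` (best pose),
#'   `rms_residual` (mm, over kept pairs), `iterations_used`, `converged`,
#'   `rms_history` (accepted improvements; non-increasing).
#' @export
icp_register <- function(source, target, source_mask = "artifact_free",
                         max_iterations = 100L, tolerance_mm = 1e-6,
                         trim_fraction = 0.1,
                         initial_transform = NULL) {
  stopifnot(inherits(source, "triangle_mesh"), inherits(target, "triangle_mesh"))
  if (any(!is.finite(source$vertices)) || any(!is.finite(target$vertices))) {
    os_abort("meshes contain non-finite vertices", "invalid_argument")
  }
  n <- nrow(source$vertices)
  mask <- if (is.null(source_mask)) {
    rep(TRUE, n)
  } else if (is.logical(source_mask)) {
    if (length(source_mask) != n) {
      os_abort("logical source_mask must have one entry per source vertex",
               "invalid_argument")
    }
    source_mask
  } else if (identical(source_mask, "artifact_free")) {
    source$artifact_free %||% rep(TRUE, n)
  } else {
    if (is.null(source$region_labels)) {
      os_abort("source mesh carries no region labels", "invalid_argument")
    }
    source$region_labels == source_mask
  }
  src <- source$vertices[mask, , drop = FALSE]
  if (nrow(src) < 3) {
    os_abort("fewer than 3 masked source vertices", "degenerate_configuration")
  }
  tgt <- target$vertices
  # incidence map: triangles around each target vertex, padded rectangular
  incidence <- NULL
  if (nrow(target$triangles) > 0) {
    tri_of_vert <- split(rep(seq_len(nrow(target$triangles)), 3),
                         as.vector(target$triangles))
    maxdeg <- max(lengths(tri_of_vert))
    incidence <- matrix(NA_integer_, nrow(tgt), maxdeg)
    for (vtx in names(tri_of_vert)) {
      tr <- tri_of_vert[[vtx]]
      incidence[as.integer(vtx), seq_along(tr)] <- tr
    }
  }
  tf <- initial_transform %||%
    rigid_transform(diag(3), colMeans(tgt) - colMeans(src))
  nkeep <- max(3L, ceiling((1 - trim_fraction) * nrow(src)))
  correspond <- function(tf, surface) {
    moved <- apply_transform(tf, src)
    nn <- nearest_neighbor(moved, tgt)
    corr <- tgt[nn$index, , drop = FALSE]
    dist <- nn$distance
    if (surface && !is.null(incidence)) {
      # refine to the closest point on the triangles around the NN vertex
      best_d2 <- dist^2
      for (k in seq_len(ncol(incidence))) {
        tri_id <- incidence[nn$index, k]
        ok <- !is.na(tri_id)
        if (!any(ok)) next
        tri <- target$triangles[tri_id[ok], , drop = FALSE]
        cand <- closest_point_on_triangle(moved[ok, , drop = FALSE],
                                          tgt[tri[, 1], , drop = FALSE],
                                          tgt[tri[, 2], , drop = FALSE],
                                          tgt[tri[, 3], , drop = FALSE])
        d2 <- rowSums((moved[ok, , drop = FALSE] - cand)^2)
        better <- d2 < best_d2[ok]
        rows <- which(ok)[better]
        corr[rows, ] <- cand[better, , drop = FALSE]
        best_d2[rows] <- d2[better]
      }
      dist <- sqrt(best_d2)
    }
    list(corr = corr, dist = dist)
  }
  # The iteration keeps the best pose seen so far; the reported history is
  # the sequence of accepted improvements, non-increasing by construction.
  # The one-ring surface matching is approximate, so single iterations can
  # regress slightly; iteration continues from the new pose regardless and
  # stops once `patience` consecutive iterations bring no improvement.
  patience <- 10L
  best_rms <- Inf
  best_tf <- tf
  rms_history <- numeric(0)
  converged <- FALSE
  iters <- 0L
  stalled <- 0L
  surface_phase <- is.null(incidence)  # no triangles: vertex matching only
  for (it in seq_len(max_iterations)) {
    iters <- it
    cp <- correspond(tf, surface_phase)
    keep <- order(cp$dist)[seq_len(nkeep)]
    fit <- kabsch_fit(src[keep, , drop = FALSE], cp$corr[keep, , drop = FALSE])
    tf <- fit$transform
    res <- apply_transform(tf, src[keep, , drop = FALSE]) -
      cp$corr[keep, , drop = FALSE]
    rms <- sqrt(mean(rowSums(res^2)))
    if (rms < best_rms) {
      if (best_rms - rms >= tolerance_mm) stalled <- -1L
      best_rms <- rms
      best_tf <- tf
      rms_history <- c(rms_history, rms)
    }
    stalled <- stalled + 1L
    if (best_rms < tolerance_mm) {  # exact alignment: nothing left to gain
      converged <- TRUE
      break
    }
    if (stalled >= patience) {
      if (surface_phase) {
        converged <- TRUE
        break
      }
      # vertex phase settled: switch to surface refinement from the best pose
      surface_phase <- TRUE
      tf <- best_tf
      stalled <- 0L
    }
  }
  structure(list(transform = best_tf, rms_residual = best_rms,
                 iterations_used = iters, converged = converged,
                 rms_history = rms_history),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf("<icp_result> rms %.6g mm after %d iterations (%s)\n",
              x$rms_residual, x$iterations_used,
              if (x$converged) "converged" else "iteration cap reached"))
  invisible(x)
}

#' Fuse the scanned dentition into the CT model
#'
#' Removes the dental-labeled vertices of the CT mesh and unions in the
#' scanned arch transformed by the ICP result, producing the dento-skeletal
#' model whose dental surface comes from the precise 3D scan. Vertices carry
#' a provenance label (`from_ct` / `from_scan`); no stitching is performed
#' across the fusion seam (downstream stages need labeled points, not
#' watertightness).
#'
#' @param ct_mesh CT surface mesh with a `"dental"` region label.
#' @param scan_mesh scanned dental arch mesh.
#' @param icp an `icp_result` from [icp_register()]; must have converged.
#' @return A [triangle_mesh()] with `region_labels` giving provenance and
#'   the scan landmarks carried along (transformed).
#' @export
fuse_dentition <- function(ct_mesh, scan_mesh, icp) {
  stopifnot(inherits(ct_mesh, "triangle_mesh"),
            inherits(scan_mesh, "triangle_mesh"),
            inherits(icp, "icp_result"))
  if (!isTRUE(icp$converged)) {
    os_abort("refusing to fuse with an unconverged ICP registration",
             "unconverged_registration")
  }
  if (is.null(ct_mesh$region_labels)) {
    os_abort("ct_mesh carries no region labels (need a dental region)",
             "invalid_argument")
  }
  keep <- ct_mesh$region_labels != "dental"
  keep_idx <- which(keep)
  remap <- integer(nrow(ct_mesh$vertices))
  remap[keep_idx] <- seq_along(keep_idx)
  tri_keep <- ct_mesh$triangles[rowSums(matrix(keep[ct_mesh$triangles],
                                               ncol = 3)) == 3L, , drop = FALSE]
  ct_part <- triangle_mesh(ct_mesh$vertices[keep_idx, , drop = FALSE],
                           matrix(remap[tri_keep], ncol = 3),
                           region_labels = rep("from_ct", length(keep_idx)))
  scan_part <- transform_mesh(scan_mesh, icp$transform)
  scan_part$region_labels <- rep("from_scan", nrow(scan_part$vertices))
  scan_part$artifact_free <- NULL
  fused <- concat_meshes(ct_part, scan_part)
  fused$landmarks <- scan_part$landmarks
  fused
}
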