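# Osteotomy simulation core: split the mandible into rigid segments
# (bilateral or unilateral sagittal splitting ramus osteotomy), drive the
# tooth-bearing distal segment with transforms from the tracking module,
# and quantify original-versus-simulated change per region.

#' Osteotomy plan
#'
#' Planar abstraction of the sagittal split: each cut is a plane
#' (point + unit normal, normal pointing toward the condyle side it
#' separates). A bilateral plan has two cut planes (left and right, in that
#' order); a unilateral plan has one. The mobile segment is always the
#' distal tooth-bearing segment.
#'
#' @param scheme `"bilateral_SSRO"`, `"unilateral_SSRO_left"` or
#'   `"unilateral_SSRO_right"`.
#' @param cut_planes list of `list(point =, normal =)` planes (mm; normals
#'   are unitized).
#' @return An object of class `osteotomy_plan`.
#' @export
osteotomy_plan <- function(scheme = c("bilateral_SSRO", "unilateral_SSRO_left",
                                      "unilateral_SSRO_right"),
                           cut_planes = NULL) {
  scheme <- match.arg(scheme)
  need <- if (scheme == "bilateral_SSRO") 2L else 1L
  if (is.null(cut_planes)) {
    # default cuts for the phantom mandible: vertical planes just medial to
    # the rami, normals pointing laterally (toward the condyles)
    cut_planes <- list(list(point = c(26, 0, 0), normal = c(1, 0, 0)),
                       list(point = c(-26, 0, 0), normal = c(-1, 0, 0)))
    cut_planes <- switch(scheme,
                         bilateral_SSRO = cut_planes,
                         unilateral_SSRO_left = cut_planes[1],
                         unilateral_SSRO_right = cut_planes[2])
  }
  if (length(cut_planes) != need) {
    os_abort(sprintf("%s requires %d cut plane(s)", scheme, need),
             "invalid_argument")
  }
  cut_planes <- lapply(cut_planes, function(p) {
    list(point = as.numeric(p$point), normal = unitize(p$normal))
  })
  structure(list(scheme = scheme, cut_planes = cut_planes,
                 mobile_segment = "distal_tooth_bearing"),
            class = "osteotomy_plan")
}

segment_sides <- function(scheme) {
  switch(scheme,
         bilateral_SSRO = c("proximal_left", "proximal_right"),
         unilateral_SSRO_left = "proximal_left",
         unilateral_SSRO_right = "proximal_right")
}

#' Split the mandible into rigid segments
#'
#' Partitions the mandible vertices by the signed side of the cut
#' plane(s): vertices beyond a cut plane (positive side of its normal) go
#' to the corresponding proximal condyle-bearing segment, everything else
#' to the distal tooth-bearing segment. Under a unilateral scheme the
#' un-cut side stays rigidly attached to the distal segment. Triangles
#' crossing a cut are assigned to the segment of their centroid (no
#' re-triangulation). The partition conserves vertices exactly.
#'
#' @param mandible a labeled [triangle_mesh()].
#' @param plan an [osteotomy_plan()].
#' @return An object of class `simulated_model`: named `segments` (each a
#'   `triangle_mesh` plus `orig_index` mapping back to the input mesh),
#'   `applied_transform` (identity), `plan`, `provenance`.
#' @export
split_mandible <- function(mandible, plan) {
  stopifnot(inherits(mandible, "triangle_mesh"), inherits(plan, "osteotomy_plan"))
  v <- mandible$vertices
  n <- nrow(v)
  sides <- segment_sides(plan$scheme)
  assign <- rep("distal", n)
  for (i in seq_along(plan$cut_planes)) {
    pl <- plan$cut_planes[[i]]
    s <- as.numeric(sweep(v, 2, pl$point) %*% pl$normal)
    beyond <- s > 0
    if (!any(beyond) || all(beyond)) {
      os_abort(sprintf("cut plane %d misses the mandible (empty segment)", i),
               "empty_segment")
    }
    assign[beyond] <- sides[i]
  }
  labs <- mandible$region_labels
  if (!is.null(labs)) {
    # plan validity: teeth must be distal, each cut's condyle proximal
    if (any(labs == "dental" & assign != "distal")) {
      os_abort("a cut plane separates tooth-bearing vertices from the distal segment",
               "plan_validity")
    }
    for (i in seq_along(plan$cut_planes)) {
      cond <- if (sides[i] == "proximal_left") "condyle_left" else "condyle_right"
      if (any(labs == cond) && !any(labs == cond & assign == sides[i])) {
        os_abort(sprintf("condyle and teeth lie on the same side of cut %d", i),
                 "plan_validity")
      }
    }
  }
  tri_ctr_side <- function(pl) {
    ctr <- (v[mandible$triangles[, 1], , drop = FALSE] +
              v[mandible$triangles[, 2], , drop = FALSE] +
              v[mandible$triangles[, 3], , drop = FALSE]) / 3
    as.numeric(sweep(ctr, 2, pl$point) %*% pl$normal) > 0
  }
  tri_assign <- rep("distal", nrow(mandible$triangles))
  for (i in seq_along(plan$cut_planes)) {
    tri_assign[tri_ctr_side(plan$cut_planes[[i]])] <- sides[i]
  }
  segments <- list()
  for (seg in c("distal", sides)) {
    vi <- which(assign == seg)
    remap <- integer(n)
    remap[vi] <- seq_along(vi)
    tri <- mandible$triangles[tri_assign == seg, , drop = FALSE]
    # a straddling triangle may reference vertices outside its segment;
    # keep only triangles fully resolvable within the segment
    ok <- rowSums(matrix(assign[tri] == seg, ncol = 3)) == 3L
    tri <- matrix(remap[tri[ok, , drop = FALSE]], ncol = 3)
    m <- triangle_mesh(v[vi, , drop = FALSE], tri,
                       region_labels = labs[vi],
                       artifact_free = mandible$artifact_free[vi])
    m$orig_index <- vi
    segments[[seg]] <- m
  }
  if (!is.null(mandible$landmarks)) segments$distal$landmarks <- mandible$landmarks
  structure(list(segments = segments, applied_transform = identity_transform(),
                 plan = plan, provenance = mandible),
            class = "simulated_model")
}

#' @export
print.simulated_model <- function(x, ...) {
  cat("<simulated_model>", x$plan$scheme, "\n")
  for (nm in names(x$segments)) {
    cat(sprintf("  %-15s %d vertices\n", nm, nrow(x$segments[[nm]]$vertices)))
  }
  invisible(x)
}

#' Apply a rigid transform to the mobile (distal) segment
#'
#' Only the tooth-bearing distal segment moves; proximal condyle-bearing
#' segments are left untouched (proximal repositioning strategies are out
#' of scope). The applied transform is composed into the model's record.
#'
#' @param model a `simulated_model`.
#' @param transform a `rigid_transform`.
#' @return The updated `simulated_model`.
#' @export
apply_segment_transform <- function(model, transform) {
  stopifnot(inherits(model, "simulated_model"))
  if (!inherits(transform, "rigid_transform")) {
    os_abort("transform must be a rigid_transform", "invalid_argument")
  }
  model$segments$distal <- transform_mesh(model$segments$distal, transform)
  model$applied_transform <- compose_transforms(transform, model$applied_transform)
  model
}

#' Superimpose the simulated model on the original and summarize change
#'
#' Matches vertices through their original indices and reports per-vertex
#' displacement magnitudes plus per-region means and maxima for the
#' condyles, the tooth-bearing region and the rami -- the quantities read
#' off superimposition renderings (e.g. whether the condylar position
#' changed).
#'
#' @param original,simulated `simulated_model` objects derived from the
#'   same mandible mesh.
#' @return A list with `per_vertex_mm` (named by segment) and `regions`, a
#'   data.frame with columns `region`, `mean_mm`, `max_mm`, `n_vertices`.
#' @export
superimpose_compare <- function(original, simulated) {
  stopifnot(inherits(original, "simulated_model"),
            inherits(simulated, "simulated_model"))
  if (!identical(dim(original$provenance$vertices),
                 dim(simulated$provenance$vertices)) ||
      max(abs(original$provenance$vertices - simulated$provenance$vertices)) > 0) {
    os_abort("models do not share the same provenance mesh", "invalid_argument")
  }
  n <- nrow(original$provenance$vertices)
  vo <- matrix(NA_real_, n, 3)
  vs <- matrix(NA_real_, n, 3)
  for (seg in original$segments) vo[seg$orig_index, ] <- seg$vertices
  for (seg in simulated$segments) vs[seg$orig_index, ] <- seg$vertices
  disp <- sqrt(rowSums((vs - vo)^2))
  per_seg <- lapply(simulated$segments, function(seg) disp[seg$orig_index])
  labs <- original$provenance$region_labels
  regions <- list(condyle_left = "condyle_left", condyle_right = "condyle_right",
                  tooth_bearing = "dental", ramus_left = "ramus_left",
                  ramus_right = "ramus_right")
  rows <- lapply(names(regions), function(nm) {
    sel <- !is.null(labs) & labs == regions[[nm]]
    if (!any(sel)) return(NULL)
    data.frame(region = nm, mean_mm = mean(disp[sel]), max_mm = max(disp[sel]),
               n_vertices = sum(sel))
  })
  list(per_vertex_mm = per_seg, regions = do.call(rbind, rows))
}

#' Run a pose-driven simulation session
#'
#' Splits the mandible, takes the first stream sample as the reference
#' (home-position) pose, converts every sample into a distal-segment
#' transform via [cast_pose_to_segment_transform()], and applies each to a
#' fresh copy of the split model. Deterministic given its inputs.
#'
#' @param mandible a labeled [triangle_mesh()].
#' @param plan an [osteotomy_plan()].
#' @param pose_stream a `pose_stream`.
#' @param calibration a `splint_calibration`.
#' @return A list with `trajectory` (one `list(t_s, transform)` per
#'   sample), `final` (the `simulated_model` at the last sample) and
#'   `initial` (the split model before any motion).
#' @export
run_session <- function(mandible, plan, pose_stream, calibration) {
  if (is.null(pose_stream) || nrow(pose_stream) == 0) {
    os_abort("empty pose stream", "invalid_argument")
  }
  base <- split_mandible(mandible, plan)
  transforms <- replay_stream(pose_stream, calibration, reference_row = 1L)
  trajectory <- lapply(seq_along(transforms), function(i) {
    list(t_s = pose_stream$t_s[i], transform = transforms[[i]])
  })
  final <- apply_segment_transform(base, transforms[[length(transforms)]])
  list(trajectory = trajectory, final = final, initial = base)
}
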