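# Diagnostic coordinate systems: cranial global coordinates anchored on a
# mirror-symmetry mid-sagittal plane fitted to the orbital regions, and
# mandibular local coordinates (MLB) from a best-fit quartic curve to the
# mandibular lower border. Both frames feed the asymmetry report.

#' Anatomy frame
#'
#' @param origin frame origin (mm, world coordinates).
#' @param axes 3x3 proper rotation whose columns are the frame axes in world
#'   coordinates, ordered (left-right, anterior, superior).
#' @param kind `"cranial"` or `"mandibular_MLB"`.
#' @return An object of class `anatomy_frame`. The frame's mid-plane is the
#'   plane through `origin` normal to the left-right axis (column 1).
#' @export
anatomy_frame <- function(origin, axes, kind = c("cranial", "mandibular_MLB")) {
  kind <- match.arg(kind)
  axes <- as.matrix(axes)
  if (max(abs(crossprod(axes) - diag(3))) > 1e-6 || det(axes) < 0) {
    os_abort("frame axes must form a proper rotation", "invalid_argument")
  }
  structure(list(origin = as.numeric(origin), axes = axes, kind = kind),
            class = "anatomy_frame")
}

#' @export
print.anatomy_frame <- function(x, ...) {
  cat(sprintf("<anatomy_frame> %s, origin (%.2f, %.2f, %.2f) mm\n",
              x$kind, x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

mirror_across_plane <- function(points, point, normal) {
  normal <- unitize(normal)
  if (is.null(dim(points))) {
    return(points - 2 * sum((points - point) * normal) * normal)
  }
  pts <- as_points(points)
  s <- as.numeric(sweep(pts, 2, point) %*% normal)
  pts - 2 * outer(s, normal)
}

# mean nearest-neighbour distance from set a to set b
mean_nn_distance <- function(a, b) mean(nearest_neighbor(a, b)$distance)

#' Fit the mid-sagittal plane by orbital mirror symmetry
#'
#' The mid-sagittal plane is chosen so that the difference between the
#' right and the left orbital region is smallest: the plane minimizes the
#' mean nearest-neighbour distance between the left point set and the
#' mirror image of the right point set across the plane (the default
#' metric; `"centroid"` and `"hausdorff"` are available as alternatives).
#' Optimization is a derivative-free Nelder-Mead simplex over the plane
#' normal (two spherical angles) and offset, initialized from the midpoint
#' of the two centroids with the normal along their difference.
#'
#' @param orbita_left,orbita_right point sets (N x 3, mm), at least 10
#'   points per side.
#' @param metric symmetry cost: `"nn_mean"` (default), `"centroid"`, or
#'   `"hausdorff"`.
#' @return A list with `point` (on the plane), `normal` (unit, oriented
#'   toward anatomical left, +X), and `asymmetry_cost` (mm).
#' @export
fit_midsagittal_plane <- function(orbita_left, orbita_right,
                                  metric = c("nn_mean", "centroid", "hausdorff")) {
  metric <- match.arg(metric)
  left <- as_points(orbita_left, "orbita_left")
  right <- as_points(orbita_right, "orbita_right")
  if (nrow(left) < 10 || nrow(right) < 10) {
    os_abort("need at least 10 points per orbital side", "invalid_argument")
  }
  cl <- colMeans(left)
  cr <- colMeans(right)
  if (vnorm(cl - cr) < 1e-6) {
    os_abort("coincident orbital centroids: cannot initialize the mirror plane",
             "degenerate_configuration")
  }
  n0 <- unitize(cl - cr)
  mid <- (cl + cr) / 2
  cost_of <- function(normal, offset) {
    mirrored <- {
      s <- as.numeric(right %*% normal) - offset
      right - 2 * outer(s, normal)
    }
    switch(metric,
           nn_mean = mean_nn_distance(left, mirrored),
           centroid = vnorm(colMeans(left) - colMeans(mirrored)),
           hausdorff = max(max(nearest_neighbor(left, mirrored)$distance),
                           max(nearest_neighbor(mirrored, left)$distance)))
  }
  # parametrize the normal by spherical angles around the initial normal
  theta0 <- acos(max(-1, min(1, n0[3])))
  phi0 <- atan2(n0[2], n0[1])
  par0 <- c(theta0, phi0, sum(n0 * mid))
  objective <- function(par) {
    nrm <- c(sin(par[1]) * cos(par[2]), sin(par[1]) * sin(par[2]), cos(par[1]))
    cost_of(nrm, par[3])
  }
  opt <- optim(par0, objective, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  nrm <- c(sin(opt$par[1]) * cos(opt$par[2]),
           sin(opt$par[1]) * sin(opt$par[2]), cos(opt$par[1]))
  off <- opt$par[3]  # plane is {p : nrm . p = off}
  if (nrm[1] < 0) {  # orient toward anatomical left (+X)
    nrm <- -nrm
    off <- -off
  }
  list(point = nrm * off, normal = nrm, asymmetry_cost = opt$value)
}

#' Build the cranial global frame from the mid-sagittal plane
#'
#' The left-right axis is the plane normal (signed toward anatomical left);
#' the superior axis is the component of world +Z orthogonal to it; the
#' anterior axis completes the right-handed triad. The origin is the
#' projection of the inter-orbital midpoint onto the plane.
#'
#' @param plane result of [fit_midsagittal_plane()] (fields `point`,
#'   `normal`).
#' @param reference_landmarks named list containing `orbita_left_centroid`
#'   and `orbita_right_centroid` (mm).
#' @return An `anatomy_frame` of kind `"cranial"`.
#' @export
build_cranial_frame <- function(plane, reference_landmarks) {
  lr <- unitize(plane$normal)
  ol <- reference_landmarks$orbita_left_centroid
  or <- reference_landmarks$orbita_right_centroid
  if (is.null(ol) || is.null(or)) {
    os_abort("reference_landmarks must include both orbital centroids",
             "invalid_argument")
  }
  if (sum(lr * (ol - or)) < 0) lr <- -lr
  zc <- c(0, 0, 1) - sum(c(0, 0, 1) * lr) * lr
  if (vnorm(zc) < 1e-6) {
    os_abort("mid-sagittal normal is parallel to world +Z: frame orientation ambiguous",
             "orientation_ambiguity")
  }
  superior <- unitize(zc)
  anterior <- cross3(superior, lr)
  mid <- (ol + or) / 2
  origin <- mid - sum((mid - plane$point) * lr) * lr
  anatomy_frame(origin, cbind(lr, anterior, superior), "cranial")
}

# canonicalize a quartic: re-express b(a) about its global minimum so the
# origin sits on the arch front (constant and linear terms vanish there).
canonical_quartic <- function(coef) {
  dcoef <- coef[-1] * 1:4
  roots <- polyroot(dcoef)
  real <- Re(roots[abs(Im(roots)) < 1e-8 * (1 + abs(Re(roots)))])
  evalp <- function(cf, x) drop(outer(x, 0:(length(cf) - 1L), "^") %*% cf)
  cand <- real
  if (length(cand) == 0) cand <- 0
  vals <- evalp(coef, cand)
  a0 <- cand[which.min(vals)]
  # Taylor shift: p(a + a0) expressed in powers of a
  shifted <- numeric(5)
  for (k in 0:4) {
    for (m in k:4) {
      shifted[k + 1] <- shifted[k + 1] + coef[m + 1] * choose(m, k) * a0^(m - k)
    }
  }
  b0 <- shifted[1]
  shifted[1] <- 0
  shifted[2] <- 0  # derivative is zero at the minimum by construction
  list(coefficients = shifted, a_min = a0, b_min = b0)
}

#' Fit the mandibular lower border (MLB) frame
#'
#' Projects the lower-border points onto their principal-component plane,
#' fits a quartic `b = c0 + c1 a + ... + c4 a^4` by least squares in that
#' plane (in-plane axes from the principal components, oriented so the
#' quartic opens upward and the width axis points toward anatomical left),
#' and re-expresses the curve about its global minimum -- the arch front.
#' The local midline is the in-plane line through that minimum; the frame
#' origin sits at the minimum with axes (arch-width direction, midline
#' tangent, plane normal).
#'
#' @param lower_border N x 3 matrix (mm) of lower-border points, at least
#'   20 spanning both sides.
#' @return A list with `curve` (class `quartic_curve`: `coefficients` in
#'   the canonical about-the-minimum form, `fit_plane`, `rms_fit_error`)
#'   and `frame` (an `anatomy_frame` of kind `"mandibular_MLB"`).
#' @export
fit_mlb_frame <- function(lower_border) {
  pts <- as_points(lower_border, "lower_border points")
  if (nrow(pts) < 20) os_abort("need at least 20 lower-border points", "invalid_argument")
  ctr <- colMeans(pts)
  pc <- prcomp(pts, center = TRUE, scale. = FALSE)
  if (pc$sdev[2] < 1e-9 || diff(range(pts %*% pc$rotation[, 1])) < 10) {
    os_abort("lower-border points are collinear or span less than 10 mm",
             "degenerate_configuration")
  }
  width_axis <- pc$rotation[, 1]
  depth_axis <- pc$rotation[, 2]
  if (width_axis[1] < 0) width_axis <- -width_axis  # toward anatomical left
  a <- as.numeric(sweep(pts, 2, ctr) %*% width_axis)
  b <- as.numeric(sweep(pts, 2, ctr) %*% depth_axis)
  fit_coef <- function(a, b) {
    A <- outer(a, 0:4, "^")
    qr.solve(A, b)
  }
  cf <- fit_coef(a, b)
  if (cf[5] < 0) {  # orient the depth axis so the arch opens upward
    depth_axis <- -depth_axis
    b <- -b
    cf <- fit_coef(a, b)
  }
  if (abs(cf[5]) < 1e-12) {
    os_abort("quartic fit degenerated (zero leading coefficient)",
             "degenerate_configuration")
  }
  pred <- drop(outer(a, 0:4, "^") %*% cf)
  rms <- sqrt(mean((b - pred)^2))
  can <- canonical_quartic(cf)
  origin <- ctr + can$a_min * width_axis + can$b_min * depth_axis
  curve <- structure(list(coefficients = can$coefficients,
                          fit_plane = list(point = origin,
                                           width_axis = width_axis,
                                           depth_axis = depth_axis),
                          rms_fit_error = rms),
                     class = "quartic_curve")
  # frame axes ordered (left-right, anterior, superior): the depth axis
  # points from the arch front into the arch (posterior), so the anterior
  # axis is its negative; the triad is re-orthogonalized right-handed.
  lr <- width_axis
  anterior <- -depth_axis
  superior <- cross3(lr, anterior)
  frame <- anatomy_frame(origin, cbind(lr, anterior, superior), "mandibular_MLB")
  list(curve = curve, frame = frame)
}

#' @export
print.quartic_curve <- function(x, ...) {
  cat("<quartic_curve> b =",
      paste(sprintf("%.4g a^%d", x$coefficients, 0:4), collapse = " + "),
      sprintf("\n  rms fit error %.4g mm\n", x$rms_fit_error))
  invisible(x)
}

#' Left-right asymmetry report
#'
#' For each landmark, the signed distance to the frame's mid-plane
#' (positive toward anatomical left, +X). For each labeled left/right
#' region pair (orbita, ramus, condyle), the mirrored surface distance: the
#' symmetric mean nearest-neighbour distance between one side and the
#' mirror image of the other across the mid-plane. Regions with a missing
#' partner are listed as absent.
#'
#' @param mesh a labeled [triangle_mesh()].
#' @param frame an `anatomy_frame`.
#' @param landmarks optional named list of points (mm); defaults to the
#'   mesh's own landmarks.
#' @return A list with `landmark_deviation_mm` (named, signed) and
#'   `region_mirror_distance_mm` (named; `NA` where a side is absent).
#' @export
asymmetry_report <- function(mesh, frame, landmarks = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(frame, "anatomy_frame"))
  lr <- frame$axes[, 1]
  landmarks <- landmarks %||% mesh$landmarks
  lm_dev <- if (!is.null(landmarks)) {
    vapply(landmarks, function(p) sum((p - frame$origin) * lr), numeric(1))
  } else numeric(0)
  pairs <- list(orbita = c("orbita_left", "orbita_right"),
                ramus = c("ramus_left", "ramus_right"),
                condyle = c("condyle_left", "condyle_right"))
  reg <- setNames(rep(NA_real_, length(pairs)), names(pairs))
  if (!is.null(mesh$region_labels)) {
    for (nm in names(pairs)) {
      li <- mesh$region_labels == pairs[[nm]][1]
      ri <- mesh$region_labels == pairs[[nm]][2]
      if (any(li) && any(ri)) {
        l <- mesh$vertices[li, , drop = FALSE]
        r <- mesh$vertices[ri, , drop = FALSE]
        rm <- mirror_across_plane(r, frame$origin, lr)
        reg[nm] <- (mean_nn_distance(l, rm) + mean_nn_distance(rm, l)) / 2
      }
    }
  }
  list(landmark_deviation_mm = lm_dev, region_mirror_distance_mm = reg)
}
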