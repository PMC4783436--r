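# Rigid-body math underlying every other module: Euler conventions,
# transform algebra, and least-squares three-point (Kabsch) registration.

#' Rigid transform (proper rotation + translation)
#'
#' Construct the universal motion currency of the toolkit: a rigid-body
#' transform consisting of a 3x3 proper rotation and a translation in mm.
#' Applying the transform maps a point `p` to `rotation %*% p + translation`.
#'
#' @param rotation 3x3 orthogonal matrix with determinant +1. Orthogonality is
#'   checked with tolerance `1e-6` on input.
#' @param translation numeric length-3 translation in mm.
#' @return An object of class `rigid_transform` with fields `rotation` and
#'   `translation`.
#' @examples
#' tf <- rigid_transform(euler_to_rotation(c(30, 10, -5)), c(1, 2, 3))
#' apply_transform(tf, c(0, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3))) {
    os_abort("rotation must be a 3x3 matrix", "invalid_argument")
  }
  stopifnot_finite(rotation, "rotation")
  stopifnot_finite(translation, "translation")
  if (length(translation) != 3) {
    os_abort("translation must have length 3", "invalid_argument")
  }
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-6) {
    os_abort(sprintf("rotation is not orthogonal (max deviation %.2e)", err),
             "invalid_argument")
  }
  if (det(rotation) < 0) {
    os_abort("rotation has determinant -1 (reflection, not a rotation)",
             "invalid_argument")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  ang <- rotation_to_euler(x$rotation)
  cat(sprintf("  euler (az, el, roll) deg: %8.3f %8.3f %8.3f\n",
              ang[1], ang[2], ang[3]))
  cat(sprintf("  translation mm:           %8.3f %8.3f %8.3f\n",
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Identity transform
#' @return A `rigid_transform` that leaves every point unchanged.
#' @export
identity_transform <- function() rigid_transform()

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` is the transform that applies `b` first and
#' then `a`, i.e. `(a o b)(p) = a(b(p))`.
#'
#' @param a,b `rigid_transform` objects.
#' @return The composed `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param tf a `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  rt <- t(tf$rotation)
  rigid_transform(rt, -as.numeric(rt %*% tf$translation))
}

#' Apply a rigid transform to points
#'
#' @param tf a `rigid_transform`.
#' @param points a length-3 vector or an N x 3 matrix of points (mm).
#' @return Transformed points in the same shape as the input.
#' @export
apply_transform <- function(tf, points) {
  stopifnot(inherits(tf, "rigid_transform"))
  if (is.null(dim(points))) {
    return(as.numeric(tf$rotation %*% points) + tf$translation)
  }
  pts <- as_points(points)
  sweep(pts %*% t(tf$rotation), 2, tf$translation, "+")
}

#' Euler angles to rotation matrix
#'
#' The convention is intrinsic Z-Y'-X'': azimuth is a yaw about +Z, elevation
#' a pitch about the once-rotated Y, and roll a rotation about the
#' twice-rotated X, matching the output convention of the electromagnetic
#' tracker family the pose stream emulates. Angles are in degrees.
#'
#' @param angles numeric length-3 `c(azimuth, elevation, roll)` in degrees.
#' @return A 3x3 proper rotation matrix.
#' @examples
#' euler_to_rotation(c(90, 0, 0)) %*% c(1, 0, 0)  # +X maps to +Y
#' @export
euler_to_rotation <- function(angles) {
  stopifnot_finite(angles, "euler angles")
  if (length(angles) != 3) os_abort("need 3 angles", "invalid_argument")
  a <- deg2rad(angles[1]); e <- deg2rad(angles[2]); r <- deg2rad(angles[3])
  ca <- cos(a); sa <- sin(a)
  ce <- cos(e); se <- sin(e)
  cr <- cos(r); sr <- sin(r)
  rz <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  ry <- matrix(c(ce, 0, se, 0, 1, 0, -se, 0, ce), 3, 3, byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cr, -sr, 0, sr, cr), 3, 3, byrow = TRUE)
  rz %*% ry %*% rx
}

#' Rotation matrix to Euler angles
#'
#' Inverse of [euler_to_rotation()]. At gimbal lock (elevation = +/-90
#' degrees) the decomposition is not unique; the tie is broken by reporting
#' roll = 0 and letting azimuth absorb the free angle.
#'
#' @param rot 3x3 proper rotation matrix (orthogonality checked at `1e-6`).
#' @return Numeric `c(azimuth, elevation, roll)` in degrees, with azimuth and
#'   roll in (-180, 180] and elevation in [-90, 90].
#' @export
rotation_to_euler <- function(rot) {
  rot <- as.matrix(rot)
  stopifnot_finite(rot, "rotation")
  if (max(abs(crossprod(rot) - diag(3))) > 1e-6 || det(rot) < 0) {
    os_abort("input is not a proper rotation matrix", "invalid_argument")
  }
  s <- max(-1, min(1, -rot[3, 1]))
  el <- asin(s)
  if (abs(s) < 1 - 1e-12) {
    az <- atan2(rot[2, 1], rot[1, 1])
    roll <- atan2(rot[3, 2], rot[3, 3])
  } else {
    # gimbal lock: roll := 0, azimuth carries the residual angle
    roll <- 0
    az <- atan2(-rot[1, 2], rot[2, 2])
  }
  c(azimuth = wrap_angle(rad2deg(az)),
    elevation = rad2deg(el),
    roll = wrap_angle(rad2deg(roll)))
}

#' Least-squares rigid registration of paired point sets (Kabsch)
#'
#' Finds the rigid transform minimizing the sum of squared distances between
#' `transform(source)` and `target` over paired points. Reflections are
#' excluded: the returned rotation always has determinant +1.
#'
#' @param source,target N x 3 matrices (mm) of paired points, N >= 3,
#'   non-collinear.
#' @return A list with `transform` (`rigid_transform`) and `rms_residual`
#'   (mm, root-mean-square distance after alignment).
#' @examples
#' src <- matrix(c(0, 0, 0, 40, 0, 0, 0, 25, 0), 3, 3, byrow = TRUE)
#' tf <- rigid_transform(euler_to_rotation(c(10, 5, -3)), c(4, -2, 7))
#' kabsch_fit(src, apply_transform(tf, src))$rms_residual
#' @export
kabsch_fit <- function(source, target) {
  source <- as_points(source, "source points")
  target <- as_points(target, "target points")
  if (nrow(source) != nrow(target)) {
    os_abort("source and target must have the same number of points",
             "invalid_argument")
  }
  if (nrow(source) < 3) {
    os_abort("need at least 3 point pairs", "degenerate_configuration")
  }
  cs <- colMeans(source)
  ct <- colMeans(target)
  sc <- sweep(source, 2, cs)
  tc <- sweep(target, 2, ct)
  # collinearity: the centered configuration must span at least a plane
  for (m in list(sc, tc)) {
    sv <- svd(m, nu = 0, nv = 0)$d
    if (sv[2] < 1e-9 * max(sv[1], 1e-300)) {
      os_abort("point configuration is collinear or degenerate",
               "degenerate_configuration")
    }
  }
  h <- crossprod(sc, tc)  # sum over pairs of s_i t_i^T
  dec <- svd(h)
  d <- sign(det(dec$v %*% t(dec$u)))
  if (d == 0) d <- 1
  rot <- dec$v %*% diag(c(1, 1, d)) %*% t(dec$u)
  tr <- ct - as.numeric(rot %*% cs)
  tf <- rigid_transform(rot, tr)
  res <- apply_transform(tf, source) - target
  list(transform = tf, rms_residual = sqrt(mean(rowSums(res^2))))
}

#' Serialize / deserialize a rigid transform as JSON
#'
#' The JSON layout is `{"rotation": [9 row-major floats],
#' "translation_mm": [3 floats]}`.
#'
#' @param tf a `rigid_transform`.
#' @param path file path; for `transform_to_json` with `path = NULL` the JSON
#'   string is returned instead of written.
#' @return `transform_to_json`: the JSON string (invisibly when written to a
#'   file); `transform_from_json`: a `rigid_transform`.
#' @export
transform_to_json <- function(tf, path = NULL) {
  stopifnot(inherits(tf, "rigid_transform"))
  obj <- list(rotation = as.numeric(t(tf$rotation)),
              translation_mm = tf$translation)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = FALSE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname transform_to_json
#' @export
transform_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  rigid_transform(matrix(obj$rotation, 3, 3, byrow = TRUE), obj$translation_mm)
}
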