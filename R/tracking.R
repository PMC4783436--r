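# The mixed-reality bridge: stylus digitization of the splint spheres,
# tracker-frame to virtual-frame calibration, and conversion of streamed
# cast poses into virtual-segment transforms.

#' 6DOF tracker pose
#'
#' @param t timestamp in seconds.
#' @param position length-3 position (mm) in the tracker frame.
#' @param angles length-3 `c(azimuth, elevation, roll)` in degrees (see
#'   [euler_to_rotation()] for the convention).
#' @return An object of class `pose6dof`.
#' @export
pose6dof <- function(t = 0, position = c(0, 0, 0), angles = c(0, 0, 0)) {
  stopifnot_finite(t, "t")
  stopifnot_finite(position, "position")
  stopifnot_finite(angles, "angles")
  structure(list(t = t, position = as.numeric(position),
                 angles = as.numeric(angles)), class = "pose6dof")
}

#' Pose as a rigid transform
#' @param pose a `pose6dof`.
#' @return The equivalent `rigid_transform` (receiver frame to tracker frame).
#' @export
pose_to_transform <- function(pose) {
  stopifnot(inherits(pose, "pose6dof"))
  rigid_transform(euler_to_rotation(pose$angles), pose$position)
}

#' Extract a pose from a pose-stream row
#' @param stream a `pose_stream` data frame.
#' @param row 1-based row index.
#' @return A `pose6dof`.
#' @export
stream_pose <- function(stream, row) {
  if (row < 1 || row > nrow(stream)) os_abort("stream row out of range", "invalid_argument")
  pose6dof(stream$t_s[row],
           c(stream$x_mm[row], stream$y_mm[row], stream$z_mm[row]),
           c(stream$azimuth_deg[row], stream$elevation_deg[row],
             stream$roll_deg[row]))
}

#' Reference-sphere center implied by a stylus digitization
#'
#' During digitization the bowl-shaped stylus tip rests on the sphere
#' surface with the stylus long axis (the +X axis of the receiver frame)
#' passing through the sphere center, so the center lies half a diameter
#' ahead of the tip along that axis: 3.0 mm for the 6.0 mm splint spheres.
#'
#' @param pose a `pose6dof` giving the stylus tip position and orientation.
#' @param sphere_diameter_mm sphere diameter (default 6.0 mm).
#' @return Length-3 sphere center (mm) in the tracker frame.
#' @examples
#' sphere_center_from_stylus(pose6dof())  # c(3, 0, 0)
#' @export
sphere_center_from_stylus <- function(pose, sphere_diameter_mm = 6) {
  stopifnot(inherits(pose, "pose6dof"))
  if (sphere_diameter_mm < 0) {
    os_abort("sphere diameter must be non-negative", "invalid_argument")
  }
  rot <- euler_to_rotation(pose$angles)
  pose$position + as.numeric(rot %*% c(sphere_diameter_mm / 2, 0, 0))
}

#' Calibrate the tracker frame against the virtual frame
#'
#' Matches the three digitized splint-sphere centers (tracker frame) with
#' the same spheres detected in the virtual dento-skeletal model by name,
#' and fits the tracker-to-virtual rigid transform by three-point Kabsch
#' registration. A calibration with fit residual of 1.0 mm or more is
#' rejected as unusable.
#'
#' @param tracker_centers,virtual_centers 3 x 3 matrices with rownames
#'   `incisal`, `right_molar`, `left_molar` (any order; matched by name), or
#'   named lists of length-3 points.
#' @return An object of class `splint_calibration`: `tracker_centers`,
#'   `virtual_centers`, `tracker_to_virtual` (`rigid_transform`),
#'   `fit_residual` (mm), `accepted`.
#' @export
calibrate_splint <- function(tracker_centers, virtual_centers) {
  as_centers <- function(x, what) {
    if (is.list(x)) x <- do.call(rbind, x)
    x <- as.matrix(x)
    if (is.null(rownames(x)) || nrow(x) != 3 || ncol(x) != 3) {
      os_abort(sprintf("%s must be 3 named 3-vectors", what), "invalid_argument")
    }
    x
  }
  tc <- as_centers(tracker_centers, "tracker_centers")
  vc <- as_centers(virtual_centers, "virtual_centers")
  if (!setequal(rownames(tc), rownames(vc))) {
    os_abort("tracker and virtual sphere names do not match", "invalid_argument")
  }
  vc <- vc[rownames(tc), , drop = FALSE]
  fit <- kabsch_fit(tc, vc)
  structure(list(tracker_centers = tc, virtual_centers = vc,
                 tracker_to_virtual = fit$transform,
                 fit_residual = fit$rms_residual,
                 accepted = fit$rms_residual < 1.0),
            class = "splint_calibration")
}

#' @export
print.splint_calibration <- function(x, ...) {
  cat(sprintf("<splint_calibration> fit residual %.4g mm (%s)\n",
              x$fit_residual, if (x$accepted) "accepted" else "REJECTED"))
  invisible(x)
}

#' Convert a streamed cast pose into the virtual-segment transform
#'
#' The virtual bone segment must follow the real cast. With `P(.)` the pose
#' as a rigid transform in the tracker frame and `V` the tracker-to-virtual
#' calibration, the segment transform in virtual space is the conjugated
#' relative motion `V P(current) P(reference)^-1 V^-1`. The reference pose
#' is captured while the casts occlude the splint (virtual model at its
#' home position), which is what makes the unknown cast-to-receiver
#' mounting offset cancel. At `current == reference` the result is the
#' identity.
#'
#' @param current,reference `pose6dof` samples from the same stream.
#' @param calib a `splint_calibration` (must be accepted).
#' @return The `rigid_transform` to apply to the mobile virtual segment.
#' @export
cast_pose_to_segment_transform <- function(current, reference, calib) {
  if (missing(reference) || is.null(reference)) {
    os_abort("reference pose is required (captured at the home position)",
             "invalid_argument")
  }
  stopifnot(inherits(calib, "splint_calibration"))
  if (!isTRUE(calib$accepted)) {
    os_abort("calibration residual too large; refusing to map poses",
             "invalid_argument")
  }
  v <- calib$tracker_to_virtual
  rel <- compose_transforms(pose_to_transform(current),
                            invert_transform(pose_to_transform(reference)))
  compose_transforms(v, compose_transforms(rel, invert_transform(v)))
}

#' Replay a pose stream as segment transforms
#'
#' Applies [cast_pose_to_segment_transform()] sample by sample (no
#' filtering or smoothing), using one stream row as the reference pose.
#'
#' @param stream a `pose_stream`.
#' @param calib a `splint_calibration`.
#' @param reference_row row index of the reference (home-position) pose.
#' @return A list of `rigid_transform`, one per stream row.
#' @export
replay_stream <- function(stream, calib, reference_row = 1L) {
  if (nrow(stream) == 0) os_abort("empty pose stream", "invalid_argument")
  ref <- stream_pose(stream, reference_row)
  lapply(seq_len(nrow(stream)), function(i) {
    cast_pose_to_segment_transform(stream_pose(stream, i), ref, calib)
  })
}

#' Simulate stylus digitization of the three splint spheres
#'
#' Generates the stylus poses a surgeon would record while touching each
#' splint sphere, optionally perturbed by tracker noise, and returns the
#' implied sphere centers in the tracker frame. The stylus is pointed at
#' each sphere along a fixed oblique direction; the tip sits on the sphere
#' surface, one radius short of the center.
#'
#' @param sphere_centers_tracker 3 x 3 named matrix of true sphere centers
#'   in the tracker frame.
#' @param sphere_diameter_mm sphere diameter.
#' @param noise_spec a [tracker_noise_spec()] applied to the stylus poses.
#' @param seed integer seed for the noise draws.
#' @return 3 x 3 named matrix of digitized centers (tracker frame, mm).
#' @export
digitize_spheres <- function(sphere_centers_tracker, sphere_diameter_mm = 6,
                             noise_spec = NULL, seed = 1L) {
  centers <- as.matrix(sphere_centers_tracker)
  if (nrow(centers) != 3 || is.null(rownames(centers))) {
    os_abort("need 3 named sphere centers", "invalid_argument")
  }
  # stylus approach direction (unit) and the matching Euler angles: the
  # receiver +X axis must point along the approach direction
  approach <- unitize(c(0.3, 0.8, -0.52))
  az <- rad2deg(atan2(approach[2], approach[1]))
  el <- rad2deg(asin(-approach[3]))
  angles <- c(az, el, 0)
  out <- centers
  for (i in 1:3) {
    tip <- centers[i, ] - approach * sphere_diameter_mm / 2
    pose <- pose6dof(0, tip, angles)
    if (!is.null(noise_spec)) {
      pert <- with_seed(seed + i, {
        list(p = runif(3, noise_spec$pos_lo, noise_spec$pos_hi),
             a = rnorm(3, 0, noise_spec$ang_sd))
      })
      pose$position <- pose$position + pert$p
      pose$angles <- pose$angles + pert$a
    }
    out[i, ] <- sphere_center_from_stylus(pose, sphere_diameter_mm)
  }
  out
}
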