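# Synthetic craniofacial phantom: stands in for the patient, the CT scanner,
# the 3D dental-cast scanner and the electromagnetic tracker. Every artifact
# carries its complete ground truth so the whole pipeline is testable with
# no external data.
#
# Geometry lives in a right-handed world frame: +X anatomical left,
# +Y anterior, +Z superior, lengths in mm. The phantom is built mirror
# symmetric about x = 0 unless an asymmetry offset is requested, so the
# ground-truth mid-sagittal plane is exactly {x = 0}.

# run expr with a deterministic RNG stream, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Phantom configuration
#'
#' Collects every tunable parameter of the synthetic phantom with its
#' default. Defaults mirror the simulated device and splint: 6.0 mm
#' reference spheres, 1.0 mm isotropic CT voxels on a 128^3 grid, a 60 Hz
#' pose stream, and a 0.3 metal-artifact vertex fraction on the CT
#' dentition.
#'
#' @param shape CT grid shape (3 positive integers).
#' @param spacing_mm voxel spacing in mm.
#' @param sphere_diameter_mm diameter of the three titanium reference
#'   spheres.
#' @param sphere_jitter_mm uniform per-axis jitter applied to the nominal
#'   sphere centers (seeded); 0 keeps the nominal symmetric placement.
#' @param asymmetry_offset_mm length-3 rigid shift of the whole mandible,
#'   mimicking a laterally displaced mandible; `c(0,0,0)` gives a mirror
#'   symmetric phantom.
#' @param ramus_offset_mm lateral (+X) shift applied to the left ramus and
#'   condyle only in the mandible mesh, mimicking ramus-confined asymmetry.
#' @param artifact_fraction fraction in [0, 1) of CT dentition vertices
#'   corrupted by the simulated metal artifact.
#' @param artifact_amplitude_mm half-width of the uniform per-axis
#'   displacement applied to corrupted vertices.
#' @param artifact_streak add a bright streak region near the dentition to
#'   the CT volume.
#' @param intensity_air,intensity_soft,intensity_bone,intensity_titanium
#'   phantom intensity levels (arbitrary CT-like units), strictly ordered.
#' @param ct_offset_angles_deg,ct_offset_translation_mm the ground-truth
#'   rigid transform carrying the scanned dental arch into the CT frame
#'   (Euler angles in degrees, translation in mm).
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(128L, 128L, 128L),
                           spacing_mm = c(1, 1, 1),
                           sphere_diameter_mm = 6,
                           sphere_jitter_mm = 0,
                           asymmetry_offset_mm = c(0, 0, 0),
                           ramus_offset_mm = 0,
                           artifact_fraction = 0.3,
                           artifact_amplitude_mm = 2,
                           artifact_streak = FALSE,
                           intensity_air = 0,
                           intensity_soft = 40,
                           intensity_bone = 300,
                           intensity_titanium = 1000,
                           ct_offset_angles_deg = c(4, -3, 2),
                           ct_offset_translation_mm = c(3, -2, 1.5)) {
  cfg <- as.list(environment())
  if (any(shape < 8)) os_abort("grid too small", "invalid_argument")
  if (any(spacing_mm <= 0)) os_abort("spacing must be > 0", "invalid_argument")
  if (artifact_fraction < 0 || artifact_fraction >= 1) {
    os_abort("artifact_fraction must be in [0, 1)", "invalid_argument")
  }
  ints <- c(intensity_air, intensity_soft, intensity_bone, intensity_titanium)
  if (any(diff(ints) <= 0)) {
    os_abort("intensities must be strictly ordered air < soft < bone < titanium",
             "invalid_argument")
  }
  class(cfg) <- "phantom_config"
  cfg
}

# Nominal splint sphere centers (before jitter). Pairwise distances exceed
# 20 mm: incisal-to-molar ~28.3 mm, molar-to-molar 40 mm.
nominal_sphere_centers <- function() {
  rbind(incisal = c(0, 45, -5),
        right_molar = c(-20, 25, -5),
        left_molar = c(20, 25, -5))
}

# Mandibular lower-border curve in the axial plane (even in x). In the
# canonical orientation used by the MLB fit (front of the arch at the curve
# minimum) the quartic coefficients are c(0, 0, MLB_C2, 0, MLB_C4).
MLB_C2 <- 0.02
MLB_C4 <- 1e-5
lower_border_curve <- function(x) 35 - MLB_C2 * x^2 - MLB_C4 * x^4

# Dental-cast arch centerline (axial plane, even in x), at cast height.
arch_curve <- function(x) 40 - 0.025 * x^2 - 1.2e-5 * x^4
ARCH_Z <- -12
ARCH_TUBE_R <- 3.5
TOOTH_BUMP <- 0.9
TOOTH_PITCH <- 6

arch_landmark_points <- function() {
  top <- ARCH_Z + ARCH_TUBE_R + TOOTH_BUMP
  list(incisor = c(0, arch_curve(0), top),
       right_molar = c(-18, arch_curve(18), top),
       left_molar = c(18, arch_curve(18), top))
}

phantom_ground_truth <- function(...) {
  structure(list(...), class = "phantom_ground_truth")
}

#' @export
print.phantom_ground_truth <- function(x, ...) {
  cat("<phantom_ground_truth>", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Generate the CT-like skull phantom volume
#'
#' Builds a scalar volume containing a skull-like bone shell (cranial vault
#' plus two mirrored orbital rims), a mandible with a tooth-bearing body and
#' two rami with condyles, and the three titanium splint spheres, over a
#' soft-tissue head on an air background. Intensities are strictly ordered
#' air < soft tissue < bone < titanium so thresholding is unambiguous.
#' Realism is geometric, not radiological: there is no Hounsfield
#' calibration or beam physics.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed driving all stochastic choices (sphere jitter);
#'   identical config + seed gives bit-identical output.
#' @return A list with `volume` (a [voxel_volume()]) and `ground_truth`
#'   (sphere centers, mid-sagittal plane, lower-border quartic coefficients,
#'   landmark points, asymmetry offset).
#' @export
generate_skull_volume <- function(config = phantom_config(), seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$sphere_diameter_mm / max(config$spacing_mm) < 3) {
    os_abort("voxel spacing too coarse to resolve the reference spheres (need diameter >= 3 voxels)",
             "resolution_error")
  }
  shape <- as.integer(config$shape)
  sp <- config$spacing_mm
  # center the grid so coordinates negate exactly under index reversal,
  # keeping even-in-x masks bitwise mirror symmetric
  xs <- ((0:(shape[1] - 1L)) - (shape[1] - 1) / 2) * sp[1]
  ys <- ((0:(shape[2] - 1L)) - (shape[2] - 1) / 2) * sp[2]
  zs <- ((0:(shape[3] - 1L)) - (shape[3] - 1) / 2) * sp[3]
  origin <- c(xs[1], ys[1], zs[1])
  n <- prod(shape)
  X <- rep(xs, times = shape[2] * shape[3])
  Y <- rep(rep(ys, each = shape[1]), times = shape[3])
  Z <- rep(zs, each = shape[1] * shape[2])

  v <- rep(config$intensity_air, n)

  # soft-tissue head ellipsoid
  head_mask <- (X / 55)^2 + (Y / 62)^2 + ((Z - 20) / 60)^2 <= 1
  v[head_mask] <- config$intensity_soft

  # cranial vault: ellipsoidal bone shell
  rho <- sqrt((X / 48)^2 + ((Y + 5) / 54)^2 + ((Z - 30) / 38)^2)
  v[rho >= 0.88 & rho <= 1] <- config$intensity_bone

  # orbital rims: mirrored spherical shells
  for (sx in c(-1, 1)) {
    d <- sqrt((X - sx * 26)^2 + (Y - 38)^2 + (Z - 28)^2)
    v[d >= 8 & d <= 11] <- config$intensity_bone
  }

  off <- config$asymmetry_offset_mm
  Xm <- X - off[1]; Ym <- Y - off[2]; Zm <- Z - off[3]
  # mandibular body: slab arch following the lower-border curve
  body <- abs(Xm) <= 28 & abs(Zm + 20) <= 4 &
    abs(Ym - lower_border_curve(Xm)) <= 4
  v[body] <- config$intensity_bone
  # rami: thin vertical slabs; condyles: spheres on top
  rami <- abs(abs(Xm) - 30) <= 1.5 & Ym >= 4 & Ym <= 16 & Zm >= -20 & Zm <= 6
  v[rami] <- config$intensity_bone
  for (sx in c(-1, 1)) {
    d <- sqrt((Xm - sx * 30)^2 + (Ym - 10)^2 + (Zm - 9)^2)
    v[d <= 5] <- config$intensity_bone
  }

  if (isTRUE(config$artifact_streak)) {
    streak <- abs(X) <= 25 & Y >= 28 & Y <= 44 & abs(Z - ARCH_Z) <= 2
    v[streak] <- (config$intensity_bone + config$intensity_titanium) / 2
  }

  centers <- nominal_sphere_centers()
  centers <- with_seed(seed, {
    if (config$sphere_jitter_mm > 0) {
      centers + matrix(runif(9, -config$sphere_jitter_mm,
                             config$sphere_jitter_mm), 3, 3)
    } else centers
  })
  r <- config$sphere_diameter_mm / 2
  for (i in 1:3) {
    d2 <- (X - centers[i, 1])^2 + (Y - centers[i, 2])^2 + (Z - centers[i, 3])^2
    v[d2 <= r^2] <- config$intensity_titanium
  }

  vol <- voxel_volume(array(v, dim = shape), origin = origin, spacing = sp)
  gt <- phantom_ground_truth(
    sphere_centers = centers,
    midsagittal_plane = list(point = c(0, 0, 0), normal = c(1, 0, 0)),
    mlb_coefficients = c(0, 0, MLB_C2, 0, MLB_C4),
    landmark_points = lapply(arch_landmark_points(), function(p) p + off),
    scan_to_ct_transform = identity_transform(),
    mandible_asymmetry_offset = off,
    orbit_centers = rbind(left = c(26, 38, 28), right = c(-26, 38, 28)),
    config = config, seed = seed
  )
  list(volume = vol, ground_truth = gt)
}

# Tube mesh along the dental arch; returns vertices, triangles and the
# cross-section angle per vertex (phi, 0 = outward horizontal, pi/2 = up).
arch_tube <- function(curve_fn, z0, radius, bump, xmax = 24, nx = 49L, nphi = 16L) {
  x <- seq(-xmax, xmax, length.out = nx)
  phi <- seq(0, 2 * pi, length.out = nphi + 1L)[-(nphi + 1L)]
  # curve tangent and horizontal normal
  eps <- 1e-6
  slope <- (curve_fn(x + eps) - curve_fn(x - eps)) / (2 * eps)
  nlen <- sqrt(1 + slope^2)
  nxv <- -slope / nlen
  nyv <- 1 / nlen
  verts <- matrix(0, nx * nphi, 3)
  phis <- numeric(nx * nphi)
  for (i in seq_len(nx)) {
    rr <- radius + bump * cos(pi * x[i] / TOOTH_PITCH)^2 * pmax(0, sin(phi))^2
    k <- ((i - 1L) * nphi + 1L):(i * nphi)
    verts[k, 1] <- x[i] + rr * cos(phi) * nxv[i]
    verts[k, 2] <- curve_fn(x[i]) + rr * cos(phi) * nyv[i]
    verts[k, 3] <- z0 + rr * sin(phi)
    phis[k] <- phi
  }
  tris <- matrix(0L, 2L * (nx - 1L) * nphi, 3)
  ti <- 1L
  for (i in seq_len(nx - 1L)) {
    for (j in seq_len(nphi)) {
      jn <- if (j == nphi) 1L else j + 1L
      a <- (i - 1L) * nphi + j
      b <- (i - 1L) * nphi + jn
      cc <- i * nphi + j
      dd <- i * nphi + jn
      tris[ti, ] <- c(a, b, cc); tris[ti + 1L, ] <- c(b, dd, cc)
      ti <- ti + 2L
    }
  }
  list(vertices = verts, triangles = tris, phi = phis, x = rep(x, each = nphi))
}

#' Generate the dental arch meshes (3D scan and CT counterpart)
#'
#' `scan_mesh` is the clean 3D-scanned lower dental cast: a parabolic-arch
#' tube with per-tooth bumps and the three measurement landmarks (lower
#' central incisor, bilateral first molars) attached. `ct_dentition_mesh` is
#' the same surface carried into the CT frame by the ground-truth
#' scan-to-CT transform, with an `artifact_fraction` of vertices displaced
#' by large noise to mimic the metal artifact; those vertices are flagged
#' `artifact_free = FALSE` on both meshes (the flag marks the corresponding
#' scan areas usable for registration).
#'
#' @inheritParams generate_skull_volume
#' @return A list with `scan_mesh`, `ct_dentition_mesh` (both
#'   [triangle_mesh()]) and `ground_truth`.
#' @export
generate_dental_arches <- function(config = phantom_config(), seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  tube <- arch_tube(arch_curve, ARCH_Z, ARCH_TUBE_R, TOOTH_BUMP)
  nvert <- nrow(tube$vertices)
  tf <- rigid_transform(euler_to_rotation(config$ct_offset_angles_deg),
                        config$ct_offset_translation_mm)
  ncorrupt <- floor(config$artifact_fraction * nvert)
  corrupt_idx <- with_seed(seed, sample.int(nvert, ncorrupt))
  af <- rep(TRUE, nvert)
  af[corrupt_idx] <- FALSE
  ct_verts <- apply_transform(tf, tube$vertices)
  if (ncorrupt > 0) {
    amp <- config$artifact_amplitude_mm
    jit <- with_seed(seed + 1L,
                     matrix(runif(3L * ncorrupt, -amp, amp), ncorrupt, 3))
    ct_verts[corrupt_idx, ] <- ct_verts[corrupt_idx, ] + jit
  }
  scan_mesh <- triangle_mesh(tube$vertices, tube$triangles,
                             region_labels = rep("dental", nvert),
                             artifact_free = af,
                             landmarks = arch_landmark_points())
  ct_mesh <- triangle_mesh(ct_verts, tube$triangles,
                           region_labels = rep("dental", nvert),
                           artifact_free = af)
  gt <- phantom_ground_truth(
    sphere_centers = nominal_sphere_centers(),
    midsagittal_plane = list(point = c(0, 0, 0), normal = c(1, 0, 0)),
    mlb_coefficients = c(0, 0, MLB_C2, 0, MLB_C4),
    landmark_points = arch_landmark_points(),
    scan_to_ct_transform = tf,
    mandible_asymmetry_offset = c(0, 0, 0),
    corrupted_vertices = sort(corrupt_idx),
    config = config, seed = seed
  )
  list(scan_mesh = scan_mesh, ct_dentition_mesh = ct_mesh, ground_truth = gt)
}

#' Generate the labeled mandible surface mesh
#'
#' A tube following the mandibular lower-border curve forms the tooth-bearing
#' body (top labeled `dental`, the exact bottom ring `lower_border`), with
#' thin vertical ramus sheets and condylar caps on both sides. The bottom
#' ring lies exactly on the ground-truth quartic lower-border curve, and the
#' mesh is exactly mirror symmetric about x = 0 when no offset is requested.
#'
#' @inheritParams generate_skull_volume
#' @return A list with `mesh` (a [triangle_mesh()]) and `ground_truth`.
#' @export
generate_mandible_mesh <- function(config = phantom_config(), seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  tube <- arch_tube(lower_border_curve, -20, 4, 0, xmax = 24, nx = 49L, nphi = 16L)
  labs <- rep("body", nrow(tube$vertices))
  labs[abs(tube$phi - pi / 2) < 1e-9] <- "dental"
  labs[abs(tube$phi - 3 * pi / 2) < 1e-9] <- "lower_border"
  meshes <- list(triangle_mesh(tube$vertices, tube$triangles, region_labels = labs))

  # ramus sheets with condylar top region
  ramus_sheet <- function(side) {  # side +1 = left, -1 = right
    yy <- seq(4, 16, length.out = 7)
    zz <- seq(-20, 6, length.out = 14)
    g <- expand.grid(y = yy, z = zz)
    verts <- cbind(side * 30, g$y, g$z)
    ny <- length(yy)
    tris <- matrix(0L, 2L * (ny - 1L) * (length(zz) - 1L), 3)
    ti <- 1L
    for (k in seq_len(length(zz) - 1L)) {
      for (j in seq_len(ny - 1L)) {
        a <- (k - 1L) * ny + j
        tris[ti, ] <- c(a, a + 1L, a + ny)
        tris[ti + 1L, ] <- c(a + 1L, a + ny + 1L, a + ny)
        ti <- ti + 2L
      }
    }
    lab <- ifelse(g$z >= 2,
                  if (side > 0) "condyle_left" else "condyle_right",
                  if (side > 0) "ramus_left" else "ramus_right")
    triangle_mesh(verts, tris, region_labels = lab)
  }
  left <- ramus_sheet(1)
  if (config$ramus_offset_mm != 0) {
    left$vertices[, 1] <- left$vertices[, 1] + config$ramus_offset_mm
  }
  mesh <- concat_meshes(meshes[[1]], left, ramus_sheet(-1))

  off <- config$asymmetry_offset_mm
  if (any(off != 0)) mesh$vertices <- sweep(mesh$vertices, 2, off, "+")
  top <- -20 + 4
  mesh$landmarks <- lapply(list(incisor = c(0, lower_border_curve(0), top),
                                right_molar = c(-18, lower_border_curve(18), top),
                                left_molar = c(18, lower_border_curve(18), top)),
                           function(p) p + off)
  gt <- phantom_ground_truth(
    sphere_centers = nominal_sphere_centers(),
    midsagittal_plane = list(point = c(0, 0, 0), normal = c(1, 0, 0)),
    mlb_coefficients = c(0, 0, MLB_C2, 0, MLB_C4),
    landmark_points = mesh$landmarks,
    scan_to_ct_transform = identity_transform(),
    mandible_asymmetry_offset = off,
    ramus_offset_mm = config$ramus_offset_mm,
    config = config, seed = seed
  )
  list(mesh = mesh, ground_truth = gt)
}

#' Orbital surface point sets for mid-sagittal plane estimation
#'
#' Samples points on the two mirrored orbital rims of the phantom. With
#' `noise_sd = 0` the right set is the exact mirror image of the left set
#' across the ground-truth mid-sagittal plane x = 0; with noise, independent
#' Gaussian jitter is added to each side after mirroring.
#'
#' @inheritParams generate_skull_volume
#' @param n_per_side points per side.
#' @param noise_sd isotropic Gaussian noise standard deviation (mm).
#' @return A list with `left`, `right` (N x 3 matrices) and `ground_truth`.
#' @export
generate_orbita_points <- function(config = phantom_config(), seed = 1L,
                                   n_per_side = 200L, noise_sd = 0) {
  with_seed(seed, {
    u <- runif(n_per_side); vphi <- runif(n_per_side, 0, 2 * pi)
    cosb <- 2 * u - 1
    sinb <- sqrt(pmax(0, 1 - cosb^2))
    r <- 9.5
    left <- cbind(26 + r * sinb * cos(vphi),
                  38 + r * sinb * sin(vphi),
                  28 + r * cosb)
    right <- left
    right[, 1] <- -right[, 1]
    if (noise_sd > 0) {
      left <- left + matrix(rnorm(3 * n_per_side, 0, noise_sd), n_per_side, 3)
      right <- right + matrix(rnorm(3 * n_per_side, 0, noise_sd), n_per_side, 3)
    }
    list(left = left, right = right,
         ground_truth = phantom_ground_truth(
           midsagittal_plane = list(point = c(0, 0, 0), normal = c(1, 0, 0)),
           config = config, seed = seed))
  })
}

#' Tracker noise specifications
#'
#' `device_band_noise_spec()` reproduces the linear-error band of the
#' emulated electromagnetic tracker: per-axis positional error uniform on
#' `(-0.308, 0.136) / sqrt(3)` mm, so the Euclidean per-sample position
#' error never exceeds the printed 0.308 mm device bound, plus Gaussian
#' angular noise (sd 0.05 degrees; the device spec gives only the linear
#' band, so the angular term is a documented assumption).
#' `zero_noise_spec()` disables all noise.
#'
#' @param pos_lo,pos_hi per-axis uniform positional error bounds (mm).
#' @param ang_sd Gaussian angular noise sd (degrees).
#' @return A list of class `noise_spec`.
#' @export
tracker_noise_spec <- function(pos_lo, pos_hi, ang_sd) {
  if (pos_lo > pos_hi || ang_sd < 0) os_abort("invalid noise spec", "invalid_argument")
  structure(list(pos_lo = pos_lo, pos_hi = pos_hi, ang_sd = ang_sd),
            class = "noise_spec")
}

#' @rdname tracker_noise_spec
#' @export
device_band_noise_spec <- function() {
  tracker_noise_spec(-0.308 / sqrt(3), 0.136 / sqrt(3), 0.05)
}

#' @rdname tracker_noise_spec
#' @export
zero_noise_spec <- function() tracker_noise_spec(0, 0, 0)

#' Simulate a 6DOF tracker pose stream
#'
#' Samples a time-parametrized rigid motion at a fixed rate and emits
#' timestamped poses (position in mm, azimuth/elevation/roll in degrees),
#' the dataset the emulated tracker streams at 60 Hz. Optional noise
#' perturbs positions and angles independently per sample.
#'
#' @param true_motion either a function `t -> rigid_transform` or a single
#'   `rigid_transform` (static pose).
#' @param duration_s stream duration in seconds.
#' @param rate_hz sampling rate (default 60).
#' @param noise_spec a [tracker_noise_spec()]; `NULL` or
#'   [zero_noise_spec()] reproduces the motion exactly.
#' @param seed integer seed for the noise draws.
#' @return A `data.frame` of class `pose_stream` with columns
#'   `t_s, x_mm, y_mm, z_mm, azimuth_deg, elevation_deg, roll_deg`.
#' @export
simulate_tracker_stream <- function(true_motion, duration_s = 1, rate_hz = 60,
                                    noise_spec = NULL, seed = 1L) {
  if (rate_hz <= 0) os_abort("rate_hz must be > 0", "invalid_argument")
  if (duration_s <= 0) os_abort("duration_s must be > 0", "invalid_argument")
  motion <- if (inherits(true_motion, "rigid_transform")) {
    force(true_motion); function(t) true_motion
  } else true_motion
  n <- round(duration_s * rate_hz)
  t_s <- (seq_len(n) - 1L) / rate_hz
  pos <- matrix(0, n, 3)
  ang <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    tf <- motion(t_s[i])
    pos[i, ] <- tf$translation
    ang[i, ] <- rotation_to_euler(tf$rotation)
  }
  if (!is.null(noise_spec) &&
      (noise_spec$pos_lo != 0 || noise_spec$pos_hi != 0 || noise_spec$ang_sd != 0)) {
    with_seed(seed, {
      pos <- pos + matrix(runif(3L * n, noise_spec$pos_lo, noise_spec$pos_hi), n, 3)
      ang <- ang + matrix(rnorm(3L * n, 0, noise_spec$ang_sd), n, 3)
    })
    ang[, 1] <- wrap_angle(ang[, 1])
    ang[, 3] <- wrap_angle(ang[, 3])
    ang[, 2] <- pmax(-90, pmin(90, ang[, 2]))
  }
  out <- data.frame(t_s = t_s, x_mm = pos[, 1], y_mm = pos[, 2], z_mm = pos[, 3],
                    azimuth_deg = ang[, 1], elevation_deg = ang[, 2],
                    roll_deg = ang[, 3])
  class(out) <- c("pose_stream", "data.frame")
  out
}

#' Write / read a pose stream as CSV
#' @param stream a `pose_stream` data frame.
#' @param path CSV path with header
#'   `t_s,x_mm,y_mm,z_mm,azimuth_deg,elevation_deg,roll_deg`.
#' @return `write_pose_stream`: the path invisibly; `read_pose_stream`: a
#'   `pose_stream`.
#' @export
write_pose_stream <- function(stream, path) {
  write.csv(as.data.frame(stream), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pose_stream
#' @export
read_pose_stream <- function(path) {
  df <- read.csv(path)
  need <- c("t_s", "x_mm", "y_mm", "z_mm", "azimuth_deg", "elevation_deg", "roll_deg")
  if (!all(need %in% names(df))) {
    os_abort("pose stream CSV missing required columns", "invalid_argument")
  }
  df <- df[, need]
  class(df) <- c("pose_stream", "data.frame")
  df
}
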