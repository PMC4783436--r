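test_that("skull volume is deterministic, strictly intensity-ordered and carries ground truth", {
  cfg <- small_config()
  a <- generate_skull_volume(cfg, seed = 7)
  b <- generate_skull_volume(cfg, seed = 7)
  expect_identical(a$volume$intensities, b$volume$intensities)
  ints <- sort(unique(as.numeric(a$volume$intensities)))
  expect_equal(ints, c(cfg$intensity_air, cfg$intensity_soft,
                       cfg$intensity_bone, cfg$intensity_titanium))
  gt <- a$ground_truth
  expect_equal(rownames(gt$sphere_centers),
               c("incisal", "right_molar", "left_molar"))
  expect_true(all(dist(gt$sphere_centers) > 20))
})

test_that("exactly three clusters sit above the titanium threshold, centered on ground truth", {
  res <- generate_skull_volume(phantom_config(), seed = 7)
  thr <- (res$ground_truth$config$intensity_bone +
            res$ground_truth$config$intensity_titanium) / 2
  comps <- label_components(res$volume, thr)
  expect_length(comps, 3)
  # brute-force intensity-weighted centroid agreement with ground truth
  got <- t(vapply(comps, function(cm) cm$centroid, numeric(3)))
  for (i in 1:3) {
    err <- min(sqrt(rowSums(sweep(got, 2, res$ground_truth$sphere_centers[i, ])^2)))
    expect_lt(err, 0.5 * max(res$volume$spacing))
  }
})

test_that("with zero asymmetry offset the volume is mirror symmetric about the mid-sagittal plane", {
  res <- generate_skull_volume(small_config(), seed = 1)
  v <- res$volume$intensities
  flipped <- v[dim(v)[1]:1, , ]
  expect_lt(max(abs(v - flipped)), 1e-6)
})

test_that("an asymmetry offset moves the mandible and its landmarks, not the mid-sagittal plane", {
  off <- c(4, 0, 0)
  res <- generate_skull_volume(small_config(asymmetry_offset_mm = off), seed = 1)
  expect_equal(res$ground_truth$midsagittal_plane$normal, c(1, 0, 0))
  base <- generate_skull_volume(small_config(), seed = 1)
  expect_equal(res$ground_truth$landmark_points$incisor,
               base$ground_truth$landmark_points$incisor + off)
})

test_that("too-coarse voxel spacing for the spheres raises a resolution error", {
  expect_error(
    generate_skull_volume(phantom_config(shape = c(32L, 32L, 32L),
                                         spacing_mm = c(4, 4, 4)), seed = 1),
    class = "resolution_error")
})

test_that("dental arches: artifact corruption count, labels and landmark names", {
  cfg <- phantom_config(artifact_fraction = 0.4)
  res <- generate_dental_arches(cfg, seed = 5)
  n <- nrow(res$scan_mesh$vertices)
  expect_equal(sum(!res$ct_dentition_mesh$artifact_free), floor(0.4 * n))
  expect_identical(res$scan_mesh$artifact_free, res$ct_dentition_mesh$artifact_free)
  expect_equal(names(res$scan_mesh$landmarks),
               c("incisor", "right_molar", "left_molar"))
  expect_error(phantom_config(artifact_fraction = 1), class = "invalid_argument")
})

test_that("zero artifact fraction gives a CT dentition that is exactly the transformed scan", {
  res <- generate_dental_arches(phantom_config(artifact_fraction = 0), seed = 2)
  moved <- apply_transform(res$ground_truth$scan_to_ct_transform,
                           res$scan_mesh$vertices)
  expect_lt(max(abs(moved - res$ct_dentition_mesh$vertices)), 1e-9)
  expect_true(all(res$ct_dentition_mesh$artifact_free))
})

test_that("generated meshes contain no degenerate triangles", {
  for (mesh in list(generate_dental_arches(phantom_config(), 1)$scan_mesh,
                    generate_mandible_mesh(phantom_config(), 1)$mesh)) {
    v <- mesh$vertices
    e1 <- v[mesh$triangles[, 2], ] - v[mesh$triangles[, 1], ]
    e2 <- v[mesh$triangles[, 3], ] - v[mesh$triangles[, 1], ]
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    expect_gt(min(sqrt(rowSums(cr^2)) / 2), 1e-6)
  }
})

test_that("mandible mesh lower border lies exactly on the ground-truth quartic", {
  res <- generate_mandible_mesh(phantom_config(), seed = 1)
  lb <- res$mesh$vertices[res$mesh$region_labels == "lower_border", , drop = FALSE]
  expect_gte(nrow(lb), 20)
  # canonical coefficients describe -y about the curve maximum at x = 0
  cf <- res$ground_truth$mlb_coefficients
  pred_y <- 35 - cf[3] * lb[, 1]^2 - cf[5] * lb[, 1]^4
  expect_lt(max(abs(lb[, 2] - pred_y)), 1e-9)
})

test_that("a static zero-noise stream reproduces the pose at the printed 60 Hz timing", {
  stream <- simulate_tracker_stream(identity_transform(), duration_s = 1,
                                    rate_hz = 60, noise_spec = zero_noise_spec())
  expect_equal(nrow(stream), 60)
  expect_true(all(stream$x_mm == 0) && all(stream$azimuth_deg == 0))
  expect_equal(unique(round(diff(stream$t_s), 12)), 1 / 60)
  interval_ms <- floor(diff(stream$t_s)[1] * 1000 / 0.1) * 0.1
  expect_equal(interval_ms, 16.6)
})

test_that("tracker noise respects the device band and streams are seed-deterministic", {
  motion <- function(t) rigid_transform(euler_to_rotation(c(10 * t, 0, 0)),
                                        c(100 * t, 0, 0))
  s1 <- simulate_tracker_stream(motion, 1, 60, device_band_noise_spec(), seed = 4)
  s2 <- simulate_tracker_stream(motion, 1, 60, device_band_noise_spec(), seed = 4)
  expect_identical(s1, s2)
  clean <- simulate_tracker_stream(motion, 1, 60, NULL)
  err <- sqrt((s1$x_mm - clean$x_mm)^2 + (s1$y_mm - clean$y_mm)^2 +
                (s1$z_mm - clean$z_mm)^2)
  expect_lt(max(err), 0.308 + 1e-12)
  expect_gt(max(err), 0)  # noise is actually applied
  expect_error(simulate_tracker_stream(motion, 1, rate_hz = 0),
               class = "invalid_argument")
})

test_that("pose streams round-trip through CSV", {
  stream <- simulate_tracker_stream(identity_transform(), 0.1, 60)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pose_stream(stream, path)
  expect_equal(readLines(path, n = 1),
               '"t_s","x_mm","y_mm","z_mm","azimuth_deg","elevation_deg","roll_deg"')
  back <- read_pose_stream(path)
  expect_equal(as.data.frame(back), as.data.frame(stream), tolerance = 1e-12)
})

test_that("orbital point sets are exact mirrors when noiseless", {
  orb <- generate_orbita_points(phantom_config(), seed = 3)
  mirrored <- orb$right
  mirrored[, 1] <- -mirrored[, 1]
  expect_lt(max(abs(orb$left - mirrored)), 1e-12)
})
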