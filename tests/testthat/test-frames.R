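test_that("mirror-plane fit recovers a constructed symmetry plane", {
  set.seed(5)
  left <- cbind(runif(60, 12, 30), runif(60, -20, 20), runif(60, 0, 25))
  plane_x <- 10
  right <- left
  right[, 1] <- 2 * plane_x - right[, 1]  # exact mirror across x = 10
  fit <- fit_midsagittal_plane(left, right)
  expect_lt(acos(min(1, abs(fit$normal[1]))) * 180 / pi, 0.1)  # normal vs +X
  expect_lt(abs(sum(fit$normal * fit$point) - plane_x), 0.01)
  expect_lt(fit$asymmetry_cost, 1e-6)
})

test_that("mirror-plane fit tolerates jitter and is equivariant under rigid motion", {
  for (s in 1:20) {
    orb <- generate_orbita_points(phantom_config(), seed = s, noise_sd = 0.1)
    fit <- fit_midsagittal_plane(orb$left, orb$right)
    ang <- acos(min(1, abs(fit$normal[1]))) * 180 / pi
    expect_lt(ang, 1)
  }
  # equivariance: moving both point sets moves the plane with them
  orb <- generate_orbita_points(phantom_config(), seed = 31)
  tf <- rigid_transform(euler_to_rotation(c(20, 10, -5)), c(8, -3, 12))
  fit0 <- fit_midsagittal_plane(orb$left, orb$right)
  fit1 <- fit_midsagittal_plane(apply_transform(tf, orb$left),
                                apply_transform(tf, orb$right))
  n_expected <- as.numeric(tf$rotation %*% fit0$normal)
  ang <- acos(min(1, abs(sum(fit1$normal * n_expected)))) * 180 / pi
  expect_lt(ang, 0.2)
  p_expected <- apply_transform(tf, fit0$point)
  expect_lt(abs(sum((p_expected - fit1$point) * fit1$normal)), 0.05)
})

test_that("degenerate orbital input is rejected", {
  pts <- matrix(rnorm(36), 12, 3)
  expect_error(fit_midsagittal_plane(pts, pts), class = "degenerate_configuration")
  expect_error(fit_midsagittal_plane(pts[1:5, ], pts), class = "invalid_argument")
})

test_that("cranial frame equals world axes on the symmetric phantom and rotates with it", {
  orb <- generate_orbita_points(phantom_config(), seed = 2)
  plane <- fit_midsagittal_plane(orb$left, orb$right)
  lmk <- list(orbita_left_centroid = colMeans(orb$left),
              orbita_right_centroid = colMeans(orb$right))
  frame <- build_cranial_frame(plane, lmk)
  expect_lt(max(abs(frame$axes - diag(3))), 1e-5)
  expect_lt(abs(frame$origin[1]), 1e-5)
  # equivariance under a known rigid motion of the whole head; the frame's
  # superior axis is anchored to world +Z, so the motion must preserve it
  # (a yaw plus translation, the usual head-positioning variation)
  tf <- rigid_transform(euler_to_rotation(c(12, 0, 0)), c(6, -4, 9))
  plane2 <- fit_midsagittal_plane(apply_transform(tf, orb$left),
                                  apply_transform(tf, orb$right))
  frame2 <- build_cranial_frame(plane2, list(
    orbita_left_centroid = apply_transform(tf, lmk$orbita_left_centroid),
    orbita_right_centroid = apply_transform(tf, lmk$orbita_right_centroid)))
  expect_lt(rotation_angle_deg(frame2$axes, tf$rotation %*% frame$axes), 0.2)
})

test_that("quartic lower-border fit is the exact least-squares solution", {
  # synthetic quartic sampled exactly
  x <- seq(-10, 10, length.out = 41)
  y <- 0.001 * x^4 + 0.05 * x^2
  pts <- cbind(x, y, 0)
  res <- fit_mlb_frame(pts)
  cf <- res$curve$coefficients
  expect_lt(abs(cf[5] - 0.001) / 0.001, 1e-6)
  expect_lt(abs(cf[3] - 0.05) / 0.05, 1e-6)
  expect_lt(max(abs(cf[c(1, 2, 4)])), 1e-8)
  expect_lt(res$curve$rms_fit_error, 1e-9)
  # least-squares agreement with a normal-equations oracle on noisy data
  set.seed(23)
  for (trial in 1:5) {
    xs <- runif(120, -25, 25)
    ys <- 30 - 0.018 * xs^2 - 8e-6 * xs^4 + rnorm(120, 0, 0.3)
    pts <- cbind(xs, ys, 5)
    res <- fit_mlb_frame(pts)
    # reproduce the fit in the same in-plane coordinates and compare residuals
    ctr <- colMeans(pts)
    w <- res$curve$fit_plane$width_axis
    d <- res$curve$fit_plane$depth_axis
    a <- as.numeric(sweep(pts, 2, ctr) %*% w)
    b <- as.numeric(sweep(pts, 2, ctr) %*% d)
    oracle <- normal_equations_quartic(a, b)
    pred <- drop(outer(a, 0:4, "^") %*% oracle)
    rms_oracle <- sqrt(mean((b - pred)^2))
    expect_equal(res$curve$rms_fit_error, rms_oracle, tolerance = 1e-9)
  }
})

test_that("MLB frame of the phantom mandible sits on the mid-sagittal trace", {
  res <- generate_mandible_mesh(phantom_config(), seed = 1)
  lb <- res$mesh$vertices[res$mesh$region_labels == "lower_border", , drop = FALSE]
  mlb <- fit_mlb_frame(lb)
  expect_lt(abs(mlb$frame$origin[1]), 0.1)  # midline on the x = 0 plane
  cf <- mlb$curve$coefficients
  gt <- res$ground_truth$mlb_coefficients
  expect_equal(cf[3], gt[3], tolerance = 1e-6)
  expect_equal(cf[5], gt[5], tolerance = 1e-6)
  # 0.1 mm jitter shows up as an rms fit error of the same order
  set.seed(9)
  errs <- replicate(20, {
    noisy <- lb + matrix(rnorm(length(lb), 0, 0.1), nrow(lb), 3)
    fit_mlb_frame(noisy)$curve$rms_fit_error
  })
  expect_true(all(errs > 0.05 & errs < 0.2))
})

test_that("degenerate lower borders are rejected", {
  line <- cbind(seq(0, 30, length.out = 25), 0, 0)
  expect_error(fit_mlb_frame(line), class = "degenerate_configuration")
  narrow <- cbind(runif(25, 0, 5), runif(25, 0, 5), runif(25, 0, 5))
  expect_error(fit_mlb_frame(narrow), class = "degenerate_configuration")
})

test_that("asymmetry report: symmetric phantom is flat, ramus offset is localized", {
  cfg <- phantom_config()
  sym <- generate_mandible_mesh(cfg, seed = 1)
  orb <- generate_orbita_points(cfg, seed = 1)
  plane <- fit_midsagittal_plane(orb$left, orb$right)
  frame <- build_cranial_frame(plane, list(
    orbita_left_centroid = colMeans(orb$left),
    orbita_right_centroid = colMeans(orb$right)))
  rep0 <- asymmetry_report(sym$mesh, frame)
  # midline landmark on the mid-sagittal plane; bilateral molars balanced
  expect_lt(abs(rep0$landmark_deviation_mm[["incisor"]]), 1e-5)
  expect_lt(abs(rep0$landmark_deviation_mm[["left_molar"]] +
                  rep0$landmark_deviation_mm[["right_molar"]]), 1e-5)
  expect_lt(rep0$region_mirror_distance_mm[["ramus"]], 1e-5)
  # ramus-only lateral offset: ramus mirror distance ~ offset, teeth unmoved
  asym <- generate_mandible_mesh(phantom_config(ramus_offset_mm = 4), seed = 1)
  rep1 <- asymmetry_report(asym$mesh, frame)
  expect_gt(rep1$region_mirror_distance_mm[["ramus"]], 3)
  expect_lt(abs(rep1$region_mirror_distance_mm[["ramus"]] - 4), 1)
  expect_lt(abs(rep1$landmark_deviation_mm[["incisor"]]), 1e-5)
  # signed landmark convention: negative offset reported toward the right
  rep2 <- asymmetry_report(sym$mesh, frame,
                           landmarks = list(probe = c(-3, 10, 0)))
  expect_equal(unname(rep2$landmark_deviation_mm["probe"]), -3, tolerance = 1e-5)
  rep3 <- asymmetry_report(sym$mesh, frame, landmarks = list(probe = c(3, 0, 0)))
  expect_equal(unname(rep3$landmark_deviation_mm["probe"]), 3, tolerance = 1e-5)
})

test_that("mirroring a mesh across the mid-plane negates all signed deviations", {
  cfg <- phantom_config(asymmetry_offset_mm = c(2.5, 0, 0))
  res <- generate_mandible_mesh(cfg, seed = 1)
  frame <- anatomy_frame(c(0, 0, 0), diag(3), "cranial")
  rep_a <- asymmetry_report(res$mesh, frame)
  mirrored <- res$mesh
  mirrored$vertices[, 1] <- -mirrored$vertices[, 1]
  mirrored$landmarks <- lapply(mirrored$landmarks, function(p) p * c(-1, 1, 1))
  rep_b <- asymmetry_report(mirrored, frame)
  expect_equal(rep_b$landmark_deviation_mm, -rep_a$landmark_deviation_mm,
               tolerance = 1e-12)
})
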