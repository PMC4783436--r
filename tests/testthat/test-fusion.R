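test_that("ICP recovers a known rigid offset exactly on clean identical surfaces", {
  ar <- generate_dental_arches(phantom_config(artifact_fraction = 0), seed = 1)
  icp <- icp_register(ar$scan_mesh, ar$ct_dentition_mesh, source_mask = NULL)
  gt <- ar$ground_truth$scan_to_ct_transform
  expect_true(icp$converged)
  expect_lt(icp$rms_residual, 1e-6)
  expect_lt(max(abs(icp$transform$translation - gt$translation)), 1e-4)
  expect_lt(rotation_angle_deg(icp$transform$rotation, gt$rotation), 1e-4)
})

test_that("identical source and target converge immediately to the identity", {
  ar <- generate_dental_arches(phantom_config(), seed = 2)
  icp <- icp_register(ar$scan_mesh, ar$scan_mesh, source_mask = NULL)
  expect_true(icp$converged)
  expect_lte(icp$iterations_used, 2)
  expect_lt(icp$rms_residual, 1e-12)
  expect_lt(max(abs(icp$transform$rotation - diag(3))), 1e-9)
})

test_that("masked ICP on a 40% artifact-corrupted arch recovers the scan-to-CT transform", {
  ar <- generate_dental_arches(phantom_config(artifact_fraction = 0.4), seed = 3)
  icp <- icp_register(ar$scan_mesh, ar$ct_dentition_mesh,
                      source_mask = "artifact_free")
  gt <- ar$ground_truth$scan_to_ct_transform
  expect_true(icp$converged)
  expect_lt(max(abs(icp$transform$translation - gt$translation)), 0.05)
  expect_lt(rotation_angle_deg(icp$transform$rotation, gt$rotation), 0.1)
})

test_that("ICP residual is non-increasing across iterations and capture range holds", {
  ar <- generate_dental_arches(phantom_config(artifact_fraction = 0.3,
                                              ct_offset_angles_deg = c(0, 0, 0),
                                              ct_offset_translation_mm = c(0, 0, 0)),
                               seed = 4)
  set.seed(21)
  ok <- 0L
  for (trial in 1:20) {
    extra <- rigid_transform(
      euler_to_rotation(runif(3, -10, 10)), runif(3, -10, 10))
    target <- ar$ct_dentition_mesh
    target$vertices <- apply_transform(extra, target$vertices)
    icp <- icp_register(ar$scan_mesh, target, source_mask = "artifact_free",
                        max_iterations = 300)
    expect_true(all(diff(icp$rms_history) <= 1e-9))
    if (icp$converged &&
        max(abs(icp$transform$translation - extra$translation)) < 0.05 &&
        rotation_angle_deg(icp$transform$rotation, extra$rotation) < 0.1) {
      ok <- ok + 1L
    }
  }
  expect_equal(ok, 20L)  # offsets up to 10 mm / 10 deg are all captured
})

test_that("an unreachable iteration budget reports non-convergence honestly", {
  ar <- generate_dental_arches(phantom_config(artifact_fraction = 0.3), seed = 4)
  extra <- rigid_transform(euler_to_rotation(c(9, -8, 7)), c(9, -9, 8))
  target <- ar$ct_dentition_mesh
  target$vertices <- apply_transform(extra, target$vertices)
  icp <- icp_register(ar$scan_mesh, target, source_mask = "artifact_free",
                      max_iterations = 5L)
  expect_false(icp$converged)
  expect_lte(icp$iterations_used, 5L)
})

test_that("degenerate and invalid ICP inputs are rejected", {
  ar <- generate_dental_arches(phantom_config(), seed = 5)
  mask <- rep(FALSE, nrow(ar$scan_mesh$vertices))
  mask[1:2] <- TRUE
  expect_error(icp_register(ar$scan_mesh, ar$ct_dentition_mesh, source_mask = mask),
               class = "degenerate_configuration")
  bad <- ar$scan_mesh
  bad$vertices[1, 1] <- NaN
  expect_error(icp_register(bad, ar$ct_dentition_mesh, source_mask = NULL),
               class = "invalid_argument")
})

test_that("fusion replaces the CT dental region by the transformed scan", {
  ar <- generate_dental_arches(phantom_config(artifact_fraction = 0), seed = 6)
  # embed the CT dentition in a larger CT mesh with non-dental bone
  mand <- generate_mandible_mesh(phantom_config(), seed = 6)$mesh
  mand$region_labels[mand$region_labels == "dental"] <- "body"
  ct_full <- concat_meshes(mand, ar$ct_dentition_mesh)
  icp <- icp_register(ar$scan_mesh, ar$ct_dentition_mesh, source_mask = NULL)
  fused <- fuse_dentition(ct_full, ar$scan_mesh, icp)
  n_ct <- nrow(ct_full$vertices)
  n_dental <- sum(ct_full$region_labels == "dental")
  expect_equal(nrow(fused$vertices),
               n_ct - n_dental + nrow(ar$scan_mesh$vertices))
  # provenance labels and the definitional from_scan placement
  from_scan <- fused$region_labels == "from_scan"
  expect_equal(sum(from_scan), nrow(ar$scan_mesh$vertices))
  expect_lt(max(abs(fused$vertices[from_scan, ] -
                      apply_transform(icp$transform, ar$scan_mesh$vertices))), 1e-9)
  # zero-artifact phantom: fused dental surface coincides with ground truth
  gt_dent <- apply_transform(ar$ground_truth$scan_to_ct_transform,
                             ar$scan_mesh$vertices)
  hausdorff <- max(
    max(orthosim:::nearest_neighbor(fused$vertices[from_scan, ], gt_dent)$distance),
    max(orthosim:::nearest_neighbor(gt_dent, fused$vertices[from_scan, ])$distance))
  expect_lt(hausdorff, 1e-6)
})

test_that("fusion refuses an unconverged registration and is idempotent under relabeling", {
  ar <- generate_dental_arches(phantom_config(artifact_fraction = 0), seed = 7)
  icp <- icp_register(ar$scan_mesh, ar$ct_dentition_mesh, source_mask = NULL)
  bad <- icp
  bad$converged <- FALSE
  expect_error(fuse_dentition(ar$ct_dentition_mesh, ar$scan_mesh, bad),
               class = "unconverged_registration")
  fused <- fuse_dentition(ar$ct_dentition_mesh, ar$scan_mesh, icp)
  # relabel the scan part as dental and re-fuse with an identity ICP
  refuse_input <- fused
  refuse_input$region_labels[refuse_input$region_labels == "from_scan"] <- "dental"
  scan_moved <- transform_mesh(ar$scan_mesh, icp$transform)
  ident_icp <- icp_register(scan_moved, scan_moved, source_mask = NULL)
  refused <- fuse_dentition(refuse_input, scan_moved, ident_icp)
  expect_equal(dim(refused$vertices), dim(fused$vertices))
  expect_lt(max(abs(sort(refused$vertices[, 1]) - sort(fused$vertices[, 1]))), 1e-9)
})
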