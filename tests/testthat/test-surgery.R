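phantom_split <- function(scheme = "bilateral_SSRO", cfg = phantom_config()) {
  mand <- generate_mandible_mesh(cfg, seed = 1)
  list(model = split_mandible(mand$mesh, osteotomy_plan(scheme)),
       mesh = mand$mesh)
}

test_that("splitting partitions the vertices without loss or duplication", {
  ps <- phantom_split()
  model <- ps$model
  expect_setequal(names(model$segments), c("distal", "proximal_left", "proximal_right"))
  idx <- sort(unname(unlist(lapply(model$segments, `[[`, "orig_index"))))
  expect_identical(idx, seq_len(nrow(ps$mesh$vertices)))
  # all dental vertices are distal, all condyle vertices are proximal
  expect_true(all(model$segments$distal$region_labels != "condyle_left"))
  expect_true(all(model$segments$distal$region_labels != "condyle_right"))
  expect_true(any(model$segments$proximal_left$region_labels == "condyle_left"))
  expect_false(any(model$segments$proximal_left$region_labels %in%
                     c("dental", "condyle_right", "ramus_right")))
})

test_that("a unilateral plan keeps the un-cut side attached to the distal segment", {
  ps <- phantom_split("unilateral_SSRO_left")
  model <- ps$model
  expect_setequal(names(model$segments), c("distal", "proximal_left"))
  expect_true(any(model$segments$distal$region_labels == "condyle_right"))
  expect_false(any(model$segments$distal$region_labels == "condyle_left"))
})

test_that("invalid plans fail loudly", {
  mand <- generate_mandible_mesh(phantom_config(), seed = 1)$mesh
  far <- osteotomy_plan("unilateral_SSRO_left",
                        list(list(point = c(0, 0, 1e6), normal = c(0, 0, 1))))
  expect_error(split_mandible(mand, far), class = "empty_segment")
  # a cut through the middle puts teeth on the proximal side
  mid <- osteotomy_plan("unilateral_SSRO_left",
                        list(list(point = c(0, 0, 0), normal = c(0, 0, -1))))
  expect_error(split_mandible(mand, mid), class = "plan_validity")
  expect_error(osteotomy_plan("bilateral_SSRO",
                              list(list(point = c(0, 0, 0), normal = c(1, 0, 0)))),
               class = "invalid_argument")
})

test_that("segment transforms move only the distal segment and preserve rigidity", {
  ps <- phantom_split()
  model <- ps$model
  same <- apply_segment_transform(model, identity_transform())
  expect_identical(same$segments$distal$vertices, model$segments$distal$vertices)
  tf <- rigid_transform(diag(3), c(0, 5, 0))
  moved <- apply_segment_transform(model, tf)
  expect_equal(moved$segments$distal$vertices,
               sweep(model$segments$distal$vertices, 2, c(0, 5, 0), "+"))
  expect_identical(moved$segments$proximal_left$vertices,
                   model$segments$proximal_left$vertices)
  # rigidity: pairwise distances within the distal segment are preserved
  set.seed(2)
  rot <- random_transform()
  rotated <- apply_segment_transform(model, rot)
  pick <- sample(nrow(model$segments$distal$vertices), 30)
  d0 <- dist(model$segments$distal$vertices[pick, ])
  d1 <- dist(rotated$segments$distal$vertices[pick, ])
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("correcting the phantom's lateral asymmetry zeroes the tooth-bearing deviation", {
  cfg <- phantom_config(asymmetry_offset_mm = c(3, 0, 0))
  mand <- generate_mandible_mesh(cfg, seed = 1)
  # cuts planned on the displaced anatomy (shifted with the mandible)
  plan <- osteotomy_plan("bilateral_SSRO",
                         list(list(point = c(29, 0, 0), normal = c(1, 0, 0)),
                              list(point = c(-23, 0, 0), normal = c(-1, 0, 0))))
  model <- split_mandible(mand$mesh, plan)
  frame <- anatomy_frame(c(0, 0, 0), diag(3), "cranial")
  before <- asymmetry_report(mand$mesh, frame)
  expect_equal(unname(before$landmark_deviation_mm["incisor"]), 3, tolerance = 1e-9)
  corrected <- apply_segment_transform(model, rigid_transform(diag(3), c(-3, 0, 0)))
  after <- asymmetry_report(corrected$segments$distal, frame,
                            landmarks = lapply(mand$mesh$landmarks,
                                               function(p) p + c(-3, 0, 0)))
  # denture midline back on the mid-sagittal plane, molars rebalanced
  expect_lt(abs(after$landmark_deviation_mm[["incisor"]]), 0.1)
  expect_lt(abs(after$landmark_deviation_mm[["left_molar"]] +
                  after$landmark_deviation_mm[["right_molar"]]), 0.1)
})

test_that("superimposition reports regional displacement means", {
  ps <- phantom_split("unilateral_SSRO_left")
  model <- ps$model
  same <- superimpose_compare(model, model)
  expect_true(all(unlist(same$per_vertex_mm) == 0))
  # 7 mm antero-inferior advancement of the distal segment
  adv <- c(0, 7 / sqrt(2), -7 / sqrt(2))
  moved <- apply_segment_transform(model, rigid_transform(diag(3), adv))
  cmp <- superimpose_compare(model, moved)
  tb <- cmp$regions[cmp$regions$region == "tooth_bearing", ]
  expect_equal(tb$mean_mm, 7, tolerance = 1e-9)
  expect_equal(cmp$regions[cmp$regions$region == "condyle_left", "mean_mm"], 0)
  # under a bilateral plan neither condyle moves with the distal segment
  bi <- phantom_split()$model
  bimoved <- apply_segment_transform(bi, rigid_transform(diag(3), adv))
  bicmp <- superimpose_compare(bi, bimoved)
  expect_equal(bicmp$regions[bicmp$regions$region %in%
                               c("condyle_left", "condyle_right"), "mean_mm"],
               c(0, 0))
  other <- split_mandible(generate_mandible_mesh(phantom_config(ramus_offset_mm = 2),
                                                 seed = 1)$mesh,
                          osteotomy_plan("bilateral_SSRO"))
  expect_error(superimpose_compare(model, other), class = "invalid_argument")
})

test_that("a pose-driven session reproduces known motion and conserves the partition", {
  mand <- generate_mandible_mesh(phantom_config(), seed = 1)$mesh
  plan <- osteotomy_plan("bilateral_SSRO")
  sph <- rbind(incisal = c(0, 45, -5), right_molar = c(-20, 25, -5),
               left_molar = c(20, 25, -5))
  calib <- calibrate_splint(sph, sph)  # V = identity
  m_fn <- function(t) rigid_transform(euler_to_rotation(c(2 * t, 0, 0)),
                                      c(0, 3 * t, 0))
  stream <- simulate_tracker_stream(m_fn, duration_s = 1, rate_hz = 60)
  session <- run_session(mand, plan, stream, calib)
  expect_length(session$trajectory, 60)
  m_last <- m_fn(stream$t_s[60])
  expect_lt(max(abs(session$final$segments$distal$vertices -
                      apply_transform(m_last, session$initial$segments$distal$vertices))),
            1e-9)
  idx <- sort(unname(unlist(lapply(session$final$segments, `[[`, "orig_index"))))
  expect_identical(idx, seq_len(nrow(mand$vertices)))
  # static stream: final equals initial
  static <- simulate_tracker_stream(identity_transform(), 0.2, 60)
  s2 <- run_session(mand, plan, static, calib)
  expect_equal(s2$final$segments$distal$vertices,
               s2$initial$segments$distal$vertices, tolerance = 1e-12)
  expect_error(run_session(mand, plan, static[0, ], calib),
               class = "invalid_argument")
})
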