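# Orchestration: run configuration with documented defaults, validation
# that rejects unknown keys, and the end-to-end demo chaining
# phantom -> detection -> fusion -> calibration -> simulation -> VCI ->
# accuracy protocol.

#' Default run configuration
#'
#' A nested list of every pipeline parameter with its default. A
#' configuration (optionally loaded from JSON) is validated against this
#' template: unknown keys are rejected, missing keys filled from defaults.
#'
#' @return A list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    phantom = list(
      shape = c(128L, 128L, 128L),
      spacing_mm = c(1, 1, 1),
      sphere_diameter_mm = 6,
      sphere_jitter_mm = 0,
      asymmetry_offset_mm = c(0, 0, 0),
      ramus_offset_mm = 0,
      artifact_fraction = 0.3
    ),
    detection = list(threshold = NULL),
    icp = list(max_iterations = 100L, tolerance_mm = 1e-6, trim_fraction = 0.1),
    session = list(duration_s = 2, rate_hz = 60,
                   noise = "device_band",
                   scheme = "bilateral_SSRO"),
    vci = list(mm_per_px = 1, film_size_mm = c(160, 160)),
    evaluate = list(n_repetitions = 25L, noise = "device_band",
                    translation_range_mm = 10, rotation_range_deg = 10)
  ), class = "run_config")
}

noise_from_name <- function(name) {
  switch(name,
         device_band = device_band_noise_spec(),
         zero = zero_noise_spec(),
         os_abort(sprintf("unknown noise spec '%s' (use 'device_band' or 'zero')",
                          name), "invalid_argument"))
}

merge_config <- function(user, template, path = "") {
  if (is.null(user)) return(template)
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(template))
  if (length(unknown)) {
    os_abort(sprintf("unknown configuration key%s: %s",
                     if (length(unknown) > 1) "s" else "",
                     paste0(path, unknown, collapse = ", ")),
             "invalid_argument")
  }
  for (nm in names(user)) {
    template[[nm]] <- if (is.list(template[[nm]]) && !is.null(names(template[[nm]]))) {
      merge_config(user[[nm]], template[[nm]], paste0(path, nm, "."))
    } else user[[nm]]
  }
  template
}

#' Validate (and complete) a run configuration
#'
#' @param config a partial configuration list, a JSON file path, or `NULL`
#'   for pure defaults.
#' @return A complete `run_config`; unknown keys raise an error naming the
#'   key.
#' @export
validate_run_config <- function(config = NULL) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  out <- merge_config(config, unclass(default_run_config()))
  class(out) <- "run_config"
  out
}

#' Run the end-to-end demonstration pipeline
#'
#' Chains every stage on the synthetic phantom and writes all artifacts to
#' `out_dir`: the phantom CT volume and meshes, sphere-detection JSON, the
#' fused dento-skeletal mesh with an ICP report, the splint calibration,
#' a simulated osteotomy session with its transform log, original and
#' simulated virtual cephalograms, the diagnostic frames with an asymmetry
#' report, and the accuracy protocol CSV. Deterministic given the
#' configuration (rerunning reproduces identical JSON/CSV outputs).
#'
#' @param config a `run_config`, partial list, JSON path or `NULL`.
#' @param out_dir writable output directory (created if needed).
#' @param seed overrides `config$seed` when non-`NULL`.
#' @param quiet suppress per-stage messages.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_demo <- function(config = NULL, out_dir = "orthosim-demo", seed = NULL,
                     quiet = FALSE) {
  cfg <- validate_run_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  paths <- list()
  pc <- do.call(phantom_config, cfg$phantom)

  say("[phantom] generating CT volume, dental arches, mandible (seed %d)", cfg$seed)
  skull <- generate_skull_volume(pc, seed = cfg$seed)
  arches <- generate_dental_arches(pc, seed = cfg$seed)
  mand <- generate_mandible_mesh(pc, seed = cfg$seed)
  paths$volume <- file.path(out_dir, "phantom_ct.nii.gz")
  write_volume(skull$volume, paths$volume)
  paths$scan_mesh <- file.path(out_dir, "dental_scan.stl")
  write_mesh(arches$scan_mesh, paths$scan_mesh)
  paths$ct_dentition <- file.path(out_dir, "ct_dentition.stl")
  write_mesh(arches$ct_dentition_mesh, paths$ct_dentition)
  paths$mandible <- file.path(out_dir, "mandible.stl")
  write_mesh(mand$mesh, paths$mandible)

  say("[detect-spheres] labeling components")
  spheres <- detect_reference_spheres(skull$volume, pc$sphere_diameter_mm,
                                      threshold = cfg$detection$threshold)
  paths$spheres <- file.path(out_dir, "spheres.json")
  write_spheres_json(spheres, paths$spheres)

  say("[fuse] ICP registration of scan onto CT dentition")
  icp <- icp_register(arches$scan_mesh, arches$ct_dentition_mesh,
                      source_mask = "artifact_free",
                      max_iterations = cfg$icp$max_iterations,
                      tolerance_mm = cfg$icp$tolerance_mm,
                      trim_fraction = cfg$icp$trim_fraction)
  fused <- fuse_dentition(arches$ct_dentition_mesh, arches$scan_mesh, icp)
  paths$fused <- file.path(out_dir, "fused.stl")
  write_mesh(fused, paths$fused)
  paths$icp_report <- file.path(out_dir, "icp_report.json")
  jsonlite::write_json(list(rms_residual_mm = icp$rms_residual,
                            iterations = icp$iterations_used,
                            converged = icp$converged),
                       paths$icp_report, digits = NA, auto_unbox = TRUE)

  say("[calibrate] stylus digitization and splint calibration")
  noise <- noise_from_name(cfg$session$noise)
  v_gt <- rigid_transform(euler_to_rotation(c(25, -10, 15)), c(180, -40, 60))
  tracker_centers <- apply_transform(invert_transform(v_gt),
                                     skull$ground_truth$sphere_centers)
  digitized <- digitize_spheres(tracker_centers, pc$sphere_diameter_mm,
                                noise_spec = noise, seed = cfg$seed)
  calib <- calibrate_splint(digitized, spheres$centers)
  paths$calibration <- file.path(out_dir, "calibration.json")
  jsonlite::write_json(
    list(fit_residual_mm = calib$fit_residual, accepted = calib$accepted,
         rotation = as.numeric(t(calib$tracker_to_virtual$rotation)),
         translation_mm = calib$tracker_to_virtual$translation),
    paths$calibration, digits = NA, auto_unbox = TRUE)

  say("[simulate] %s session, %.0f s at %.0f Hz", cfg$session$scheme,
      cfg$session$duration_s, cfg$session$rate_hz)
  p_ref <- rigid_transform(euler_to_rotation(c(5, 3, -8)), c(20, 15, -10))
  target_m <- rigid_transform(euler_to_rotation(c(4, 0, 2)), c(-3, 5, -2))
  motion <- function(t) {
    s <- min(1, t / max(cfg$session$duration_s, 1e-9))
    m <- rigid_transform(
      euler_to_rotation(s * rotation_to_euler(target_m$rotation)),
      s * target_m$translation)
    compose_transforms(compose_transforms(invert_transform(v_gt), m),
                       compose_transforms(v_gt, p_ref))
  }
  stream <- simulate_tracker_stream(motion, cfg$session$duration_s,
                                    cfg$session$rate_hz, noise_spec = noise,
                                    seed = cfg$seed + 1L)
  paths$stream <- file.path(out_dir, "poses.csv")
  write_pose_stream(stream, paths$stream)
  plan <- osteotomy_plan(cfg$session$scheme)
  session <- run_session(mand$mesh, plan, stream, calib)
  paths$transform_log <- file.path(out_dir, "session_transforms.jsonl")
  con <- file(paths$transform_log, "w")
  for (entry in session$trajectory) {
    writeLines(jsonlite::toJSON(
      list(t_s = entry$t_s,
           rotation = as.numeric(t(entry$transform$rotation)),
           translation_mm = entry$transform$translation),
      digits = NA, auto_unbox = TRUE), con)
  }
  close(con)
  for (seg in names(session$final$segments)) {
    paths[[paste0("segment_", seg)]] <-
      file.path(out_dir, paste0("segment_", seg, ".stl"))
    write_mesh(session$final$segments[[seg]], paths[[paste0("segment_", seg)]])
  }
  cmp <- superimpose_compare(session$initial, session$final)
  paths$displacement <- file.path(out_dir, "displacement.csv")
  write.csv(cmp$regions, paths$displacement, row.names = FALSE)

  say("[frames] mid-sagittal plane, MLB frame, asymmetry report")
  orb <- generate_orbita_points(pc, seed = cfg$seed)
  plane <- fit_midsagittal_plane(orb$left, orb$right)
  cran <- build_cranial_frame(plane, list(
    orbita_left_centroid = colMeans(orb$left),
    orbita_right_centroid = colMeans(orb$right)))
  lb <- mand$mesh$vertices[mand$mesh$region_labels == "lower_border", , drop = FALSE]
  mlb <- fit_mlb_frame(lb)
  asym <- asymmetry_report(mand$mesh, cran)
  paths$frames <- file.path(out_dir, "frames.json")
  jsonlite::write_json(
    list(midsagittal = list(point = plane$point, normal = plane$normal,
                            asymmetry_cost_mm = plane$asymmetry_cost),
         cranial = list(origin = cran$origin, axes = as.numeric(t(cran$axes))),
         mlb = list(origin = mlb$frame$origin,
                    axes = as.numeric(t(mlb$frame$axes)),
                    quartic = mlb$curve$coefficients,
                    rms_fit_error_mm = mlb$curve$rms_fit_error)),
    paths$frames, digits = NA, auto_unbox = TRUE)
  paths$asymmetry <- file.path(out_dir, "asymmetry.csv")
  asym_df <- rbind(
    data.frame(item = names(asym$landmark_deviation_mm), kind = "landmark",
               value_mm = as.numeric(asym$landmark_deviation_mm)),
    data.frame(item = names(asym$region_mirror_distance_mm), kind = "region",
               value_mm = as.numeric(asym$region_mirror_distance_mm)))
  write.csv(asym_df, paths$asymmetry, row.names = FALSE)

  say("[vci] rendering virtual cephalograms")
  geom <- projection_geometry()
  vci_orig <- render_vci(geom, skull$volume, mm_per_px = cfg$vci$mm_per_px,
                         film_size_mm = cfg$vci$film_size_mm)
  paths$vci <- file.path(out_dir, "vci_original.pgm")
  write_vci_pgm(vci_orig, paths$vci)

  say("[evaluate] accuracy protocol, n = %d", cfg$evaluate$n_repetitions)
  report <- run_accuracy_protocol(
    n_repetitions = cfg$evaluate$n_repetitions,
    noise_spec = noise_from_name(cfg$evaluate$noise),
    seed = cfg$seed, config = pc,
    translation_range_mm = cfg$evaluate$translation_range_mm,
    rotation_range_deg = cfg$evaluate$rotation_range_deg)
  paths$accuracy <- file.path(out_dir, "accuracy_report.csv")
  write_accuracy_csv(report, paths$accuracy)

  say("demo complete: %d artifacts in %s", length(paths), out_dir)
  invisible(paths)
}
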