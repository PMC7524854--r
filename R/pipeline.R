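#' Pipeline configuration
#'
#' A fully serialisable description of a simulated cohort run. Every field
#' has a default; unknown fields are rejected. A run is reproducible
#' bit-identically from `config + seed`: all stochastic steps derive their
#' seeds from `seed` and the patient index.
#'
#' @param seed master seed (integer).
#' @param n_patients number of simulated patients.
#' @param n_phase1 how many of them are "phase 1" (manual-only) patients.
#' @param n_patches stereo patches (viewpoints) recorded per patient.
#' @param points_per_patch correspondences per patch.
#' @param noise_sd_px stereo pixel noise sigma.
#' @param gate_error_rate segmentation gate symmetric error rate.
#' @param distractor `TRUE` to add the diaphragm-like sheet distractor.
#' @param distractor_clearance_mm sheet-to-liver gap (mm).
#' @param manual_trans_sd_mm,manual_rot_sd_deg spread of the simulated
#'   manual placement error (the coarse pose a human would supply).
#' @param landmark_noise_sd_mm per-frame landmark identification noise.
#' @param n_frames video frames per patient used for TRE.
#' @param icp list of overrides for [icp_params()]. The pipeline replays
#'   registrations offline, so it defaults to a larger iteration budget
#'   than the intraoperative [icp_params()] default.
#' @param camera_distance_mm laparoscope stand-off from the liver centroid.
#' @param force_failure_patients integer vector of patient indices whose
#'   initial pose is displaced by 200 mm, far outside the ICP capture
#'   range, to exercise the registration-failure path.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_patients = 2L, n_phase1 = 0L,
                            n_patches = 5L, points_per_patch = 2000L,
                            noise_sd_px = 0.5, gate_error_rate = 0,
                            distractor = TRUE, distractor_clearance_mm = 5,
                            manual_trans_sd_mm = 5, manual_rot_sd_deg = 3,
                            landmark_noise_sd_mm = 1, n_frames = 3L,
                            icp = list(max_iterations = 500L),
                            camera_distance_mm = 300,
                            force_failure_patients = integer(0)) {
  cfg <- list(seed = as.integer(seed), n_patients = as.integer(n_patients),
              n_phase1 = as.integer(n_phase1),
              n_patches = as.integer(n_patches),
              points_per_patch = as.integer(points_per_patch),
              noise_sd_px = noise_sd_px, gate_error_rate = gate_error_rate,
              distractor = isTRUE(distractor),
              distractor_clearance_mm = distractor_clearance_mm,
              manual_trans_sd_mm = manual_trans_sd_mm,
              manual_rot_sd_deg = manual_rot_sd_deg,
              landmark_noise_sd_mm = landmark_noise_sd_mm,
              n_frames = as.integer(n_frames), icp = icp,
              camera_distance_mm = camera_distance_mm,
              force_failure_patients = as.integer(force_failure_patients))
  if (cfg$n_phase1 > cfg$n_patients) {
    stop_liverreg("schema", "n_phase1 cannot exceed n_patients")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write pipeline configs as JSON
#' @param path JSON path.
#' @param config a `pipeline_config`.
#' @export
config_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(x), known)
  if (length(bad)) {
    stop_liverreg("schema", paste("unknown config field(s):",
                                  paste(bad, collapse = ", ")))
  }
  do.call(pipeline_config, x)
}

#' @rdname config_from_json
#' @export
config_to_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# deterministic sub-seed, kept below 2^31 (numeric arithmetic avoids
# integer overflow for large master seeds)
sub_seed <- function(seed, patient, salt = 0L) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(patient) * 101 +
                as.numeric(salt)) %% 2147483629)
}

#' Simulate, observe and register one patient
#'
#' One pass of the study workflow for a single simulated patient: scene
#' generation, multi-angle stereo observation, reconstruction, gating,
#' manual-mode registration (the perturbed pose IS the result) and
#' semi-automatic ICP refinement from the same initialisation, then TRE
#' evaluation of both against noisy per-frame landmark observations.
#'
#' @param config a `pipeline_config`.
#' @param patient patient index (1-based).
#' @return list with `scene`, `cloud` (gated), `manual` and `semiauto`
#'   registration entries (each `result` or `error`), `tre_manual`,
#'   `tre_semiauto` (mm or NA), `patient_id`, `phase`.
#' @export
simulate_patient <- function(config, patient) {
  sseed <- sub_seed(config$seed, patient, 1L)
  true_pose <- with_seed(sub_seed(config$seed, patient, 2L), {
    axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
    ang <- stats::runif(1, 0, 10) * pi / 180
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    rigid_transform(nearest_rotation(R), stats::runif(3, -30, 30))
  })
  spec <- if (config$distractor) {
    list(clearance_mm = config$distractor_clearance_mm)
  } else NULL
  scene <- make_scene(seed = sseed, distractor_spec = spec,
                      n_landmarks = 4L, true_pose = true_pose)
  rig <- default_rig()
  center <- apply_transform(scene$true_pose, colMeans(scene$liver_mesh$vertices))
  # laparoscope viewpoints: below/front of the liver, fanned in azimuth so
  # patches cover different parts of the surface
  clouds <- vector("list", config$n_patches)
  for (k in seq_len(config$n_patches)) {
    az <- (k - (config$n_patches + 1) / 2) * 0.35
    eye <- center + config$camera_distance_mm *
      c(sin(az) * 0.8, -0.55, -0.8 * cos(az))
    obs <- observe(scene, rig, look_at(eye, center),
                   n_points = config$points_per_patch,
                   noise_sd_px = config$noise_sd_px,
                   seed = sub_seed(config$seed, patient, 10L + k))
    obs$correspondences$patch_id <- k
    clouds[[k]] <- reconstruct_patch(obs$rig, obs$correspondences)
  }
  cloud_full <- bind_clouds(clouds)
  cloud <- gate_points(cloud_full, config$gate_error_rate,
                       seed = sub_seed(config$seed, patient, 3L))
  # coarse manual placement: truth perturbed by the configured human error
  init <- with_seed(sub_seed(config$seed, patient, 4L), {
    dt <- stats::rnorm(3, 0, config$manual_trans_sd_mm)
    da <- stats::rnorm(3, 0, config$manual_rot_sd_deg)
    compose(rigid_transform(
      rot_z(da[3] * pi / 180) %*% rot_y(da[2] * pi / 180) %*%
        rot_x(da[1] * pi / 180), dt), true_pose)
  })
  if (patient %in% config$force_failure_patients) {
    # displace well beyond the correspondence distance along the liver's
    # short axis, so no overlap remains for ICP to grab
    init <- compose(rigid_transform(diag(3), c(0, 0, 200)), init)
  }
  params <- do.call(icp_params, config$icp)
  manual <- list(result = registration_result(
    init, NA_real_, 0L, 0L, TRUE, numeric(0)), error = NULL)
  semiauto <- tryCatch(
    list(result = icp_register(cloud, scene$liver_mesh, init, params,
                               sample_seed = sub_seed(config$seed, patient, 5L)),
         error = NULL),
    liverreg_registration_failure = function(e) {
      list(result = e$result, error = conditionMessage(e))
    })
  # per-frame landmark observations in patient space
  frames <- with_seed(sub_seed(config$seed, patient, 6L), {
    do.call(rbind, lapply(seq_len(config$n_frames), function(fr) {
      lm <- do.call(rbind, scene$landmarks)
      obs_lm <- apply_transform(true_pose, lm) +
        matrix(stats::rnorm(length(lm), 0, config$landmark_noise_sd_mm),
               ncol = 3)
      data.frame(frame_id = fr, name = names(scene$landmarks),
                 px = obs_lm[, 1], py = obs_lm[, 2], pz = obs_lm[, 3])
    }))
  })
  phase <- if (patient <= config$n_phase1) 1L else 2L
  tre_of <- function(reg_entry) {
    if (is.null(reg_entry$result) || !is.null(reg_entry$error)) return(NA_real_)
    tre_report(reg_entry$result$transform, scene$landmarks, frames)$tre_mm
  }
  list(patient_id = sprintf("SIM%02d", patient), phase = phase,
       scene = scene, cloud = cloud, frames = frames,
       manual = manual, semiauto = semiauto,
       tre_manual = tre_of(manual),
       tre_semiauto = if (phase == 1L) NA_real_ else tre_of(semiauto))
}

#' Run the full simulated study pipeline
#'
#' For each simulated patient: scene generation, stereo observation,
#' reconstruction, segmentation gating, manual and semi-automatic
#' registration, TRE evaluation; then cohort statistics over the
#' survivors. Per-patient registration failures are recorded in the
#' manifest and the pipeline continues (mirroring an intraoperative series
#' where some registrations fail). All outputs land in `out_dir`:
#' scene files, registration JSONs, `tre.csv` (cohort schema), the
#' cohort-analysis JSON and a manifest with seeds and file hashes.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created).
#' @return list of class `pipeline_run`: `cohort` (the survivors, as a
#'   `cohort_table` when the schema permits), `cohort_all` (every patient,
#'   failed registrations carrying `NA`), `report` (or NULL when too few
#'   survivors), `failures`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  failures <- list()
  for (p in seq_len(config$n_patients)) {
    pat <- simulate_patient(config, p)
    pdir <- file.path(out_dir, pat$patient_id)
    dir.create(pdir, showWarnings = FALSE)
    export_scene(pat$scene, file.path(pdir, "scene"))
    write_cloud(pat$cloud, file.path(pdir, "cloud_gated.ply"))
    registration_to_json(pat$manual$result,
                         file.path(pdir, "registration_manual.json"))
    if (!is.null(pat$semiauto$result)) {
      registration_to_json(pat$semiauto$result,
                           file.path(pdir, "registration_semiauto.json"))
    }
    if (!is.null(pat$semiauto$error)) {
      failures[[pat$patient_id]] <- pat$semiauto$error
    }
    rows[[p]] <- data.frame(patient_id = pat$patient_id, phase = pat$phase,
                            tre_manual = pat$tre_manual,
                            tre_semiauto = pat$tre_semiauto)
  }
  cohort <- do.call(rbind, rows)
  # drop patients whose semi-automatic registration failed from the paired
  # analysis, the way failed registrations leave a clinical series
  keep <- cohort$phase == 1L | !is.na(cohort$tre_semiauto)
  cohort_csv <- file.path(out_dir, "tre.csv")
  utils::write.csv(cohort, cohort_csv, row.names = FALSE, quote = FALSE)
  survivors <- cohort[keep, , drop = FALSE]
  report <- tryCatch(analyze_cohort(survivors),
                     liverreg_error = function(e) NULL)
  survivors <- tryCatch(cohort_table(survivors),
                        liverreg_error = function(e) survivors)
  if (!is.null(report)) {
    cohort_report_to_json(report, file.path(out_dir, "cohort_report.json"))
  }
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("liverreg")),
    config = unclass(config),
    failures = failures,
    hashes = as.list(tools::md5sum(sort(files))))
  names(manifest$hashes) <- substring(names(manifest$hashes),
                                      nchar(out_dir) + 2L)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(cohort = survivors, cohort_all = cohort, report = report,
                 failures = failures, manifest = manifest,
                 out_dir = out_dir),
            class = "pipeline_run")
}

#' Cohort statistics command
#'
#' Runs [analyze_cohort()] on a cohort CSV, or on the packaged reference
#' fixture when `fixture = "table3"`.
#'
#' @param cohort_csv_path CSV path in the cohort schema (ignored when a
#'   fixture is requested).
#' @param fixture `NULL` or `"table3"`.
#' @return A `cohort_report`.
#' @export
stats_command <- function(cohort_csv_path = NULL, fixture = NULL) {
  tab <- if (!is.null(fixture)) {
    if (!identical(fixture, "table3")) {
      stop_liverreg("schema", "unknown fixture (only 'table3' is packaged)")
    }
    reference_cohort()
  } else {
    read_cohort(cohort_csv_path)
  }
  analyze_cohort(tab)
}
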