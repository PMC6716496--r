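#' End-to-end simulated comparison pipeline
#'
#' Orchestrates the whole study for seeded synthetic trials: phantom
#' generation, radiograph rendering, calibration from the bead cube,
#' markerless tracking (or exact truth-pose replay), drop-trial
#' synchronization, co-registration, virtual-marker synthesis, kinematics
#' and agreement statistics. One global seed fans out to per-stage
#' sub-streams (stage label + seed), so identical configurations give
#' byte-identical reports.
#'
#' @name pipeline
NULL

# fixed rigid offset between the x-ray (radiographic) global frame and the
# optical global frame; the co-registration stage must recover its inverse
xray_frame_transform <- function() {
  R <- rot_z(20 * pi / 180) %*% rot_x(5 * pi / 180)
  rigid_transform(R, c(250, -120, 30))
}

#' Pipeline configuration
#'
#' @param activities conditions to simulate ("walking", "running" or both).
#' @param n_trials trials per condition.
#' @param stance_frames frames per trial.
#' @param frame_rate Hz.
#' @param sta_amplitude STA 3D RMS amplitude: NULL = per-segment defaults,
#'   0 = rigid (identity test), or a scalar/named vector in mm.
#' @param rate_mismatch OMC-to-BVR sample-rate ratio.
#' @param heel_pad_mm optional heel-pad compression, mm.
#' @param tracking_mode "truth" replays exact ground-truth poses through the
#'   BVR chain (isolating STA and processing effects); "drr" runs full
#'   NCC/simplex tracking on rendered radiographs.
#' @param bones_to_track bones passed through the BVR chain.
#' @param tracking a \code{tracking_config} (used in "drr" mode).
#' @param init_perturb_mm,init_perturb_deg seeded perturbation of the
#'   tracker's initial guess (emulates the manual first alignment).
#' @param image_noise_sd additive pixel noise SD for rendered radiographs.
#' @param filter_cutoff_hz marker/pose filter cutoff.
#' @param window percent-of-stance analysis window, c(lo, hi).
#' @param out_dir optional artifact directory.
#' @param seed global seed.
#' @export
pipeline_config <- function(activities = "walking", n_trials = 1,
                            stance_frames = NULL, frame_rate = 250,
                            sta_amplitude = NULL, rate_mismatch = 1.0,
                            heel_pad_mm = NULL,
                            tracking_mode = c("truth", "drr"),
                            bones_to_track = c("shank", "calcaneus",
                                               "navicular", "metatarsal"),
                            tracking = tracking_config(),
                            init_perturb_mm = 2, init_perturb_deg = 2,
                            image_noise_sd = 0, filter_cutoff_hz = 10,
                            window = c(11, 75), out_dir = NULL, seed = 1L) {
  tracking_mode <- match.arg(tracking_mode)
  stopifnot(all(activities %in% c("walking", "running")), n_trials >= 1)
  structure(list(activities = activities, n_trials = n_trials,
                 stance_frames = stance_frames, frame_rate = frame_rate,
                 sta_amplitude = sta_amplitude,
                 rate_mismatch = rate_mismatch, heel_pad_mm = heel_pad_mm,
                 tracking_mode = tracking_mode,
                 bones_to_track = bones_to_track, tracking = tracking,
                 init_perturb_mm = init_perturb_mm,
                 init_perturb_deg = init_perturb_deg,
                 image_noise_sd = image_noise_sd,
                 filter_cutoff_hz = filter_cutoff_hz, window = window,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

# seeded rigid perturbation of a pose (emulates the manual initial guess)
perturb_pose <- function(pose, mm, deg, seed, label) {
  if (mm == 0 && deg == 0) return(pose)
  u <- make_rng(seed, label)(6) * 2 - 1
  dv <- u[1:3] / sqrt(sum(u[1:3]^2)) * mm
  ax <- u[4:6] / sqrt(sum(u[4:6]^2)) * deg * pi / 180
  rigid_pose(quat_multiply(rotvec_to_quat(ax), pose$q), pose$t + dv,
             pose$frame, pose$tracked)
}

# one simulated trial through the full chain; returns per-trial statistics
run_trial <- function(cfg, bones, cameras_omc, cameras_xray, Txray,
                      activity, trial, static_ms, mla_static) {
  trial_seed <- (cfg$seed * 1009L + trial * 97L +
                   sum(utf8ToInt(activity))) %% .Machine$integer.max
  scenario <- gait_scenario(
    activity = activity, frame_rate = cfg$frame_rate,
    stance_frames = cfg$stance_frames,
    sta = sta_model(amplitude = cfg$sta_amplitude, seed = trial_seed),
    heel_pad_compression_mm = cfg$heel_pad_mm,
    rate_mismatch = cfg$rate_mismatch, seed = trial_seed)
  truth <- make_gait_trajectory(scenario)
  nf <- scenario$stance_frames
  # --- optical side: markers on the (possibly mismatched) optical grid ----
  r <- scenario$rate_mismatch
  if (r == 1) {
    omc_poses <- truth$poses
  } else {
    Tdur <- (nf - 1) / cfg$frame_rate
    n_omc <- floor(Tdur * cfg$frame_rate * r) + 1
    tt <- (seq_len(n_omc) - 1) / (cfg$frame_rate * r)
    plist <- truth$program(tt)
    omc_poses <- lapply(names(plist[[1]]), function(b) {
      pose_trajectory(b,
                      t(vapply(plist, function(p) p[[b]]$q, numeric(4))),
                      t(vapply(plist, function(p) p[[b]]$t, numeric(3))),
                      cfg$frame_rate * r)
    })
    names(omc_poses) <- names(plist[[1]])
  }
  omc_markers <- synthesize_markers(
    bones, omc_poses, scenario$sta, activity = activity,
    heel_pad_mm = cfg$heel_pad_mm,
    heel_strike_frame = truth$events$heel_strike * r)
  # --- radiographic side ------------------------------------------------
  track_bones <- bones[cfg$bones_to_track]
  if (cfg$tracking_mode == "truth") {
    bvr_traj_xray <- lapply(track_bones, function(b) {
      coregister(truth$poses[[b$name]], Txray)
    })
  } else {
    bvr_traj_xray <- list()
    for (b in track_bones) {
      imgs <- render_trial_images(list(b), truth$poses[b$name],
                                  cameras_omc, step = cfg$tracking$step_mm,
                                  noise_sd = cfg$image_noise_sd,
                                  seed = trial_seed)
      init <- coregister(traj_pose(truth$poses[[b$name]], 1), Txray)
      init <- perturb_pose(init, cfg$init_perturb_mm, cfg$init_perturb_deg,
                           trial_seed, paste0("init_", b$name))
      bvr_traj_xray[[b$name]] <-
        track_sequence(b, imgs$stacks, cameras_xray, init,
                       cfg$tracking, frame_rate = cfg$frame_rate)
    }
  }
  names(bvr_traj_xray) <- vapply(track_bones, `[[`, "", "name")
  # --- synchronization --------------------------------------------------
  if (r != 1) {
    drops <- make_drop_trials(rate_mismatch = r, frame_rate = cfg$frame_rate,
                              seed = trial_seed)
    sync <- estimate_sync(drops)
    omc_markers <- resample_to_bvr(omc_markers, sync, n_frames = nf)
  }
  # --- co-registration and virtual markers ------------------------------
  coreg_pts <- make_coreg_object(seed = cfg$seed)
  tf <- rigid_fit(transform_points(Txray, coreg_pts), coreg_pts)
  # tracked trajectories are pose-filtered (quaternion-component dual
  # Butterworth) to suppress tracking jitter; exact truth replays have
  # nothing to smooth and skipping the step keeps the zero-STA comparison
  # an exact identity
  bvr_traj <- lapply(bvr_traj_xray, function(tr) {
    tr <- coregister(tr, tf)
    if (cfg$tracking_mode == "drr") tr <- filter_poses(tr, cfg$filter_cutoff_hz)
    tr
  })
  static_poses <- lapply(stats::setNames(names(bvr_traj), names(bvr_traj)),
                         function(b) rigid_pose())
  defs <- seed_virtual_markers(static_ms, static_poses)
  bvr_markers <- replay_virtual_markers(defs, bvr_traj)
  # --- kinematics -------------------------------------------------------
  omc_f <- filter_markers(omc_markers, cfg$filter_cutoff_hz)
  bvr_f <- filter_markers(bvr_markers, cfg$filter_cutoff_hz)
  events <- detect_gait_events(omc_f)
  omc_w <- angle_waveforms(omc_f, events, mla_static = mla_static)
  bvr_w <- angle_waveforms(bvr_f, events, mla_static = mla_static)
  angle_stats <- do.call(rbind, lapply(colnames(omc_w), function(a) {
    wo <- crop_to_window(omc_w[, a], cfg$window[1], cfg$window[2])
    wb <- crop_to_window(bvr_w[, a], cfg$window[1], cfg$window[2])
    fit <- lfm(wo, wb)
    data.frame(angle = a, r2 = fit$r2, a0 = fit$a0, a1 = fit$a1,
               rmse = rmse(wo, wb))
  }))
  stance <- events$heel_strike:events$toe_off
  marker_stats <- rms_marker_difference(omc_f, bvr_f, window = stance)
  list(activity = activity, trial = trial, events = events,
       angle_stats = angle_stats, marker_stats = marker_stats,
       omc_waveforms = omc_w, bvr_waveforms = bvr_w,
       omc_markers = omc_f, bvr_markers = bvr_f, truth = truth,
       bvr_trajectories = bvr_traj, coregistration = tf)
}

#' Run the full simulated comparison
#'
#' @param cfg a \code{pipeline_config}.
#' @return an \code{agreement_report} (see \code{aggregate_and_test}) with
#'   an additional \code{trials} element holding every per-trial result.
#'   With \code{cfg$out_dir} set, writes markers (CSV), bone poses (CSV),
#'   angle waveforms (CSV), cameras and co-registration (JSON), the report
#'   (JSON) and a manifest.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  bones <- make_phantom_foot(seed = cfg$seed)
  Txray <- xray_frame_transform()
  cameras_omc <- make_bvr_cameras()
  # calibrate the x-ray cameras from the bead cube, in the x-ray frame
  cube_omc <- make_calibration_cube()
  cube_xray <- transform_points(Txray, cube_omc)
  Tinv <- transform_inverse(Txray)
  M4 <- rbind(cbind(Tinv$R, Tinv$t), c(0, 0, 0, 1))
  cameras_xray <- lapply(cameras_omc, function(cam) {
    truth_cam <- camera_model(cam$projection %*% M4, cam$image_size, cam$id)
    calibrate_camera(cube_xray, project_points(truth_cam, cube_xray),
                     image_size = cam$image_size, id = cam$id)
  })
  static_ms <- make_static_markers(bones, cfg$frame_rate)
  mla_static <- mla_angle(static_ms, 1)
  trials <- list()
  marker_reports <- list()
  angle_reports <- list()
  for (act in cfg$activities) {
    mr <- list(); ar <- list()
    for (k in seq_len(cfg$n_trials)) {
      tr <- run_trial(cfg, bones, cameras_omc, cameras_xray, Txray,
                      act, k, static_ms, mla_static)
      trials[[paste(act, k, sep = "_")]] <- tr
      mr[[k]] <- tr$marker_stats
      ar[[k]] <- tr$angle_stats
    }
    marker_reports[[act]] <- mr
    angle_reports[[act]] <- ar
  }
  report <- aggregate_and_test(marker_reports, angle_reports)
  report$trials <- trials
  report$config <- cfg
  if (!is.null(cfg$out_dir)) write_pipeline_artifacts(report, cfg)
  report
}

# write every intermediate with a manifest
write_pipeline_artifacts <- function(report, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(p) { paths[length(paths) + 1] <<- p; p }
  write_transform_json(report$trials[[1]]$coregistration,
                       put(file.path(cfg$out_dir, "coregistration.json")))
  for (nm in names(report$trials)) {
    tr <- report$trials[[nm]]
    write_marker_csv(tr$omc_markers,
                     put(file.path(cfg$out_dir, paste0(nm, "_omc.csv"))))
    write_marker_csv(tr$bvr_markers,
                     put(file.path(cfg$out_dir, paste0(nm, "_bvr.csv"))))
    for (b in names(tr$bvr_trajectories)) {
      write_pose_csv(tr$bvr_trajectories[[b]],
                     put(file.path(cfg$out_dir,
                                   paste0(nm, "_pose_", b, ".csv"))))
    }
    utils::write.csv(
      data.frame(percent = 0:100, tr$omc_waveforms, tr$bvr_waveforms),
      put(file.path(cfg$out_dir, paste0(nm, "_angles.csv"))),
      row.names = FALSE)
  }
  summary_json <- list(
    marker_summary = report$marker_summary,
    angle_summary = report$angle_summary,
    tests = report$tests, seed = cfg$seed)
  jsonlite::write_json(summary_json,
                       put(file.path(cfg$out_dir, "report.json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(list(files = sort(basename(paths)),
                            seed = cfg$seed,
                            activities = cfg$activities,
                            n_trials = cfg$n_trials),
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(paths)
}
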