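#!/usr/bin/env Rscript
# Generate the synthetic study material: a four-bone phantom foot carrying
# the 14 Rizzoli markers, ground-truth walking and running stance trials,
# soft-tissue-artifact-corrupted optical markers, two-view radiograph
# stacks, and all calibration fixtures.

suppressPackageStartupMessages(library(footbvr))
dir.create("results/simulated", recursive = TRUE, showWarnings = FALSE)
seed <- 1L

bones <- make_phantom_foot(seed = seed)
cat("Phantom foot:", paste(names(bones), collapse = ", "), "-",
    sum(vapply(bones, function(b) nrow(b$landmarks), integer(1))),
    "landmarks total\n")

cams <- make_bvr_cameras()
write_cameras_json(cams, "results/simulated/cameras_truth.json")

for (act in c("walking", "running")) {
  sc <- gait_scenario(act, seed = seed)
  truth <- make_gait_trajectory(sc)
  omc <- synthesize_markers(bones, truth$poses, sc$sta, activity = act)
  write_marker_csv(omc, sprintf("results/simulated/%s_omc_markers.csv", act))
  for (b in names(truth$poses)) {
    write_pose_csv(truth$poses[[b]],
                   sprintf("results/simulated/%s_truth_%s.csv", act, b))
  }
  cat(sprintf(
    "%s: %d frames at %g Hz, true heel strike frame %d, toe off %d\n",
    act, n_frames(truth$poses[[1]]), sc$frame_rate,
    truth$events$heel_strike, truth$events$toe_off))
}

# a short two-view radiograph excerpt (kept small on disk)
truth <- make_gait_trajectory(gait_scenario(stance_frames = 20, seed = seed))
imgs <- render_trial_images(bones["calcaneus"], truth$poses["calcaneus"],
                            cams)
write_image_stack(imgs$stacks[[1]], "results/simulated/cam1_excerpt.tif")
write_image_stack(imgs$stacks[[2]], "results/simulated/cam2_excerpt.tif")
cat("Wrote a 20-frame calcaneus radiograph excerpt for both views\n")

fx <- make_fixtures(seed = seed, rate_mismatch = 0.99)
utils::write.csv(data.frame(fx$cube_beads),
                 "results/simulated/cube_beads.csv", row.names = FALSE)
utils::write.csv(data.frame(fx$coreg_points),
                 "results/simulated/coreg_beads.csv", row.names = FALSE)
cat("Fixtures: 64 cube beads, 11 co-registration beads, 5 drop trials,",
    "one undistortion grid\n")
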