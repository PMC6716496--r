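# Shared fixtures, built once per test run. Everything is generated in code;
# small sizes keep the default suite fast.
fx <- new.env()

fx_bones <- function() {
  if (is.null(fx$bones)) fx$bones <- make_phantom_foot(seed = 1)
  fx$bones
}

fx_cameras <- function() {
  if (is.null(fx$cams)) fx$cams <- make_bvr_cameras()
  fx$cams
}

fx_truth <- function() {
  if (is.null(fx$truth)) {
    fx$truth <- make_gait_trajectory(gait_scenario(seed = 1))
  }
  fx$truth
}

fx_rigid_markers <- function() {
  if (is.null(fx$rigid_markers)) {
    fx$rigid_markers <- synthesize_markers(fx_bones(), fx_truth()$poses,
                                           sta_model(amplitude = 0))
  }
  fx$rigid_markers
}

# a small single-bone tracking scene: calcaneus only, short excerpt
fx_track_scene <- function() {
  if (is.null(fx$scene)) {
    bones <- fx_bones()["calcaneus"]
    truth <- make_gait_trajectory(gait_scenario(stance_frames = 25, seed = 2))
    poses <- truth$poses["calcaneus"]
    imgs <- render_trial_images(bones, poses, fx_cameras())
    fx$scene <- list(bone = bones$calcaneus, truth = poses$calcaneus,
                     stacks = imgs$stacks)
  }
  fx$scene
}

# random unit quaternion from a given RNG stream
rand_quat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}
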