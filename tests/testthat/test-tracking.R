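test_that("NCC hits its analytic identities and noise bound", {
  scene <- fx_track_scene()
  img <- scene$stacks[[1]][[1]]
  expect_equal(ncc(img, img), 1, tolerance = 1e-12)
  expect_equal(ncc(-img, img), -1, tolerance = 1e-12)
  set.seed(31)
  a <- matrix(rnorm(128^2), 128)
  b <- matrix(rnorm(128^2), 128)
  expect_lt(abs(ncc(a, b, mask = matrix(TRUE, 128, 128))), 0.05)
  expect_error(ncc(matrix(1, 8, 8), matrix(1, 8, 8),
                   mask = matrix(TRUE, 8, 8)), "constant")
  expect_error(ncc(matrix(1, 8, 8), matrix(1, 4, 4)), "shape")
})

test_that("cost is globally optimal at ground truth on noiseless images", {
  scene <- fx_track_scene()
  cams <- fx_cameras()
  cfg <- tracking_config()
  p0 <- traj_pose(scene$truth, 1)
  imgs <- list(scene$stacks[[1]][[1]], scene$stacks[[2]][[1]])
  c0 <- footbvr:::two_view_cost(scene$bone, p0, imgs, cams, cfg)
  expect_lt(c0, 1e-10)
  set.seed(32)
  for (i in 1:6) {
    dp <- rigid_pose(quat_multiply(rotvec_to_quat(rnorm(3, sd = 0.02)),
                                   p0$q), p0$t + rnorm(3, sd = 1))
    expect_gt(footbvr:::two_view_cost(scene$bone, dp, imgs, cams, cfg), c0)
  }
})

test_that("optimization recovers a perturbed pose on a noiseless frame", {
  scene <- fx_track_scene()
  cams <- fx_cameras()
  p0 <- traj_pose(scene$truth, 1)
  imgs <- list(scene$stacks[[1]][[1]], scene$stacks[[2]][[1]])
  init <- footbvr:::perturb_pose(p0, 2, 3, 7, "test")
  res <- optimize_pose(scene$bone, imgs, cams, init)
  expect_lt(sqrt(sum((res$pose$t - p0$t)^2)), 0.3)
  expect_lt(quat_angle(res$pose$q, p0$q) * 180 / pi, 0.5)
  # starting at the truth stays at the truth
  res0 <- optimize_pose(scene$bone, imgs, cams, p0)
  expect_lt(res0$cost, 1e-8)
  expect_lt(sqrt(sum((res0$pose$t - p0$t)^2)), 0.05)
})

test_that("an initial pose far outside both views is rejected", {
  scene <- fx_track_scene()
  cams <- fx_cameras()
  p0 <- traj_pose(scene$truth, 1)
  imgs <- list(scene$stacks[[1]][[1]], scene$stacks[[2]][[1]])
  bad <- rigid_pose(p0$q, p0$t + c(0, 0, 4000))
  expect_error(optimize_pose(scene$bone, imgs, cams, bad), "outside")
})

test_that("squad spline passes through keyframes and bisects two-key geodesics", {
  set.seed(33)
  kf <- lapply(c(1, 11, 21), function(f) {
    rigid_pose(rand_quat(), rnorm(3, sd = 10), frame = f)
  })
  out <- quaternion_spline(kf, c(1, 11, 21))
  for (i in 1:3) {
    expect_equal(abs(sum(out[[i]]$q * kf[[i]]$q)), 1, tolerance = 1e-9)
    expect_equal(out[[i]]$t, kf[[i]]$t, tolerance = 1e-9)
  }
  two <- quaternion_spline(kf[1:2], 6)
  d0 <- quat_angle(two[[1]]$q, kf[[1]]$q)
  d1 <- quat_angle(two[[1]]$q, kf[[2]]$q)
  expect_equal(d0, d1, tolerance = 1e-9)
  # constant keyframes give constant output; duplicates are rejected
  const <- lapply(c(1, 5, 9), function(f) rigid_pose(frame = f))
  for (p in quaternion_spline(const, 1:9)) {
    expect_equal(abs(p$q[1]), 1, tolerance = 1e-12)
  }
  dup <- list(rigid_pose(frame = 1), rigid_pose(frame = 1))
  expect_error(quaternion_spline(dup, 1), "duplicate")
})

test_that("sequence tracking follows a smooth trajectory within tolerance", {
  scene <- fx_track_scene()
  cams <- fx_cameras()
  init <- footbvr:::perturb_pose(traj_pose(scene$truth, 1), 1.5, 1.5, 3,
                                 "seq")
  cfg10 <- tracking_config(keyframe_stride = 10)
  tr <- track_sequence(scene$bone, scene$stacks, cams, init, cfg10,
                       frame_rate = 250)
  err <- trajectory_error(tr, scene$truth)
  expect_lt(err$rms_trans_mm, 0.5)
  expect_lt(err$rms_rot_deg, 0.7)
  expect_true(all(tr$tracked))
})

test_that("constant-pose sequences track as constant trajectories", {
  bones <- fx_bones()["calcaneus"]
  cams <- fx_cameras()
  p0 <- rigid_pose(rotvec_to_quat(c(0.02, 0, 0.03)), c(2, 1, -1))
  n <- 12
  Q <- matrix(rep(p0$q, n), ncol = 4, byrow = TRUE)
  Tr <- matrix(rep(p0$t, n), ncol = 3, byrow = TRUE)
  poses <- list(calcaneus = pose_trajectory("calcaneus", Q, Tr, 250))
  imgs <- render_trial_images(bones, poses, cams)
  tr <- track_sequence(bones$calcaneus, imgs$stacks, cams,
                       footbvr:::perturb_pose(p0, 1, 1, 9, "const"),
                       tracking_config(keyframe_stride = 5),
                       frame_rate = 250)
  err <- trajectory_error(tr, poses$calcaneus)
  expect_lt(max(err$trans_mm), 0.2)
  expect_lt(max(err$rot_deg), 0.3)
})

test_that("pose filtering preserves DC, attenuates above cutoff, keeps unit norm", {
  n <- 500; fs <- 250
  q0 <- c(1, 0, 0, 0)
  Q <- matrix(rep(q0, n), ncol = 4, byrow = TRUE)
  t_s <- (seq_len(n) - 1) / fs
  Tr <- cbind(10 + sin(2 * pi * 30 * t_s), rep(2, n), rep(-1, n))
  traj <- pose_trajectory("b", Q, Tr, fs)
  f <- filter_poses(traj, 10)
  mid <- 100:400
  # 30 Hz at a 10 Hz dual-pass 2nd-order Butterworth: amplitude < 10%
  expect_lt(stats::sd(f$Tr[mid, 1] - 10), 0.1 * stats::sd(Tr[mid, 1] - 10))
  expect_equal(f$Tr[mid, 2], rep(2, length(mid)), tolerance = 1e-9)
  expect_equal(rowSums(f$Q^2), rep(1, n), tolerance = 1e-9)
  # constant trajectories are unchanged
  const <- pose_trajectory("b", Q, matrix(5, n, 3), fs)
  fc <- filter_poses(const, 10)
  expect_equal(fc$Tr, const$Tr, tolerance = 1e-9)
  expect_error(filter_poses(traj, 125), "Nyquist")
  short <- pose_trajectory("b", Q[1:8, ], Tr[1:8, ], fs)
  expect_error(filter_poses(short, 10), "13")
})

test_that("tracking is equivariant under a common rigid motion of the rig", {
  scene <- fx_track_scene()
  cams <- fx_cameras()
  tf <- rigid_transform(cardan_zxy(15, 5, -10), c(40, -20, 10))
  M4i <- rbind(cbind(t(tf$R), -t(tf$R) %*% tf$t), c(0, 0, 0, 1))
  cams2 <- lapply(cams, function(cam) {
    camera_model(cam$projection %*% M4i, cam$image_size, cam$id)
  })
  p0 <- traj_pose(scene$truth, 1)
  p0m <- coregister(p0, tf)
  img_a <- render_drr(scene$bone, p0, cams[[1]])
  img_b <- render_drr(scene$bone, p0m, cams2[[1]])
  expect_equal(img_a, img_b, tolerance = 1e-9, ignore_attr = TRUE)
})
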