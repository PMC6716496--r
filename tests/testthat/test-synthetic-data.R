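test_that("phantom foot carries the 14 Rizzoli landmarks split 3/4/1/6", {
  bones <- fx_bones()
  expect_named(bones, c("shank", "calcaneus", "navicular", "metatarsal"))
  counts <- vapply(bones, function(b) nrow(b$landmarks), integer(1))
  expect_equal(unname(counts), c(3L, 4L, 1L, 6L))
  all_marks <- unlist(lapply(bones, function(b) rownames(b$landmarks)))
  expect_setequal(all_marks, names(rizzoli_marker_map()))
  mmap <- rizzoli_marker_map()
  for (b in bones) {
    expect_true(all(mmap[rownames(b$landmarks)] == b$name))
  }
})

test_that("phantom volumes are non-negative with landmarks inside bounds", {
  for (b in fx_bones()) {
    expect_true(all(b$volume >= 0))
    ext <- (dim(b$volume) - 1) * b$voxel_spacing
    lo <- b$origin; hi <- b$origin + ext
    expect_true(all(t(b$landmarks) >= lo - 1e-9))
    expect_true(all(t(b$landmarks) <= hi + 1e-9))
  }
})

test_that("phantom generation is seed-deterministic and rejects degenerate sizes", {
  a <- make_phantom_foot(seed = 7)
  b <- make_phantom_foot(seed = 7)
  expect_identical(a$calcaneus$volume, b$calcaneus$volume)
  c2 <- make_phantom_foot(seed = 8)
  expect_false(identical(a$calcaneus$volume, c2$calcaneus$volume))
  bad <- phantom_config()
  bad$shank$dim <- c(0, 10, 10)
  expect_error(make_phantom_foot(config = bad), "degenerate|zero")
})

test_that("zero-amplitude scenario gives constant identity poses", {
  tr <- make_gait_trajectory(gait_scenario(amp_scale = 0, seed = 1))
  for (p in tr$poses) {
    expect_equal(p$Q, matrix(rep(c(1, 0, 0, 0), n_frames(p)),
                             ncol = 4, byrow = TRUE), tolerance = 1e-12)
    expect_equal(max(abs(p$Tr)), 0, tolerance = 1e-12)
  }
})

test_that("gait trajectories are unit-norm, deterministic, sagittal-dominant", {
  truth <- fx_truth()
  for (p in truth$poses) {
    expect_equal(rowSums(p$Q^2), rep(1, n_frames(p)), tolerance = 1e-9)
  }
  again <- make_gait_trajectory(gait_scenario(seed = 1))
  expect_identical(truth$poses$calcaneus$Q, again$poses$calcaneus$Q)
  # ground-truth angle ranges from the rigid marker replay
  w <- vapply(seq_len(n_frames(truth$poses[[1]])), function(i) {
    fr <- segment_frames(fx_rigid_markers(), i)
    ankle_angles(fr$shank, fr$calcaneus)
  }, numeric(3))
  rng <- apply(w, 1, function(x) diff(range(x)))
  expect_gte(rng["sagittal"], 3 * rng["frontal"])
  expect_gte(rng["sagittal"], 3 * rng["transverse"])
})

test_that("calcaneus vertical velocity has exactly one interior min and max", {
  truth <- fx_truth()
  ctr <- footbvr:::segment_rest_centers()["calcaneus", ]
  traj <- truth$poses$calcaneus
  z <- vapply(seq_len(n_frames(traj)), function(i) {
    pose_apply(traj_pose(traj, i), ctr)[3]
  }, numeric(1))
  v <- diff(z)
  # slope sign of the velocity, carrying the previous sign across exact
  # ties (symmetric sampling) and the numerically flat mid-stance region
  s <- sign(diff(v))
  tol <- 1e-6 * max(abs(v))
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  turns <- which(diff(s) != 0) + 1
  prominent <- turns[abs(v[turns]) > tol]
  mins <- prominent[v[prominent] < 0]
  maxs <- prominent[v[prominent] > 0]
  expect_length(mins, 1)
  expect_length(maxs, 1)
  expect_lt(mins, maxs)
  expect_equal(which.min(v), mins, tolerance = 1)
  expect_equal(which.max(v), maxs, tolerance = 1)
})

test_that("stance_frames below 20 is rejected", {
  expect_error(gait_scenario(stance_frames = 10), "stance_frames")
})

test_that("zero-STA markers equal the rigid landmark replay exactly", {
  bones <- fx_bones()
  truth <- fx_truth()
  ms <- fx_rigid_markers()
  i <- 37
  for (b in bones) {
    p <- traj_pose(truth$poses[[b$name]], i)
    expect_equal(t(ms$pos[i, , rownames(b$landmarks)]),
                 pose_apply(p, b$landmarks), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("STA displacement magnitude and bias behave as specified", {
  bones <- fx_bones()
  truth <- fx_truth()
  rigid <- fx_rigid_markers()
  amps <- numeric(0)
  for (s in 1:5) {
    ms <- synthesize_markers(bones, truth$poses,
                             sta_model(amplitude = 3, smoothness = 2,
                                       seed = s))
    d <- ms$pos - rigid$pos
    amps <- c(amps, sqrt(colMeans(apply(d^2, c(1, 3), sum))))
  }
  expect_true(all(abs(amps - 3) <= 0.6))  # within 20% of the amplitude
  # constant systematic offset with zero noise displaces every frame exactly
  off <- synthesize_markers(bones, truth$poses,
                            sta_model(amplitude = 0, offset = c(1, 0, 0)))
  d <- off$pos - rigid$pos
  expect_equal(max(abs(d[, 1, ] - 1)), 0, tolerance = 1e-12)
  expect_equal(max(abs(d[, 2:3, ])), 0, tolerance = 1e-12)
})

test_that("marker synthesis needs a pose for every parent bone", {
  bones <- fx_bones()
  truth <- fx_truth()
  expect_error(
    synthesize_markers(bones, truth$poses[c("shank", "calcaneus")],
                       sta_model(amplitude = 0)),
    "no pose")
})

test_that("fixtures match the laboratory hardware counts", {
  f <- make_fixtures(seed = 1)
  expect_equal(nrow(f$cube_beads), 64)         # 4 layers x 16 beads
  expect_equal(nrow(f$coreg_points), 11)       # 11 steel beads
  expect_equal(length(f$drop_trials), 5)       # 5 drops
  sv <- svd(scale(f$cube_beads, scale = FALSE))$d
  expect_gt(sv[3], 1)                          # beads not coplanar as a set
  g <- f$undistortion_grid
  expect_true(all(dim(g$image) == c(160, 160)))
  expect_equal(nrow(g$ideal), nrow(g$observed))
})

test_that("trial rendering flags an empty scene and is signal-deterministic", {
  cams <- fx_cameras()
  empty <- render_trial_images(list(), list(), cams)
  expect_true(all(vapply(empty$stacks[[1]], function(im) all(im == 0),
                         logical(1))))
  scene <- fx_track_scene()
  a <- render_trial_images(fx_bones()["calcaneus"],
                           list(calcaneus = scene$truth), cams,
                           noise_sd = 0.1, seed = 4)
  b <- render_trial_images(fx_bones()["calcaneus"],
                           list(calcaneus = scene$truth), cams,
                           noise_sd = 0.1, seed = 4)
  expect_identical(a$stacks[[1]][[1]], b$stacks[[1]][[1]])
  c2 <- render_trial_images(fx_bones()["calcaneus"],
                            list(calcaneus = scene$truth), cams,
                            noise_sd = 0.1, seed = 5)
  d <- a$stacks[[1]][[1]] - c2$stacks[[1]][[1]]
  # same signal term, different noise: difference is pure noise
  expect_gt(stats::sd(d), 0.05)
  expect_lt(abs(mean(d)), 0.02)
})
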