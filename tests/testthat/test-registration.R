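test_that("rigid fit recovers exact transforms and reports honest residuals", {
  set.seed(41)
  A <- matrix(rnorm(33, sd = 40), 11, 3)
  expect_identity <- rigid_fit(A, A)
  expect_equal(expect_identity$R, diag(3), tolerance = 1e-12)
  expect_equal(expect_identity$t, c(0, 0, 0), tolerance = 1e-10)
  expect_lt(expect_identity$fit_rms, 1e-10)
  R <- cardan_zxy(30, 0, 0)  # 30 degrees about z
  B <- sweep(A %*% t(R), 2, -c(7, -2, 11))
  tf <- rigid_fit(A, B)
  expect_equal(tf$R, R, tolerance = 1e-12)
  expect_equal(tf$t, c(7, -2, 11), tolerance = 1e-10)
  expect_lt(tf$fit_rms, 1e-9)
})

test_that("rigid fit on the 11-bead fixture with 0.1 mm noise has 0.1 mm-scale residual", {
  pts <- make_coreg_object(seed = 5)
  R <- cardan_zxy(12, -8, 20)
  rms <- replicate(20, {
    noisy <- sweep(pts %*% t(R), 2, -c(3, 4, -5)) +
      matrix(rnorm(33, sd = 0.1), 11, 3)
    rigid_fit(pts, noisy)$fit_rms
  })
  expect_gt(mean(rms), 0.03)
  expect_lt(mean(rms), 0.2)
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(rigid_fit(line, line), "collinear")
  expect_error(rigid_fit(line[1:2, ], line[1:2, ]), "3 paired")
})

test_that("rigid fit never returns a reflection", {
  set.seed(42)
  # near-planar cloud plus reflected target tempts an improper solution
  A <- cbind(matrix(rnorm(20, sd = 30), 10, 2), rnorm(10, sd = 0.01))
  B <- A %*% diag(c(1, 1, -1)) + matrix(rnorm(30, sd = 0.5), 10, 3)
  tf <- rigid_fit(A, B)
  expect_equal(det(tf$R), 1, tolerance = 1e-9)
})

test_that("rigid fit is invariant to pair relabeling and equivariant to common motion", {
  set.seed(43)
  A <- matrix(rnorm(33, sd = 30), 11, 3)
  R <- cardan_zxy(25, 10, -5); tt <- c(4, -6, 2)
  B <- sweep(A %*% t(R), 2, -tt)
  perm <- sample(11)
  tf1 <- rigid_fit(A, B)
  tf2 <- rigid_fit(A[perm, ], B[perm, ])
  expect_equal(tf1$R, tf2$R, tolerance = 1e-10)
  expect_equal(tf1$t, tf2$t, tolerance = 1e-8)
  G <- rigid_transform(cardan_zxy(-40, 3, 8), c(100, 0, -50))
  tf3 <- rigid_fit(transform_points(G, A), transform_points(G, B))
  # common motion of both clouds conjugates the fitted transform
  expect_equal(tf3$R, G$R %*% tf1$R %*% t(G$R), tolerance = 1e-9)
})

test_that("co-registration round-trips exactly across data types", {
  tf <- rigid_transform(cardan_zxy(20, 5, -15), c(250, -120, 30))
  truth <- fx_truth()
  traj <- truth$poses$calcaneus
  back <- coregister(coregister(traj, tf), transform_inverse(tf))
  expect_equal(back$Tr, traj$Tr, tolerance = 1e-10)
  expect_lt(max(abs(abs(rowSums(back$Q * traj$Q)) - 1)), 1e-10)
  ms <- fx_rigid_markers()
  ms_back <- coregister(coregister(ms, tf), transform_inverse(tf))
  expect_equal(ms_back$pos, ms$pos, tolerance = 1e-9)
  # identity and pure-translation behavior
  id <- rigid_transform(diag(3), c(0, 0, 0))
  expect_equal(coregister(traj, id)$Tr, traj$Tr, tolerance = 1e-12)
  sh <- coregister(traj, rigid_transform(diag(3), c(5, 0, 0)))
  expect_equal(sh$Tr, sweep(traj$Tr, 2, -c(5, 0, 0)), tolerance = 1e-12)
  expect_equal(sh$Q, traj$Q, tolerance = 1e-12)
})

test_that("virtual marker seeding and replay is a definitional round trip", {
  bones <- fx_bones()
  static <- make_static_markers(bones)
  set.seed(44)
  static_poses <- lapply(stats::setNames(names(bones), names(bones)),
                         function(b) rigid_pose(rand_quat(), rnorm(3, sd = 15)))
  moved <- synthesize_markers(
    bones,
    lapply(static_poses, function(p) {
      pose_trajectory("x", matrix(p$q, 1), matrix(p$t, 1), 250)
    }),
    sta_model(amplitude = 0))
  defs <- seed_virtual_markers(moved, static_poses)
  # replaying at the static poses reproduces the static markers
  trajs <- lapply(names(bones), function(b) {
    p <- static_poses[[b]]
    pose_trajectory(b, matrix(p$q, 1), matrix(p$t, 1), 250)
  })
  names(trajs) <- names(bones)
  replay <- replay_virtual_markers(defs, trajs)
  expect_equal(replay$pos, moved$pos[, , replay$names, drop = FALSE],
               tolerance = 1e-9)
  # a marker placed at the bone origin has local position pose^-1(origin)
  p <- static_poses$calcaneus
  M <- marker_frame(moved, 1)
  M["ST", ] <- p$t
  moved2 <- moved; moved2$pos[1, , "ST"] <- p$t
  defs2 <- seed_virtual_markers(moved2, static_poses)
  expect_equal(unlist(defs2[defs2$marker == "ST", c("lx", "ly", "lz")]),
               pose_apply(pose_inverse(p), p$t), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(unname(unlist(defs2[defs2$marker == "ST",
                                   c("lx", "ly", "lz")])),
               c(0, 0, 0), tolerance = 1e-9)
})

test_that("unassigned markers and missing poses are rejected; gaps propagate", {
  bones <- fx_bones()
  static <- make_static_markers(bones)
  poses <- lapply(stats::setNames(names(bones), names(bones)),
                  function(b) rigid_pose())
  expect_error(seed_virtual_markers(static, poses["shank"]), "static pose")
  bad_map <- rizzoli_marker_map()
  bad_map["ST"] <- NA
  expect_error(seed_virtual_markers(static, poses, assignment = bad_map),
               "assignment")
  defs <- seed_virtual_markers(static, poses)
  truth <- fx_truth()
  trajs <- truth$poses
  trajs$calcaneus$tracked[10:20] <- FALSE
  replay <- replay_virtual_markers(defs, trajs)
  expect_true(all(replay$occluded[10:20, "ST"]))
  expect_false(any(replay$occluded[, "TN"]))
})

test_that("replay through truth poses reproduces the rigid markers end to end", {
  bones <- fx_bones()
  truth <- fx_truth()
  static <- make_static_markers(bones)
  static_poses <- lapply(stats::setNames(names(bones), names(bones)),
                         function(b) rigid_pose())
  defs <- seed_virtual_markers(static, static_poses)
  replay <- replay_virtual_markers(defs, truth$poses)
  rigid <- fx_rigid_markers()
  expect_lt(max(abs(replay$pos[, , rigid$names] - rigid$pos)), 1e-6)
})
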