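test_that("LFM identities hold exactly and affine relations are recovered", {
  pct <- 0:100
  w <- 10 * sin(2 * pi * pct / 100) + 3
  self <- lfm(w, w)
  expect_equal(self$r2, 1, tolerance = 1e-12)
  expect_equal(self$a0, 0, tolerance = 1e-10)
  expect_equal(self$a1, 1, tolerance = 1e-12)
  aff <- lfm(w, 2 * w + 5)
  expect_equal(aff$r2, 1, tolerance = 1e-12)
  expect_equal(aff$a0, 5, tolerance = 1e-9)
  expect_equal(aff$a1, 2, tolerance = 1e-12)
  expect_error(lfm(rep(1, 101), w), "constant")
  expect_error(lfm(w[1:2], w[1:2]), "3")
  # fuzz: identity on random smooth waveforms
  set.seed(61)
  for (i in 1:10) {
    v <- cumsum(rnorm(101))
    r <- lfm(v, v)
    expect_equal(c(r$r2, r$a0, r$a1), c(1, 0, 1), tolerance = 1e-8)
    expect_equal(rmse(v, v), 0, tolerance = 1e-12)
  }
})

test_that("LFM r2 under additive noise matches the variance-ratio prediction", {
  set.seed(62)
  pct <- (0:100) / 100
  ref <- sin(2 * pi * pct)
  r2s <- replicate(400, {
    lfm(ref, ref + rnorm(101, sd = stats::sd(ref)))$r2
  })
  # signal-to-total variance ratio 0.5 -> mean r2 near 0.5
  expect_equal(mean(r2s), 0.5, tolerance = 0.06)
})

test_that("RMSE matches closed forms", {
  pct <- 0:100
  w <- 5 * cos(2 * pi * pct / 100)
  expect_equal(rmse(w, w + 3), 3, tolerance = 1e-12)
  # full-period sine vs zero: sqrt(1/2) of the amplitude
  s <- 4 * sin(2 * pi * (0:99) / 100)
  expect_equal(rmse(s, rep(0, 100)), 4 * sqrt(1 / 2), tolerance = 1e-9)
  expect_error(rmse(c(NA, NA), c(1, 2)), "valid")
})

test_that("marker RMS differences equal a brute-force frame loop", {
  set.seed(63)
  n <- 40
  nm <- c("A", "B", "C")
  p1 <- array(rnorm(n * 9), c(n, 3, 3), dimnames = list(NULL, NULL, nm))
  p2 <- p1 + array(rnorm(n * 9, sd = 0.5), c(n, 3, 3))
  occ <- matrix(FALSE, n, 3, dimnames = list(NULL, nm))
  occ[1:5, "B"] <- TRUE
  m1 <- marker_set(p1, 100); m2 <- marker_set(p2, 100, occ)
  out <- rms_marker_difference(m1, m2)
  for (m in nm) {
    keep <- which(!occ[, m])
    acc3 <- 0; accx <- 0
    for (i in keep) {
      d <- p1[i, , m] - p2[i, , m]
      acc3 <- acc3 + sum(d^2); accx <- accx + d[1]^2
    }
    expect_equal(out$rms_3d[out$marker == m], sqrt(acc3 / length(keep)),
                 tolerance = 1e-12)
    expect_equal(out$rms_x[out$marker == m], sqrt(accx / length(keep)),
                 tolerance = 1e-12)
  }
  # identities: equal sets give zero; a constant X offset is purely axial
  zero <- rms_marker_difference(m1, m1)
  expect_true(all(zero$rms_3d == 0))
  p3 <- p1; p3[, 1, ] <- p3[, 1, ] + 1
  one <- rms_marker_difference(m1, marker_set(p3, 100))
  expect_equal(one$rms_3d, rep(1, 3), tolerance = 1e-12)
  expect_equal(one$rms_x, rep(1, 3), tolerance = 1e-12)
  expect_equal(one$rms_y + one$rms_z, rep(0, 3), tolerance = 1e-12)
})

test_that("marker RMS is invariant under a common rigid transform", {
  set.seed(64)
  n <- 30
  p1 <- array(rnorm(n * 6, sd = 20), c(n, 3, 2),
              dimnames = list(NULL, NULL, c("A", "B")))
  p2 <- p1 + array(rnorm(n * 6, sd = 1), c(n, 3, 2))
  m1 <- marker_set(p1, 100); m2 <- marker_set(p2, 100)
  tf <- rigid_transform(cardan_zxy(28, -14, 33), c(100, -50, 20))
  a <- rms_marker_difference(m1, m2)
  b <- rms_marker_difference(coregister(m1, tf), coregister(m2, tf))
  expect_equal(a$rms_3d, b$rms_3d, tolerance = 1e-9)
})

test_that("group aggregation reports means and handles degenerate designs", {
  df <- function(x) data.frame(marker = c("A", "B"), n_frames = 10,
                               rms_3d = x, rms_x = x / 2, rms_y = x / 2,
                               rms_z = x / 2)
  # identical conditions: rank-sum test cannot reject
  rep0 <- aggregate_and_test(list(walking = list(df(1), df(2)),
                                  running = list(df(1), df(2))))
  expect_false(rep0$tests$skipped)
  expect_gt(rep0$tests$condition_rms$p, 0.9)
  # single trial per condition: tests skipped, means still reported
  rep1 <- aggregate_and_test(list(walking = list(df(1)),
                                  running = list(df(2))))
  expect_true(rep1$tests$skipped)
  expect_equal(rep1$marker_summary$walking$rms_3d_mean, c(1, 1))
})

test_that("condition test rejects when running STA doubles walking STA", {
  # Monte-Carlo power check on generator-made trials (small scenes)
  bones <- fx_bones()
  poses <- fx_truth()$poses
  rigid <- fx_rigid_markers()
  one_trial <- function(amp, seed) {
    ms <- synthesize_markers(bones, poses, sta_model(amplitude = amp,
                                                     seed = seed))
    rms_marker_difference(ms, rigid)
  }
  rejections <- vapply(1:5, function(rep_i) {
    walking <- lapply(1:20, function(k) one_trial(2.5, 1000 * rep_i + k))
    running <- lapply(1:20, function(k) one_trial(5, 2000 * rep_i + k))
    out <- aggregate_and_test(list(walking = walking, running = running))
    out$tests$condition_rms$p < 0.05
  }, logical(1))
  expect_true(all(rejections))
})
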