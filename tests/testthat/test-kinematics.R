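test_that("marker filtering preserves constants, attenuates jitter, respects gaps", {
  n <- 400; fs <- 250
  t_s <- (seq_len(n) - 1) / fs
  pos <- array(0, c(n, 3, 2), dimnames = list(NULL, NULL, c("A", "B")))
  pos[, 1, "A"] <- 5
  pos[, 2, "A"] <- 2
  pos[, 1, "B"] <- sin(2 * pi * 50 * t_s)
  ms <- marker_set(pos, fs)
  f <- filter_markers(ms, 10)
  expect_lt(max(abs(f$pos[, , "A"] - pos[, , "A"])), 1e-6)
  mid <- 100:300
  # 50 Hz jitter at 5x the cutoff: dual-pass attenuation above 95%
  expect_lt(stats::sd(f$pos[mid, 1, "B"]), 0.05 * stats::sd(pos[mid, 1, "B"]))
  expect_error(filter_markers(ms, 200), "Nyquist")
  short <- marker_set(pos[1:3, , , drop = FALSE], fs)
  expect_error(filter_markers(short, 10), "13")
})

test_that("gait events land within 2 frames of the generator truth", {
  truth <- fx_truth()
  ms <- filter_markers(fx_rigid_markers(), 10)
  ev <- detect_gait_events(ms)
  expect_equal(ev$source_marker, "ICR")
  expect_lte(abs(ev$heel_strike - truth$events$heel_strike), 2)
  expect_lte(abs(ev$toe_off - truth$events$toe_off), 2)
  expect_lt(ev$heel_strike, ev$toe_off)
})

test_that("event detection falls back to SCR and rejects monotone series", {
  ms <- fx_rigid_markers()
  occ <- ms$occluded
  occ[, "ICR"] <- TRUE
  hidden <- marker_set(ms$pos, ms$frame_rate, occ)
  ev <- detect_gait_events(hidden)
  expect_equal(ev$source_marker, "SCR")
  n <- 60
  pos <- array(0, c(n, 3, 1), dimnames = list(NULL, NULL, "ICR"))
  pos[, 3, 1] <- seq(0, 10, length.out = n)
  expect_error(detect_gait_events(marker_set(pos, 250)),
               "monotone|impact")
})

test_that("time normalization yields exactly 101 samples with exact endpoints", {
  ev <- structure(list(heel_strike = 11L, toe_off = 87L), class = "gait_events")
  ramp <- seq(-3, 14, length.out = 120)
  out <- time_normalize(ramp, ev)
  expect_length(out, 101)
  expect_equal(out[1], ramp[11], tolerance = 1e-12)
  expect_equal(out[101], ramp[87], tolerance = 1e-12)
  # a linear ramp stays linear under linear interpolation
  expect_equal(out, seq(ramp[11], ramp[87], length.out = 101),
               tolerance = 1e-9)
  const <- time_normalize(rep(4, 120), ev)
  expect_equal(const, rep(4, 101), tolerance = 1e-12)
  expect_error(time_normalize(ramp, list(heel_strike = 50, toe_off = 50)),
               "after")
})

test_that("segment frames are orthonormal and equivariant under rigid motion", {
  M <- marker_frame(fx_rigid_markers(), 20)
  fr <- segment_frames(M)
  for (f in fr) {
    expect_equal(t(f) %*% f, diag(3), tolerance = 1e-9)
    expect_equal(det(f), 1, tolerance = 1e-9)
  }
  R <- cardan_zxy(33, -12, 7); tt <- c(10, 40, -6)
  M2 <- sweep(M %*% t(R), 2, -tt)
  fr2 <- segment_frames(M2)
  for (nm in names(fr)) {
    expect_equal(fr2[[nm]], R %*% fr[[nm]], tolerance = 1e-9)
  }
  # collinear triad
  bad <- M
  bad["LtS", ] <- c(0, 0, 100); bad["MdS", ] <- c(0, 0, 110)
  bad["Shk", ] <- c(0, 0, 90)
  expect_error(segment_frames(bad), "collinear|degenerate")
  expect_error(segment_frames(M[setdiff(rownames(M), "ST"), ]), "missing")
})

test_that("ankle Cardan angles isolate axes and round-trip compositions", {
  F0 <- diag(3)
  expect_equal(unname(ankle_angles(F0, F0)), c(0, 0, 0), tolerance = 1e-12, ignore_attr = TRUE)
  Fz <- F0 %*% cardan_zxy(10, 0, 0)
  a <- ankle_angles(F0, Fz)
  expect_equal(unname(a), c(10, 0, 0), tolerance = 1e-9, ignore_attr = TRUE)
  set.seed(51)
  for (i in 1:20) {
    ang <- c(runif(1, -40, 40), runif(1, -20, 20), runif(1, -20, 20))
    rec <- ankle_angles(F0, F0 %*% cardan_zxy(ang[1], ang[2], ang[3]))
    expect_equal(unname(rec), ang, tolerance = 1e-9, ignore_attr = TRUE)
  }
  rec <- ankle_angles(F0, F0 %*% cardan_zxy(5, 3, 2))
  expect_equal(unname(rec), c(5, 3, 2), tolerance = 1e-9, ignore_attr = TRUE)
  g <- ankle_angles(F0, F0 %*% cardan_zxy(0, 88, 0))
  expect_true(attr(g, "gimbal"))
})

test_that("MLA angle matches an independent projection oracle and its identities", {
  # collinear ICR, ST, FMH along the foot x axis: zero angle
  M <- rbind(ICR = c(0, 0, 0), ST = c(50, 0, 0), FMH = c(120, 0, 0),
             PT = c(20, -40, 0))
  expect_equal(mla_angle(M), 0, tolerance = 1e-9)
  # right angle within the projection plane
  M2 <- rbind(ICR = c(0, 0, 50), ST = c(0, 0, 0), FMH = c(80, 0, 0),
              PT = c(0, -40, 0))
  expect_equal(mla_angle(M2), 90, tolerance = 1e-9)
  # general 3D configuration vs brute-force projector P = xx' + nn'
  set.seed(52)
  for (i in 1:10) {
    M3 <- rbind(ICR = c(-60, 0, 25), ST = c(0, 30, 35),
                FMH = c(120, 30, 20), PT = c(-5, -30, 30)) +
      matrix(rnorm(12, sd = 5), 4, 3)
    x <- M3["FMH", ] - M3["ST", ]; x <- x / sqrt(sum(x^2))
    y <- M3["PT", ] - M3["ST", ]; y <- y / sqrt(sum(y^2))
    nv <- c(x[2] * y[3] - x[3] * y[2], x[3] * y[1] - x[1] * y[3],
            x[1] * y[2] - x[2] * y[1])
    nv <- nv / sqrt(sum(nv^2))
    P <- tcrossprod(x) + tcrossprod(nv)
    v1 <- as.numeric(P %*% (M3["ST", ] - M3["ICR", ]))
    v2 <- as.numeric(P %*% (M3["FMH", ] - M3["ST", ]))
    oracle <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    expect_equal(mla_angle(M3), oracle, tolerance = 1e-6)
  }
  # invariant under common rigid motion
  R <- cardan_zxy(17, 9, -21)
  M4 <- sweep(M3 %*% t(R), 2, -c(30, -10, 80))
  expect_equal(mla_angle(M4), mla_angle(M3), tolerance = 1e-6)
  expect_error(mla_angle(rbind(ICR = c(0, 0, 0), ST = c(1, 0, 0),
                               FMH = c(2, 0, 0), PT = c(3, 0, 0))),
               "degenerate")
})

test_that("stance-window cropping keeps the documented sample counts", {
  w <- seq(0, 10, length.out = 101)
  full <- crop_to_window(w, 0, 100)
  expect_equal(sum(is.finite(full)), 101)
  win <- crop_to_window(w, 11, 75)
  expect_equal(sum(is.finite(win)), 65)  # integer percents 11..75
  expect_true(all(is.na(win[c(1:11, 77:101)])))
  expect_error(crop_to_window(w, 40, 40), "invalid")
  expect_error(crop_to_window(w[1:50], 11, 75), "101")
})

test_that("zero-STA angles agree between marker paths within 1e-6 degrees", {
  bones <- fx_bones()
  truth <- fx_truth()
  static <- make_static_markers(bones)
  defs <- seed_virtual_markers(
    static, lapply(stats::setNames(names(bones), names(bones)),
                   function(b) rigid_pose()))
  replay <- replay_virtual_markers(defs, truth$poses)
  omc <- fx_rigid_markers()
  ev <- structure(list(heel_strike = truth$events$heel_strike,
                       toe_off = truth$events$toe_off),
                  class = "gait_events")
  w1 <- angle_waveforms(omc, ev)
  w2 <- angle_waveforms(replay, ev)
  expect_lt(max(abs(w1 - w2), na.rm = TRUE), 1e-6)
})
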