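#' Synthetic stance-phase gait scenarios
#'
#' A scenario fixes everything about one simulated trial: activity, sampling
#' rate, stance length, smooth parametric pose programs for the four bones,
#' the soft-tissue-artifact (STA) model, the OMC/BVR sample-rate mismatch and
#' the seed. Pose programs are closed-form in time, so trajectories can be
#' sampled on the radiographic grid and on a mismatched optical grid from the
#' same ground truth.
#'
#' The calcaneus vertical program integrates a velocity profile made of one
#' negative Gaussian lobe (impact, heel-strike-like) and one positive lobe
#' (lift-off, toe-off-like), so its velocity has exactly one interior minimum
#' and one interior maximum; ankle rotations are sagittal-dominant with small
#' frontal/transverse components, matching the plane-asymmetry of stance.
#'
#' @name gait
NULL

#' Soft-tissue-artifact model
#'
#' Per-marker STA displacement is the sum of a motion-correlated component
#' (skin stretch tracking the ankle's sagittal excursion, in a seeded fixed
#' direction per marker; weight \code{motion_coupling}) and band-limited
#' Gaussian noise (white noise through a zero-phase 2nd-order Butterworth
#' low-pass at \code{smoothness} Hz). The combination is rescaled so each
#' marker's 3D displacement RMS equals its amplitude; an optional constant
#' bias is added on top. Amplitude defaults follow per-segment magnitudes:
#' largest on the shank (greater soft-tissue mass), smallest on the
#' calcaneus.
#'
#' @param amplitude per-marker 3D RMS displacement, mm: a scalar, a named
#'   vector (by marker), or NULL for per-segment defaults.
#' @param smoothness cutoff of the displacement noise, Hz.
#' @param motion_coupling fraction (in RMS) of the artifact that follows the
#'   sagittal joint excursion; 0 = pure noise.
#' @param offset constant bias, mm: length-3 vector applied to all markers or
#'   a markers x 3 matrix.
#' @param seed integer seed for the noise stream.
#' @export
sta_model <- function(amplitude = NULL, smoothness = 6,
                      motion_coupling = 0.6, offset = c(0, 0, 0),
                      seed = 1L) {
  stopifnot(smoothness > 0, motion_coupling >= 0, motion_coupling <= 1)
  if (!is.null(amplitude) && any(amplitude < 0)) {
    stop("STA amplitude must be >= 0")
  }
  structure(list(amplitude = amplitude, smoothness = smoothness,
                 motion_coupling = motion_coupling,
                 offset = offset, seed = as.integer(seed)),
            class = "sta_model")
}

# per-segment default STA 3D RMS amplitudes (mm), walking
sta_segment_defaults <- c(shank = 4, calcaneus = 2.5, navicular = 3,
                          metatarsal = 3.5)

# resolve the STA amplitude for every marker name
resolve_sta_amplitude <- function(sta, names, activity = "walking") {
  mmap <- rizzoli_marker_map()
  if (is.null(sta$amplitude)) {
    amp <- sta_segment_defaults[mmap[names]]
    if (activity == "running") amp <- amp * 1.6
  } else if (length(sta$amplitude) == 1) {
    amp <- rep(sta$amplitude, length(names))
  } else {
    if (!all(names %in% names(sta$amplitude))) {
      stop("per-marker STA amplitude missing entries")
    }
    amp <- sta$amplitude[names]
  }
  stats::setNames(as.numeric(amp), names)
}

#' Construct a gait scenario
#'
#' @param activity "walking" or "running"; running scales rotation amplitudes
#'   by 1.3, deepens the impact/lift-off profile, and (by default) raises STA.
#' @param frame_rate sampling rate, Hz.
#' @param stance_duration_s duration of the full stance phase in seconds;
#'   NULL picks a physiologic value (0.6 s walking, 0.4 s running). Pose
#'   programs run in real time against this duration, so shorter recordings
#'   capture an excerpt of stance at unchanged motion speed.
#' @param stance_frames number of frames recorded (>= 20); NULL records the
#'   whole stance at \code{frame_rate}.
#' @param amp_scale global multiplier on every pose-program amplitude; 0
#'   gives constant identity poses.
#' @param sta soft-tissue-artifact model (\code{sta_model}).
#' @param heel_pad_compression_mm optional transient inferior displacement of
#'   the calcaneal markers over the first 50 ms after heel strike (NULL =
#'   off; 10-12 mm is a realistic heel-pad range).
#' @param rate_mismatch OMC-to-BVR sample-rate ratio in [0.9, 1.1].
#' @param seed integer seed.
#' @export
gait_scenario <- function(activity = c("walking", "running"),
                          frame_rate = 250, stance_duration_s = NULL,
                          stance_frames = NULL,
                          amp_scale = 1, sta = sta_model(),
                          heel_pad_compression_mm = NULL,
                          rate_mismatch = 1.0, seed = 1L) {
  activity <- match.arg(activity)
  if (is.null(stance_duration_s)) {
    stance_duration_s <- if (activity == "running") 0.4 else 0.6
  }
  if (is.null(stance_frames)) {
    stance_frames <- round(frame_rate * stance_duration_s)
  }
  if (stance_frames < 20) stop("stance_frames must be >= 20")
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  if (rate_mismatch < 0.9 || rate_mismatch > 1.1) {
    stop("rate_mismatch must lie in [0.9, 1.1]")
  }
  run <- activity == "running"
  amp <- list(
    sag = 25 * (if (run) 1.3 else 1),      # deg, plantar/dorsiflexion
    fro = 2.5 * (if (run) 1.3 else 1),     # deg, inversion/eversion
    tra = 1.5 * (if (run) 1.3 else 1),     # deg, ab/adduction (smallest ROM)
    pitch = 4 * (if (run) 1.3 else 1),     # deg, whole-foot pitch
    mla = 8 * (if (run) 1.3 else 1),       # deg, arch joint excursion
    nav_frac = 0.5,                        # navicular share of arch motion
    drop_mm = if (run) 28 else 20,         # descent into / rise out of stance
    forward_mm = if (run) 9 else 6,        # forward progression
    lateral_mm = 1.5)                      # medial-lateral sway
  amp <- lapply(amp, function(a) a * amp_scale)
  amp$nav_frac <- if (amp_scale > 0) 0.5 else 0
  structure(list(activity = activity, frame_rate = frame_rate,
                 stance_duration_s = stance_duration_s,
                 stance_frames = as.integer(stance_frames), amp = amp,
                 sta = sta, heel_pad_compression_mm = heel_pad_compression_mm,
                 rate_mismatch = rate_mismatch, seed = as.integer(seed)),
            class = "gait_scenario")
}

rot_z <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                            3, 3, byrow = TRUE)
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                            3, 3, byrow = TRUE)
rot_y <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
                            3, 3, byrow = TRUE)

#' Compose a Cardan Z-X-Y rotation (degrees)
#' @param sag,fro,tra rotations about z, x, y in degrees, applied in that
#'   order: \code{R = Rz(sag) Rx(fro) Ry(tra)}.
#' @export
cardan_zxy <- function(sag, fro, tra) {
  d <- pi / 180
  rot_z(sag * d) %*% rot_x(fro * d) %*% rot_y(tra * d)
}

# joint frame used by the pose programs: local z = sagittal axis (global -Y,
# medial-lateral), local x = anterior, local y = superior
joint_frame <- function() {
  cbind(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0))
}

# integral of exp(-((s-c)/w)^2) from 0 to s
gauss_int <- function(s, c, w) {
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  w * sqrt(pi) / 2 * (erf((s - c) / w) - erf((0 - c) / w))
}

# fraction-of-stance positions of the impact and lift-off velocity extrema
gait_event_fractions <- function() c(hs = 0.12, to = 0.88)

# pose of a rotation R about a fixed world point p, plus translation d
rot_about_point <- function(R, p, d = c(0, 0, 0)) {
  rigid_pose(matrix_to_quat(R), p + d - as.numeric(R %*% p))
}

# closed-form pose program: times (s) -> list of rigid poses per bone
gait_pose_program <- function(scenario) {
  amp <- scenario$amp
  Ttrial <- scenario$stance_duration_s
  ctr <- segment_rest_centers()
  a0 <- c(0, 0, 45)        # ankle joint center, world rest
  jm <- c(60, 0, 25)       # arch (midfoot) joint center, world rest
  Fj <- joint_frame()
  ef <- gait_event_fractions()
  # impact/lift-off lobe width: 0.08 of stance (~50 ms of a walking stance,
  # the time scale of heel-pad loading); lobe heights give drop_mm of
  # vertical excursion each
  w <- 0.08
  A1 <- amp$drop_mm / (w * sqrt(pi))
  A2 <- amp$drop_mm / (w * sqrt(pi))
  d <- pi / 180
  function(times) {
    s <- times / Ttrial
    out <- lapply(seq_along(s), function(i) {
      si <- s[i]
      # starts drop_mm above the planted level, descends through the
      # impact lobe, stays planted, and rises again through lift-off
      dz <- amp$drop_mm - A1 * gauss_int(si, ef["hs"], w) +
        A2 * gauss_int(si, ef["to"], w)
      dtr <- c(amp$forward_mm * si, amp$lateral_mm * sin(pi * si), dz)
      R_pitch <- rot_y(amp$pitch * sin(2 * pi * si) * d)
      calc <- rot_about_point(R_pitch, ctr["calcaneus", ], dtr)
      sag <- amp$sag * sin(pi * si)
      fro <- amp$fro * sin(2 * pi * si)
      tra <- amp$tra * (sin(2 * pi * si + 1) - sin(1))
      R_ankle <- Fj %*% cardan_zxy(sag, fro, tra) %*% t(Fj)
      ankle <- rot_about_point(R_ankle, a0)
      shank <- pose_compose(calc, pose_inverse(ankle))
      R_mla <- rot_y(-amp$mla * sin(pi * si) * d)
      met <- pose_compose(calc, rot_about_point(R_mla, jm))
      R_nav <- rot_y(-amp$nav_frac * amp$mla * sin(pi * si) * d)
      nav <- pose_compose(calc, rot_about_point(R_nav, jm))
      list(shank = shank, calcaneus = calc, navicular = nav, metatarsal = met)
    })
    out
  }
}

#' Generate ground-truth bone pose trajectories for a scenario
#'
#' @param scenario a \code{gait_scenario}.
#' @return object of class \code{gait_truth}: \code{poses} (named list of
#'   \code{pose_trajectory} on the radiographic frame grid), \code{events}
#'   (true heel-strike / toe-off frames), \code{program} (the closed-form
#'   pose program, for resampling on other time grids) and the scenario.
#' @export
make_gait_trajectory <- function(scenario) {
  stopifnot(inherits(scenario, "gait_scenario"))
  N <- scenario$stance_frames
  times <- (seq_len(N) - 1) / scenario$frame_rate
  prog <- gait_pose_program(scenario)
  plist <- prog(times)
  bones <- names(plist[[1]])
  poses <- lapply(bones, function(b) {
    Q <- t(vapply(plist, function(p) p[[b]]$q, numeric(4)))
    Tr <- t(vapply(plist, function(p) p[[b]]$t, numeric(3)))
    pose_trajectory(b, Q, Tr, scenario$frame_rate)
  })
  names(poses) <- bones
  ef <- gait_event_fractions()
  ev_frame <- function(f) {
    as.integer(1 + round(f * scenario$stance_duration_s *
                           scenario$frame_rate))
  }
  events <- list(heel_strike = ev_frame(ef["hs"]),
                 toe_off = ev_frame(ef["to"]))
  events$in_window <- events$heel_strike >= 1 && events$toe_off <= N
  structure(list(poses = poses, events = events, program = prog,
                 scenario = scenario),
            class = "gait_truth")
}

# zero-phase (forward-backward) filtering with reflected-and-flipped end
# padding, so short stance series do not pick up edge transients
filtfilt_refl <- function(bf, x) {
  n <- length(x)
  np <- min(n - 1, 90)
  head_pad <- 2 * x[1] - x[(np + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(np + 1):(np + n)]
}

# band-limited unit-RMS noise of length n (filtered white noise, rescaled)
band_limited_noise <- function(n, cutoff, frame_rate, rnorm_fun) {
  if (cutoff >= frame_rate / 2) stop("STA cutoff must be below Nyquist")
  if (n < 13) stop("need >= 13 frames for band-limited STA noise")
  bf <- signal::butter(2, cutoff / (frame_rate / 2))
  x <- filtfilt_refl(bf, rnorm_fun(n))
  r <- sqrt(mean(x^2))
  if (r < 1e-12) return(rep(0, n))
  x / r
}

#' Synthesize skin-marker trajectories from bone poses
#'
#' Each marker is its parent bone's landmark carried through that bone's pose
#' trajectory, plus STA displacement. With STA amplitude 0 (and no heel-pad
#' compression) the output is the exact rigid replay.
#'
#' @param bones named list of \code{phantom_bone}s.
#' @param poses named list of \code{pose_trajectory}, one per bone, all on
#'   the same frame grid.
#' @param sta an \code{sta_model}.
#' @param activity "walking" or "running" (scales default STA amplitudes).
#' @param heel_pad_mm optional heel-pad compression magnitude, mm; applied as
#'   a smooth inferior bump on calcaneal markers in the 50 ms after
#'   \code{heel_strike_frame}.
#' @param heel_strike_frame frame of heel strike (required with
#'   \code{heel_pad_mm}).
#' @return a \code{marker_set}.
#' @export
synthesize_markers <- function(bones, poses, sta = sta_model(amplitude = 0),
                               activity = "walking", heel_pad_mm = NULL,
                               heel_strike_frame = NULL) {
  mmap <- rizzoli_marker_map()
  all_marks <- unlist(lapply(bones, function(b) rownames(b$landmarks)))
  n <- n_frames(poses[[1]])
  fr <- poses[[1]]$frame_rate
  for (p in poses) stopifnot(n_frames(p) == n)
  pos <- array(NA_real_, c(n, 3, length(all_marks)),
               dimnames = list(NULL, c("X", "Y", "Z"), all_marks))
  for (b in bones) {
    if (is.null(poses[[b$name]])) {
      stop("no pose trajectory for parent bone ", b$name)
    }
    tr <- poses[[b$name]]
    for (i in seq_len(n)) {
      Ri <- quat_to_matrix(tr$Q[i, ])
      pts <- tr$Tr[rep(i, nrow(b$landmarks)), , drop = FALSE] +
        b$landmarks %*% t(Ri)
      pos[i, , rownames(b$landmarks)] <- t(pts)
    }
  }
  amp <- resolve_sta_amplitude(sta, all_marks, activity)
  if (any(amp > 0)) {
    rnorm_fun <- make_rng_norm(sta$seed, "sta")
    gam <- sta$motion_coupling
    drive <- rep(0, n)
    if (gam > 0 && all(c("shank", "calcaneus") %in% names(poses))) {
      sagit <- vapply(seq_len(n), function(i) {
        Rs <- quat_to_matrix(poses$shank$Q[i, ])
        Rc <- quat_to_matrix(poses$calcaneus$Q[i, ])
        Fj <- joint_frame()
        R <- t(Fj) %*% t(Rs) %*% Rc %*% Fj
        atan2(-R[1, 2], R[2, 2])     # sagittal Cardan component
      }, numeric(1))
      drive <- sagit - mean(sagit)
      rd <- sqrt(mean(drive^2))
      if (rd > 1e-9) drive <- drive / rd else drive <- rep(0, n)
    }
    if (all(drive == 0)) gam <- 0
    for (m in all_marks) {
      if (amp[m] == 0) next
      noise <- vapply(1:3, function(ax) {
        band_limited_noise(n, sta$smoothness, fr, rnorm_fun)
      }, numeric(n))
      u <- rnorm_fun(3)
      u <- u / sqrt(sum(u^2))
      d <- sqrt(1 - gam^2) * noise / sqrt(3) + gam * outer(drive, u)
      # rescale so the realized 3D displacement RMS equals the amplitude
      rms3 <- sqrt(mean(rowSums(d^2)))
      if (rms3 > 1e-9) d <- d / rms3
      pos[, , m] <- pos[, , m] + amp[m] * d
    }
  }
  off <- sta$offset
  if (is.matrix(off)) {
    for (m in rownames(off)) pos[, , m] <- sweep(pos[, , m], 2, -off[m, ])
  } else if (any(off != 0)) {
    for (m in all_marks) pos[, , m] <- sweep(pos[, , m], 2, -off)
  }
  if (!is.null(heel_pad_mm)) {
    if (is.null(heel_strike_frame)) {
      stop("heel_strike_frame is required with heel_pad_mm")
    }
    u <- ((seq_len(n) - heel_strike_frame) / fr)    # seconds after HS
    bump <- heel_pad_mm * exp(-((u - 0.025) / 0.012)^2) * (u >= 0)
    for (m in names(mmap)[mmap == "calcaneus"]) {
      if (m %in% all_marks) pos[, 3, m] <- pos[, 3, m] - bump
    }
  }
  marker_set(pos, fr)
}

#' Static standing-trial markers (single frame, zero STA)
#'
#' Markers at their anatomical rest positions, as captured in a static
#' calibration trial.
#' @param bones named list of \code{phantom_bone}s.
#' @param frame_rate nominal rate, Hz.
#' @export
make_static_markers <- function(bones, frame_rate = 250) {
  marks <- do.call(rbind, lapply(bones, function(b) b$landmarks))
  pos <- array(NA_real_, c(1, 3, nrow(marks)),
               dimnames = list(NULL, c("X", "Y", "Z"), rownames(marks)))
  pos[1, , ] <- t(marks)
  marker_set(pos, frame_rate)
}
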