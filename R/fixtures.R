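#' Calibration and synchronization fixtures
#'
#' Synthetic stand-ins for the physical calibration hardware of a biplanar
#' x-ray / optical capture laboratory: a four-layer bead calibration cube
#' (4 x 16 = 64 radio-opaque beads at known positions), an 11-bead
#' co-registration object visible to both systems, five dropped-marker
#' synchronization trials, and an undistortion grid image with an optional
#' known distortion field.
#'
#' @name fixtures
NULL

#' Known 3D bead positions of the calibration cube
#'
#' Four plexiglass layers, each with a 4 x 4 grid of beads.
#' @param center cube center in world mm.
#' @param pitch in-layer bead spacing, mm.
#' @param layer_gap vertical spacing between layers, mm.
#' @return 64 x 3 matrix of bead positions.
#' @export
make_calibration_cube <- function(center = c(30, 0, 60), pitch = 30,
                                  layer_gap = 30) {
  g <- (c(1, 2, 3, 4) - 2.5) * pitch
  lz <- (c(1, 2, 3, 4) - 2.5) * layer_gap
  beads <- as.matrix(expand.grid(x = g, y = g, z = lz))
  sweep(beads, 2, -center)
}

#' Known geometry of the co-registration object
#'
#' Eleven steel beads at the centers of retro-reflective markers, so each
#' point is seen as a bead by the x-ray system and as a marker by the
#' optical system. Positions are a seeded, well-spread, non-coplanar cloud.
#' @param seed integer seed.
#' @param center object center, world mm.
#' @param radius cloud half-extent, mm.
#' @return 11 x 3 matrix.
#' @export
make_coreg_object <- function(seed = 1L, center = c(30, 0, 60), radius = 60) {
  rng <- make_rng(seed, "coreg")
  pts <- matrix(rng(33), 11, 3) * 2 - 1
  sweep(pts * radius, 2, -center)
}

#' Synthetic dropped-marker synchronization trials
#'
#' A marker falls from a known height and bounces elastically off a
#' compliant surface: the flight phases are exact parabolas and the brief
#' contact rounds the velocity reversal into a smooth symmetric valley whose
#' minimum marks the impact time. Each trial is recorded by both systems,
#' the optical one at \code{rate_mismatch} times the radiographic rate and
#' delayed by \code{offset_frames} (radiographic frames).
#'
#' @param n_trials number of drops.
#' @param rate_mismatch OMC-to-BVR sample-rate ratio.
#' @param offset_frames temporal offset of the optical clock, BVR frames.
#' @param frame_rate radiographic rate, Hz.
#' @param heights_mm drop heights (recycled across trials), mm.
#' @param noise_sd additive measurement noise on the coordinates, mm.
#' @param seed integer seed.
#' @return list of trials, each \code{list(bvr =, omc =)} vertical series
#'   (mm), plus attributes \code{rate_mismatch} and \code{offset_frames}.
#' @export
make_drop_trials <- function(n_trials = 5, rate_mismatch = 1.0,
                             offset_frames = 0, frame_rate = 250,
                             heights_mm = c(80, 120, 160, 200, 250),
                             noise_sd = 0.02, seed = 1L) {
  g <- 9810  # mm / s^2
  rnorm_fun <- make_rng_norm(seed, "drops")
  heights <- rep(heights_mm, length.out = n_trials)
  trials <- lapply(seq_len(n_trials), function(k) {
    H <- heights[k]
    Timp <- sqrt(2 * H / g)
    # elastic bounce: exact mirror parabola, smooth symmetric minimum
    tau <- 0.004  # contact compliance time constant, s
    zfun <- function(t) {
      tt <- sqrt((t - Timp)^2 + tau^2)  # smoothed |t - T|: compliant floor
      H - g / 2 * (Timp - tt)^2
    }
    dur <- 2 * Timp + 0.05
    nb <- floor(dur * frame_rate)
    tb <- (seq_len(nb) - 1) / frame_rate
    # optical frame j samples true time (j - 1 + offset) / (rate * mismatch)
    no <- floor(dur * frame_rate * rate_mismatch)
    to <- (seq_len(no) - 1 + offset_frames) / (frame_rate * rate_mismatch)
    list(bvr = zfun(tb) + noise_sd * rnorm_fun(nb),
         omc = zfun(pmin(to, dur)) + noise_sd * rnorm_fun(no))
  })
  attr(trials, "rate_mismatch") <- rate_mismatch
  attr(trials, "offset_frames") <- offset_frames
  trials
}

#' Render a synthetic undistortion-grid image
#'
#' A regular lattice of bright Gaussian "holes" on a dark background, warped
#' by an optional known radial distortion about the image center.
#'
#' @param image_size c(width, height), pixels.
#' @param pitch lattice pitch, pixels.
#' @param sigma blob width, pixels.
#' @param radial_k radial distortion coefficient (px^-2); observed position
#'   = ideal + k * r^2 * (ideal - center).
#' @return list: \code{image} (height x width matrix in [0, 1]),
#'   \code{ideal} (n x 2 ideal lattice positions, zero-based pixels),
#'   \code{observed} (warped positions actually rendered), \code{pitch}.
#' @export
make_undistortion_grid <- function(image_size = c(160, 160), pitch = 12,
                                   sigma = 1.4, radial_k = 0) {
  w <- image_size[1]; h <- image_size[2]
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  margin <- pitch
  xs <- seq(margin, w - 1 - margin, by = pitch)
  ys <- seq(margin, h - 1 - margin, by = pitch)
  ideal <- as.matrix(expand.grid(u = xs, v = ys))
  r2 <- (ideal[, 1] - cx)^2 + (ideal[, 2] - cy)^2
  obs <- ideal + radial_k * r2 * cbind(ideal[, 1] - cx, ideal[, 2] - cy)
  img <- matrix(0, h, w)
  ug <- matrix(0:(w - 1), h, w, byrow = TRUE)
  vg <- matrix(0:(h - 1), h, w)
  for (i in seq_len(nrow(obs))) {
    img <- img + exp(-(((ug - obs[i, 1])^2 + (vg - obs[i, 2])^2) /
                         (2 * sigma^2)))
  }
  img <- pmin(img, 1)
  list(image = img, ideal = ideal, observed = obs, pitch = pitch)
}

#' Generate the full fixture bundle
#'
#' @param seed integer seed.
#' @param rate_mismatch OMC-to-BVR sample-rate ratio used for the drop
#'   trials.
#' @param offset_frames temporal offset used for the drop trials.
#' @param radial_k distortion applied to the undistortion grid.
#' @return list with \code{cube_beads} (64 x 3), \code{coreg_points}
#'   (11 x 3), \code{drop_trials} (5 trials), and \code{undistortion_grid}.
#' @export
make_fixtures <- function(seed = 1L, rate_mismatch = 1.0, offset_frames = 0,
                          radial_k = 0) {
  list(cube_beads = make_calibration_cube(),
       coreg_points = make_coreg_object(seed = seed),
       drop_trials = make_drop_trials(rate_mismatch = rate_mismatch,
                                      offset_frames = offset_frames,
                                      seed = seed),
       undistortion_grid = make_undistortion_grid(radial_k = radial_k))
}
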