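#' Multi-segment foot kinematics
#'
#' Marker filtering, gait-event detection from calcaneal marker velocity,
#' Rizzoli-style segment frames, ankle Cardan angles (Z-X-Y:
#' plantar/dorsiflexion, inversion/eversion, ab/adduction), the medial
#' longitudinal arch (MLA) angle, time normalization to 101 percent-of-stance
#' samples and the 11-75% analysis window.
#'
#' Segment frame recipes (single source of truth; all frames have local
#' x ~ anterior, y ~ superior, z = x cross y ~ lateral):
#' \itemize{
#'   \item shank: y0 = midpoint(LtS, MdS) - Shk (superior);
#'     z0 = MdS - LtS; x = z0 x y0 normalized, z = x x y.
#'   \item calcaneus: x0 = midpoint(ST, PT) - midpoint(SCR, ICR) (anterior);
#'     y0 = SCR - ICR (superior); z = x0 x y0... orthonormalized as below.
#'   \item metatarsus: x0 = SMH - SMB (anterior); w0 = FMB - VMB (medial);
#'     y = x0 cross w0 ... orthonormalized.
#' }
#' Each recipe is finished by the same Gram-Schmidt step: normalize x, set
#' z = normalize(x cross y0), y = z cross x.
#'
#' @name kinematics
NULL

# right-handed orthonormal frame from an anterior axis and a superior hint
frame_from_xy <- function(x0, y0) {
  nx <- sqrt(sum(x0^2))
  if (nx < 1e-9) stop("degenerate segment axis")
  x <- x0 / nx
  z0 <- pracma_cross(x, y0)
  nz <- sqrt(sum(z0^2))
  if (nz < 1e-9) stop("collinear segment markers")
  z <- z0 / nz
  y <- pracma_cross(z, x)
  `dimnames<-`(cbind(x, y, z), NULL)
}

#' Segment frames from one frame of markers
#'
#' @param markers named n x 3 matrix of marker positions (one frame, mm), or
#'   a \code{marker_set} plus \code{frame}.
#' @param frame frame index when \code{markers} is a \code{marker_set}.
#' @return list of 3x3 orthonormal frames (columns x, y, z) for
#'   \code{shank}, \code{calcaneus}, \code{metatarsus}; segments with
#'   occluded required markers are reported as errors.
#' @export
segment_frames <- function(markers, frame = 1) {
  M <- if (inherits(markers, "marker_set")) marker_frame(markers, frame)
  else as.matrix(markers)
  need <- function(nms, seg) {
    if (!all(nms %in% rownames(M))) {
      stop("segment ", seg, ": required marker(s) missing/occluded: ",
           paste(setdiff(nms, rownames(M)), collapse = ", "))
    }
    M[nms, , drop = FALSE]
  }
  s <- need(c("LtS", "MdS", "Shk"), "shank")
  sh_y <- (s["LtS", ] + s["MdS", ]) / 2 - s["Shk", ]
  sh_x0 <- pracma_cross(s["MdS", ] - s["LtS", ], sh_y)
  shank <- frame_from_xy(sh_x0, sh_y)
  cpts <- need(c("SCR", "ICR", "ST", "PT"), "calcaneus")
  ca_x <- (cpts["ST", ] + cpts["PT", ]) / 2 -
    (cpts["SCR", ] + cpts["ICR", ]) / 2
  ca_y <- cpts["SCR", ] - cpts["ICR", ]
  calcaneus <- frame_from_xy(ca_x, ca_y)
  m <- need(c("FMB", "SMB", "VMB", "FMH", "SMH", "VMH"), "metatarsus")
  mt_x <- m["SMH", ] - m["SMB", ]
  mt_y <- pracma_cross(mt_x, m["FMB", ] - m["VMB", ])
  metatarsus <- frame_from_xy(mt_x, mt_y)
  list(shank = shank, calcaneus = calcaneus, metatarsus = metatarsus)
}

#' Zero-phase Butterworth filtering of marker trajectories
#'
#' Dual-pass 2nd-order low-pass per coordinate; occlusion gaps split the
#' series and are never filtered across (runs shorter than 13 frames pass
#' through unfiltered).
#'
#' @param markers a \code{marker_set}.
#' @param cutoff_hz cutoff, Hz (below Nyquist).
#' @export
filter_markers <- function(markers, cutoff_hz = 10) {
  fr <- markers$frame_rate
  if (cutoff_hz >= fr / 2) stop("cutoff must be below the Nyquist frequency")
  n <- dim(markers$pos)[1]
  if (n == 1) return(markers)
  bf <- signal::butter(2, cutoff_hz / (fr / 2))
  pos <- markers$pos
  any_long <- FALSE
  for (m in markers$names) {
    vis <- !markers$occluded[, m]
    runs <- split(seq_len(n), cumsum(c(TRUE, diff(vis) != 0)))
    runs <- Filter(function(ix) vis[ix[1]], runs)
    for (ix in runs) {
      if (length(ix) < 13) next
      any_long <- TRUE
      for (ax in 1:3) pos[ix, ax, m] <- filtfilt_refl(bf, pos[ix, ax, m])
    }
  }
  if (!any_long) {
    stop("no contiguous visible run of >= 13 frames; cannot filter")
  }
  marker_set(pos, fr, markers$occluded)
}

#' Detect heel strike and toe off from calcaneal marker velocity
#'
#' Central-difference vertical (Z) velocity of the inferior calcaneal ridge
#' marker (ICR); heel strike is its global interior minimum and toe off the
#' global interior maximum after heel strike. Falls back to the superior
#' ridge marker (SCR) when ICR has occlusions.
#'
#' @param markers a \code{marker_set} containing ICR and/or SCR.
#' @return a \code{gait_events} list: \code{heel_strike}, \code{toe_off}
#'   (frames), \code{source_marker}.
#' @export
detect_gait_events <- function(markers) {
  n_all <- dim(markers$pos)[1]
  longest_run <- function(m) {
    if (!m %in% markers$names) return(integer(0))
    vis <- !markers$occluded[, m]
    runs <- split(seq_len(n_all), cumsum(c(TRUE, diff(vis) != 0)))
    runs <- Filter(function(ix) vis[ix[1]], runs)
    if (!length(runs)) return(integer(0))
    runs[[which.max(lengths(runs))]]
  }
  icr <- longest_run("ICR"); scr <- longest_run("SCR")
  # ICR drives detection unless occlusions cut away a substantial part of
  # its record, in which case SCR takes over
  if (length(icr) >= 0.9 * n_all || length(icr) >= length(scr)) {
    pick <- "ICR"; run <- icr
  } else {
    pick <- "SCR"; run <- scr
  }
  if (length(run) < 10) {
    stop("neither ICR nor SCR has a usable visible run for event detection")
  }
  z <- markers$pos[run, 3, pick]
  n <- length(z)
  v <- c(NA, (z[3:n] - z[1:(n - 2)]) / 2, NA)
  interior <- 2:(n - 1)
  hs <- interior[which.min(v[interior])]
  if (hs >= n - 1) stop("no interior velocity maximum after heel strike")
  after <- (hs + 1):(n - 1)
  to <- after[which.max(v[after])]
  if (v[hs] >= 0 || v[to] <= 0) {
    stop("velocity extrema do not look like impact/lift-off ",
         "(monotone trajectory?)")
  }
  structure(list(heel_strike = as.integer(run[hs]),
                 toe_off = as.integer(run[to]),
                 source_marker = pick),
            class = "gait_events")
}

#' Time-normalize a stance series to 101 samples
#'
#' Linear interpolation onto 101 equally spaced points spanning heel strike
#' (0%) to toe off (100%). Missing values inside the span propagate as
#' missing.
#'
#' @param series numeric vector over frames (NA = missing).
#' @param events a \code{gait_events} (or list with heel_strike/toe_off).
#' @return numeric vector of length 101.
#' @export
time_normalize <- function(series, events) {
  hs <- events$heel_strike; to <- events$toe_off
  if (to <= hs) stop("toe_off must be after heel_strike")
  if (to - hs < 1 || hs < 1 || to > length(series)) {
    stop("stance span invalid for this series")
  }
  x <- hs:to
  y <- series[x]
  xo <- seq(hs, to, length.out = 101)
  if (all(is.na(y))) return(rep(NA_real_, 101))
  out <- stats::approx(x, y, xout = xo)$y
  # propagate missing sub-intervals rather than interpolating across them
  if (anyNA(y)) {
    bad <- x[is.na(y)]
    for (b in bad) out[xo >= b - 1 & xo <= b + 1] <- NA
  }
  out
}

#' Ankle Cardan angles from shank and calcaneus frames
#'
#' Decomposes \code{R_rel = t(shank) \%*\% calcaneus} in Z-X-Y order:
#' z-rotation = sagittal (plantar/dorsiflexion), x-rotation = frontal
#' (inversion/eversion), y-rotation = transverse (ab/adduction), in degrees.
#'
#' @param shank_frame,calcaneus_frame 3x3 orthonormal segment frames.
#' @return named numeric length-3 (sagittal, frontal, transverse) with
#'   attribute \code{gimbal} flagging proximity to the frontal-angle
#'   singularity (|frontal| > 85 deg).
#' @export
ankle_angles <- function(shank_frame, calcaneus_frame) {
  R <- t(shank_frame) %*% calcaneus_frame
  # R = Rz(a) Rx(b) Ry(c)
  b <- asin(max(-1, min(1, R[3, 2])))
  a <- atan2(-R[1, 2], R[2, 2])
  cc <- atan2(-R[3, 1], R[3, 3])
  out <- c(sagittal = a, frontal = b, transverse = cc) * 180 / pi
  attr(out, "gimbal") <- abs(out["frontal"]) > 85
  out
}

#' Medial longitudinal arch angle from one frame of markers
#'
#' The foot plane is built from \code{x = unit(FMH - ST)} and
#' \code{y = unit(PT - ST)}; its normal is \code{n = unit(x cross y)}. The
#' vectors ICR->ST and ST->FMH are projected onto the plane spanned by
#' \code{x} and \code{n} (the foot's sagittal plane, orthogonal to the foot
#' plane) and the angle between the projections is returned in degrees.
#'
#' @param markers named n x 3 matrix (one frame) or \code{marker_set}.
#' @param frame frame index for a \code{marker_set}.
#' @param static_reference optional reference angle (deg) subtracted from the
#'   result, for static normalization.
#' @export
mla_angle <- function(markers, frame = 1, static_reference = NULL) {
  M <- if (inherits(markers, "marker_set")) marker_frame(markers, frame)
  else as.matrix(markers)
  need <- c("ICR", "ST", "FMH", "PT")
  if (!all(need %in% rownames(M))) {
    stop("MLA needs markers: ", paste(setdiff(need, rownames(M)),
                                      collapse = ", "))
  }
  xv <- M["FMH", ] - M["ST", ]
  yv <- M["PT", ] - M["ST", ]
  nx <- sqrt(sum(xv^2))
  x <- xv / nx
  nvec <- pracma_cross(x, yv / sqrt(sum(yv^2)))
  nn <- sqrt(sum(nvec^2))
  if (nn < 1e-9) stop("degenerate foot plane (x parallel to y)")
  nvec <- nvec / nn
  proj <- function(v) c(sum(v * x), sum(v * nvec))
  v1 <- proj(M["ST", ] - M["ICR", ])
  v2 <- proj(M["FMH", ] - M["ST", ])
  ang <- atan2(v1[1] * v2[2] - v1[2] * v2[1],
               sum(v1 * v2)) * 180 / pi
  ang <- abs(ang)
  if (!is.null(static_reference)) ang <- ang - static_reference
  ang
}

#' Angle waveforms across a whole trial
#'
#' Computes per-frame ankle angles (3 planes) and the MLA angle from a
#' marker set, then time-normalizes each to 101 percent-of-stance samples.
#' Frames where a required marker is occluded yield missing values.
#'
#' @param markers a \code{marker_set}.
#' @param events a \code{gait_events}.
#' @param mla_static optional static MLA reference (deg).
#' @return matrix 101 x 4 (sagittal, frontal, transverse, mla), percent of
#'   stance 0..100 on rows.
#' @export
angle_waveforms <- function(markers, events, mla_static = NULL) {
  n <- dim(markers$pos)[1]
  per_frame <- matrix(NA_real_, n, 4,
                      dimnames = list(NULL, c("sagittal", "frontal",
                                              "transverse", "mla")))
  for (i in seq_len(n)) {
    fr <- try(segment_frames(markers, i), silent = TRUE)
    if (!inherits(fr, "try-error")) {
      per_frame[i, 1:3] <- ankle_angles(fr$shank, fr$calcaneus)
    }
    ml <- try(mla_angle(markers, i, static_reference = mla_static),
              silent = TRUE)
    if (!inherits(ml, "try-error")) per_frame[i, 4] <- ml
  }
  # unwrap is unnecessary at physiologic ranges; keep continuity check cheap
  out <- vapply(1:4, function(j) time_normalize(per_frame[, j], events),
                numeric(101))
  dimnames(out) <- list(NULL, colnames(per_frame))
  out
}

#' Restrict a stance waveform to a percent-of-stance window
#'
#' @param waveform length-101 numeric (0..100% of stance).
#' @param lo,hi window bounds in percent (default 11-75).
#' @return length-101 numeric with samples outside [lo, hi] set NA;
#'   attribute \code{window} records the bounds.
#' @export
crop_to_window <- function(waveform, lo = 11, hi = 75) {
  if (length(waveform) != 101) stop("waveform must have 101 samples")
  if (lo < 0 || hi > 100 || lo >= hi) stop("invalid window [lo, hi]")
  pct <- 0:100
  waveform[pct < lo | pct > hi] <- NA
  attr(waveform, "window") <- c(lo = lo, hi = hi)
  waveform
}
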