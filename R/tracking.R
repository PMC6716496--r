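#' Markerless bone-pose tracking
#'
#' An automated stand-in for scientific rotoscoping: for each keyframe the
#' bone's pose is found by minimizing \code{1 - mean(NCC)} between its DRRs
#' and the captured radiographs across the two views with the downhill
#' simplex (Nelder-Mead) method, parameterized as a local rotation vector and
#' translation about the current estimate. Keyframes are spaced
#' \code{keyframe_stride} frames apart (default 10); intermediate rotations
#' are interpolated with a quaternion (squad) spline and translations with a
#' cubic spline. Keyframes whose final cost exceeds 1.5x the median keyframe
#' cost are re-optimized from the spline of their neighbors - an automated
#' replacement for manual retracking.
#'
#' @name tracking
NULL

#' Tracking configuration
#' @param keyframe_stride frames between optimized keyframes (>= 1).
#' @param max_iter Nelder-Mead iteration cap per keyframe.
#' @param cost_tol relative convergence tolerance on the cost.
#' @param trans_scale,rot_scale parameter scales (mm, rad) handed to the
#'   simplex; they set the initial simplex size.
#' @param step_mm DRR ray-marching step.
#' @param mask_dilate_px dilation radius of the NCC mask around nonzero DRR
#'   pixels.
#' @param retrack_factor keyframes costing more than this multiple of the
#'   median keyframe cost are re-optimized.
#' @param check_visibility flag frames whose DRR is empty in either view as
#'   untracked (costs one render per frame).
#' @export
tracking_config <- function(keyframe_stride = 10, max_iter = 400,
                            cost_tol = 1e-7, trans_scale = 10,
                            rot_scale = 0.2, step_mm = 1.0,
                            mask_dilate_px = 5, retrack_factor = 1.5,
                            check_visibility = TRUE) {
  if (keyframe_stride < 1) stop("keyframe_stride must be >= 1")
  structure(list(keyframe_stride = as.integer(keyframe_stride),
                 max_iter = max_iter, cost_tol = cost_tol,
                 trans_scale = trans_scale, rot_scale = rot_scale,
                 step_mm = step_mm, mask_dilate_px = mask_dilate_px,
                 retrack_factor = retrack_factor,
                 check_visibility = check_visibility),
            class = "tracking_config")
}

# binary dilation of a mask by a disc of the given radius
dilate_mask <- function(mask, radius) {
  if (radius < 1) return(mask)
  kern <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  EBImage::dilate(mask * 1, kern) > 0
}

#' Normalized cross-correlation of two images
#'
#' Zero-mean, unit-variance correlation over a mask; by default the mask is
#' the set of nonzero pixels of \code{image_b} (the DRR) dilated by
#' \code{mask_dilate_px}.
#'
#' @param image_a,image_b equal-size image matrices.
#' @param mask optional logical matrix; NULL uses the dilated-DRR rule.
#' @param mask_dilate_px dilation radius for the default mask.
#' @return correlation score in [-1, 1].
#' @export
ncc <- function(image_a, image_b, mask = NULL, mask_dilate_px = 5) {
  if (!all(dim(image_a) == dim(image_b))) stop("images must share a shape")
  if (is.null(mask)) {
    mask <- dilate_mask(image_b != 0, mask_dilate_px)
  }
  a <- image_a[mask]; b <- image_b[mask]
  if (length(a) < 2) stop("empty correlation mask")
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) stop("constant image within the correlation mask")
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb) *
    length(a) / (length(a) - 1)
}

# pose from a 6-parameter local chart about an anchor pose:
# world-frame rotation vector (rad) and translation offset (mm)
pose_from_chart <- function(par, anchor) {
  rigid_pose(quat_multiply(rotvec_to_quat(par[4:6]), anchor$q),
             anchor$t + par[1:3], anchor$frame, anchor$tracked)
}

# pixel window around the projected bone bounding box; held fixed across the
# simplex evaluations of one keyframe so the cost stays continuous
bone_roi <- function(bone, pose, camera, pad) {
  uv <- project_points(camera, posed_bbox_corners(bone, pose))
  w <- camera$image_size[1]; h <- camera$image_size[2]
  u0 <- max(0, floor(min(uv[, 1])) - pad)
  u1 <- min(w - 1, ceiling(max(uv[, 1])) + pad)
  v0 <- max(0, floor(min(uv[, 2])) - pad)
  v1 <- min(h - 1, ceiling(max(uv[, 2])) + pad)
  if (u1 <= u0 || v1 <= v0) return(NULL)
  list(u0 = as.integer(u0), v0 = as.integer(v0),
       width = as.integer(u1 - u0 + 1), height = as.integer(v1 - v0 + 1))
}

# DRR restricted to a pixel window
render_drr_roi <- function(bone, pose, camera, roi, step) {
  R <- quat_to_matrix(pose$q)
  t_eff <- pose$t + as.numeric(R %*% bone$origin)
  .drr_render_cpp(bone$volume, bone$voxel_spacing, R, t_eff,
                  camera_center(camera), camera_ray_matrix(camera),
                  roi$width, roi$height, step, roi$u0, roi$v0)
}

# two-view cost: 1 - mean NCC; empty DRRs score as worst (ncc -1)
# rois/crops: optional precomputed pixel windows and cropped captured images
two_view_cost <- function(bone, pose, images, cameras, cfg, rois = NULL) {
  scores <- vapply(seq_along(cameras), function(ci) {
    if (is.null(rois)) {
      d <- render_drr(bone, pose, cameras[[ci]], step = cfg$step_mm)
      cap <- images[[ci]]
    } else {
      d <- render_drr_roi(bone, pose, cameras[[ci]], rois[[ci]],
                          cfg$step_mm)
      cap <- images[[ci]]  # already cropped by the caller
    }
    if (all(d == 0)) return(-1)
    ncc(cap, d, mask_dilate_px = cfg$mask_dilate_px)
  }, numeric(1))
  1 - mean(scores)
}

#' Optimize one bone's pose against a two-view frame
#'
#' @param bone a \code{phantom_bone}.
#' @param images list of two image matrices (one per view).
#' @param cameras list of two \code{camera_model}s.
#' @param init initial \code{rigid_pose}; must project into at least one
#'   view.
#' @param cfg a \code{tracking_config}.
#' @return list: \code{pose} (optimized \code{rigid_pose}), \code{cost}
#'   (final \code{1 - mean(NCC)}), \code{convergence}.
#' @export
optimize_pose <- function(bone, images, cameras, init,
                          cfg = tracking_config()) {
  both_out <- all(vapply(cameras, function(cam) {
    bone_out_of_view(bone, init, cam)
  }, logical(1)))
  if (both_out) {
    stop("initial pose of bone '", bone$name,
         "' projects outside both views; tracking cannot start")
  }
  # fixed pixel windows around the initial projection keep the cost cheap
  # and continuous; the pad leaves room for the pose to move several mm
  pad <- cfg$mask_dilate_px + 15
  rois <- lapply(cameras, function(cam) bone_roi(bone, init, cam, pad))
  crops <- images
  use_roi <- !any(vapply(rois, is.null, logical(1)))
  if (use_roi) {
    crops <- lapply(seq_along(images), function(ci) {
      r <- rois[[ci]]
      images[[ci]][r$v0 + seq_len(r$height), r$u0 + seq_len(r$width)]
    })
  } else {
    rois <- NULL
  }
  fn <- function(par) two_view_cost(bone, pose_from_chart(par, init),
                                    crops, cameras, cfg, rois)
  # simplex restarts with shrinking scale refine past the first basin
  par <- rep(0, 6)
  value <- fn(par)
  for (shrink in c(1, 0.2, 0.05)) {
    opt <- stats::optim(par, fn, method = "Nelder-Mead",
                        control = list(
                          maxit = cfg$max_iter, reltol = cfg$cost_tol,
                          parscale = c(rep(cfg$trans_scale * shrink, 3),
                                       rep(cfg$rot_scale * shrink, 3))))
    if (opt$value < value) {
      par <- opt$par
      value <- opt$value
    }
  }
  opt <- list(par = par, value = value, convergence = 0L)
  best <- pose_from_chart(opt$par, init)
  if (all(vapply(cameras, function(cam) bone_out_of_view(bone, best, cam),
                 logical(1)))) {
    stop("optimizer left both view frustums for bone '", bone$name, "'")
  }
  list(pose = best, cost = opt$value, convergence = opt$convergence)
}

#' Quaternion (squad) spline through keyframe poses
#'
#' C1 spherical interpolation passing exactly through the keyframes;
#' translations are interpolated with a cubic spline.
#'
#' @param keyframes list of \code{rigid_pose}s with distinct, increasing
#'   \code{frame} indices (>= 2 of them).
#' @param frames target frame indices (must lie within the keyframe span).
#' @return list of \code{rigid_pose}s, one per requested frame.
#' @export
quaternion_spline <- function(keyframes, frames) {
  kf <- vapply(keyframes, function(p) as.numeric(p$frame), numeric(1))
  if (anyDuplicated(kf)) stop("duplicate keyframe indices")
  o <- order(kf); kf <- kf[o]; keyframes <- keyframes[o]
  m <- length(kf)
  if (m < 2) stop("need at least 2 keyframes")
  Q <- quat_hemisphere_align(t(vapply(keyframes, `[[`, numeric(4), "q")))
  Tr <- t(vapply(keyframes, `[[`, numeric(3), "t"))
  # squad control points
  S <- Q
  if (m > 2) {
    for (i in 2:(m - 1)) {
      qi_inv <- quat_conjugate(Q[i, ])
      la <- quat_log(quat_multiply(qi_inv, Q[i - 1, ]))
      lb <- quat_log(quat_multiply(qi_inv, Q[i + 1, ]))
      S[i, ] <- quat_multiply(Q[i, ], quat_exp(-(la + lb) / 4))
    }
  }
  tx <- stats::splinefun(kf, Tr[, 1], method = "natural")
  ty <- stats::splinefun(kf, Tr[, 2], method = "natural")
  tz <- stats::splinefun(kf, Tr[, 3], method = "natural")
  lapply(frames, function(f) {
    if (f < kf[1] || f > kf[m]) stop("frame ", f, " outside keyframe span")
    i <- findInterval(f, kf, rightmost.closed = TRUE)
    i <- min(i, m - 1)
    u <- (f - kf[i]) / (kf[i + 1] - kf[i])
    q <- if (u == 0) Q[i, ] else if (u == 1) Q[i + 1, ] else {
      e1 <- quat_slerp(Q[i, ], Q[i + 1, ], u)
      e2 <- quat_slerp(S[i, ], S[i + 1, ], u)
      quat_slerp(e1, e2, 2 * u * (1 - u))
    }
    rigid_pose(q, c(tx(f), ty(f), tz(f)), frame = f)
  })
}

#' Track one bone across a two-view image sequence
#'
#' @param bone a \code{phantom_bone}.
#' @param image_stacks list of two stacks (lists of image matrices), equal
#'   length.
#' @param cameras list of two \code{camera_model}s.
#' @param init initial \code{rigid_pose} for the first frame.
#' @param cfg a \code{tracking_config}.
#' @param frame_rate Hz, carried into the returned trajectory.
#' @return a \code{pose_trajectory} with attribute \code{keyframes} (indices)
#'   and \code{keyframe_costs}.
#' @export
track_sequence <- function(bone, image_stacks, cameras, init,
                           cfg = tracking_config(), frame_rate = 250) {
  n <- length(image_stacks[[1]])
  if (n == 0 || length(image_stacks[[2]]) != n) {
    stop("image stacks must be non-empty and equal length")
  }
  keys <- unique(c(seq(1, n, by = cfg$keyframe_stride), n))
  frame_imgs <- function(i) list(image_stacks[[1]][[i]],
                                 image_stacks[[2]][[i]])
  kposes <- vector("list", length(keys))
  kcosts <- numeric(length(keys))
  cur <- init
  for (k in seq_along(keys)) {
    res <- optimize_pose(bone, frame_imgs(keys[k]), cameras, cur, cfg)
    res$pose$frame <- as.integer(keys[k])
    kposes[[k]] <- res$pose
    kcosts[k] <- res$cost
    cur <- res$pose
  }
  # automated retracking: redo outlier keyframes from their neighbors
  if (length(keys) >= 3) {
    med <- stats::median(kcosts)
    bad <- which(kcosts > cfg$retrack_factor * med + 1e-9)
    for (k in bad) {
      nb <- if (k == 1) 2 else if (k == length(keys)) length(keys) - 1 else
        c(k - 1, k + 1)
      qn <- if (length(nb) == 2) {
        quat_slerp(kposes[[nb[1]]]$q, kposes[[nb[2]]]$q, 0.5)
      } else kposes[[nb]]$q
      tn <- if (length(nb) == 2) {
        (kposes[[nb[1]]]$t + kposes[[nb[2]]]$t) / 2
      } else kposes[[nb]]$t
      alt <- try(optimize_pose(bone, frame_imgs(keys[k]), cameras,
                               rigid_pose(qn, tn, keys[k]), cfg),
                 silent = TRUE)
      if (!inherits(alt, "try-error") && alt$cost < kcosts[k]) {
        alt$pose$frame <- as.integer(keys[k])
        kposes[[k]] <- alt$pose
        kcosts[k] <- alt$cost
      }
    }
  }
  all_poses <- if (length(keys) >= 2) {
    quaternion_spline(kposes, seq_len(n))
  } else rep(kposes, n)
  Q <- t(vapply(all_poses, `[[`, numeric(4), "q"))
  Tr <- t(vapply(all_poses, `[[`, numeric(3), "t"))
  tracked <- rep(TRUE, n)
  if (cfg$check_visibility) {
    for (i in seq_len(n)) {
      p <- rigid_pose(Q[i, ], Tr[i, ], i)
      out <- vapply(cameras, function(cam) bone_out_of_view(bone, p, cam),
                    logical(1))
      if (any(out)) tracked[i] <- FALSE
    }
  }
  traj <- pose_trajectory(bone$name, Q, Tr, frame_rate, tracked = tracked)
  attr(traj, "keyframes") <- keys
  attr(traj, "keyframe_costs") <- kcosts
  traj
}

#' Zero-phase Butterworth filtering of a pose trajectory
#'
#' Dual-pass (forward-backward) 2nd-order low-pass applied component-wise to
#' the hemisphere-aligned quaternions (renormalized afterwards) and to the
#' translations. Untracked gaps split the series; each contiguous tracked
#' run of at least 13 frames is filtered independently, shorter runs are
#' passed through unfiltered.
#'
#' @param traj a \code{pose_trajectory}.
#' @param cutoff_hz cutoff frequency, Hz (must be below Nyquist).
#' @return filtered \code{pose_trajectory}.
#' @export
filter_poses <- function(traj, cutoff_hz = 10) {
  if (cutoff_hz >= traj$frame_rate / 2) {
    stop("cutoff must be below the Nyquist frequency")
  }
  runs <- split(seq_len(n_frames(traj)),
                cumsum(c(TRUE, diff(traj$tracked) != 0)))
  runs <- Filter(function(ix) traj$tracked[ix[1]], runs)
  if (!any(vapply(runs, length, integer(1)) >= 13)) {
    stop("need at least 13 contiguous tracked frames to filter")
  }
  bf <- signal::butter(2, cutoff_hz / (traj$frame_rate / 2))
  Q <- traj$Q; Tr <- traj$Tr
  for (ix in runs) {
    if (length(ix) < 13) next
    Qr <- quat_hemisphere_align(Q[ix, , drop = FALSE])
    for (j in 1:4) Qr[, j] <- filtfilt_refl(bf, Qr[, j])
    Q[ix, ] <- quat_normalize(Qr)
    for (j in 1:3) Tr[ix, j] <- filtfilt_refl(bf, Tr[ix, j])
  }
  pose_trajectory(traj$bone, Q, Tr, traj$frame_rate, traj$tracked,
                  traj$frames)
}
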