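#' Rigid poses and pose trajectories
#'
#' A rigid pose maps a bone's local frame into the global frame:
#' \code{world = R \%*\% local + t}, with the rotation stored as a unit
#' quaternion (wxyz) and the translation in millimetres. A pose trajectory is
#' one pose per frame with per-frame tracked flags.
#'
#' @name poses
NULL

#' Construct a rigid pose
#' @param q unit quaternion, wxyz.
#' @param t translation, mm.
#' @param frame frame index (1-based).
#' @param tracked logical; untracked poses are ignored downstream.
#' @export
rigid_pose <- function(q = c(1, 0, 0, 0), t = c(0, 0, 0), frame = 1L,
                       tracked = TRUE) {
  q <- quat_normalize(as.numeric(q))
  stopifnot(length(t) == 3)
  structure(list(q = q, t = as.numeric(t), frame = as.integer(frame),
                 tracked = isTRUE(tracked)),
            class = "rigid_pose")
}

#' Apply a pose to local points
#' @param pose a \code{rigid_pose}.
#' @param pts n x 3 matrix (or length-3 vector) of local coordinates, mm.
#' @return points in the global frame, same shape.
#' @export
pose_apply <- function(pose, pts) {
  R <- quat_to_matrix(pose$q)
  if (is.matrix(pts)) {
    sweep(pts %*% t(R), 2, -pose$t)
  } else {
    as.numeric(R %*% pts + pose$t)
  }
}

#' Invert a pose
#' @param pose a \code{rigid_pose}.
#' @export
pose_inverse <- function(pose) {
  qi <- quat_conjugate(pose$q)
  Ri <- quat_to_matrix(qi)
  rigid_pose(qi, -as.numeric(Ri %*% pose$t), pose$frame, pose$tracked)
}

#' Compose two poses: (a o b)(x) = a(b(x))
#' @param a,b \code{rigid_pose} objects.
#' @export
pose_compose <- function(a, b) {
  q <- quat_normalize(quat_multiply(a$q, b$q))
  Ra <- quat_to_matrix(a$q)
  rigid_pose(q, as.numeric(Ra %*% b$t + a$t), b$frame,
             a$tracked && b$tracked)
}

#' Construct a pose trajectory
#' @param bone bone label.
#' @param Q n x 4 matrix of unit quaternions (wxyz), hemisphere-aligned on
#'   construction.
#' @param Tr n x 3 matrix of translations, mm.
#' @param frame_rate sampling rate, Hz.
#' @param tracked logical vector of length n (default all TRUE).
#' @param frames frame indices (default 1..n).
#' @export
pose_trajectory <- function(bone, Q, Tr, frame_rate,
                            tracked = rep(TRUE, nrow(Q)),
                            frames = seq_len(nrow(Q))) {
  Q <- quat_normalize(as.matrix(Q))
  Tr <- as.matrix(Tr)
  stopifnot(ncol(Q) == 4, ncol(Tr) == 3, nrow(Q) == nrow(Tr),
            length(tracked) == nrow(Q), frame_rate > 0)
  if (any(diff(frames) <= 0)) stop("frames must be strictly increasing")
  Q <- quat_hemisphere_align(Q)
  structure(list(bone = bone, Q = Q, Tr = Tr,
                 frame_rate = frame_rate, tracked = as.logical(tracked),
                 frames = as.integer(frames)),
            class = "pose_trajectory")
}

#' Number of frames in a pose trajectory
#' @param traj a \code{pose_trajectory}.
#' @export
n_frames <- function(traj) nrow(traj$Q)

#' Extract one frame of a trajectory as a rigid pose
#' @param traj a \code{pose_trajectory}.
#' @param i row index.
#' @export
traj_pose <- function(traj, i) {
  rigid_pose(traj$Q[i, ], traj$Tr[i, ], traj$frames[i], traj$tracked[i])
}

#' Per-frame pose error against a reference trajectory
#'
#' @param traj,ref \code{pose_trajectory} objects over the same frames.
#' @return list with per-frame \code{trans_mm} and \code{rot_deg} errors
#'   (frames tracked in both), and their RMS values.
#' @export
trajectory_error <- function(traj, ref) {
  stopifnot(n_frames(traj) == n_frames(ref))
  ok <- traj$tracked & ref$tracked
  te <- sqrt(rowSums((traj$Tr - ref$Tr)^2))[ok]
  re <- vapply(which(ok), function(i) {
    quat_angle(traj$Q[i, ], ref$Q[i, ]) * 180 / pi
  }, numeric(1))
  list(trans_mm = te, rot_deg = re,
       rms_trans_mm = sqrt(mean(te^2)), rms_rot_deg = sqrt(mean(re^2)))
}
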