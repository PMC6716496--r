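#' Co-registration and virtual markers
#'
#' Rigid-body point-set registration (SVD orthogonal Procrustes with a
#' reflection guard) co-registers the x-ray and optical coordinate systems
#' from paired bead/marker positions; virtual markers are points fixed in a
#' bone's local frame, seeded from a static trial and replayed through the
#' tracked bone poses.
#'
#' @name registration
NULL

#' Construct a rigid transform
#' @param R 3x3 proper rotation matrix.
#' @param t length-3 translation, mm.
#' @param fit_rms RMS fit residual, mm (0 for exact transforms).
#' @export
rigid_transform <- function(R, t = c(0, 0, 0), fit_rms = 0) {
  R <- as.matrix(R)
  if (max(abs(t(R) %*% R - diag(3))) > 1e-6 || det(R) < 0) {
    stop("R must be a proper rotation matrix")
  }
  structure(list(R = R, t = as.numeric(t), fit_rms = fit_rms),
            class = "rigid_transform")
}

#' Least-squares rigid fit between paired point sets
#'
#' Finds the rotation and translation minimizing
#' \code{sum(|R a_i + t - b_i|^2)} by SVD of the cross-covariance, with the
#' determinant sign corrected so a proper rotation (never a reflection) is
#' returned.
#'
#' @param points_a,points_b n x 3 paired point sets (n >= 3, not collinear).
#' @return a \code{rigid_transform} mapping \code{points_a} onto
#'   \code{points_b}, with \code{fit_rms} in mm.
#' @export
rigid_fit <- function(points_a, points_b) {
  A <- as.matrix(points_a); B <- as.matrix(points_b)
  if (nrow(A) < 3 || nrow(B) != nrow(A)) {
    stop("need at least 3 paired points")
  }
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  sv <- svd(Ac)$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) stop("points are collinear")
  H <- t(Ac) %*% Bc
  dec <- svd(H)
  D <- diag(c(1, 1, sign(det(dec$v %*% t(dec$u)))))
  R <- dec$v %*% D %*% t(dec$u)
  t <- cb - as.numeric(R %*% ca)
  resid <- sweep(A %*% t(R), 2, -t) - B
  rigid_transform(R, t, fit_rms = sqrt(mean(rowSums(resid^2))))
}

#' Invert a rigid transform
#' @param tf a \code{rigid_transform}.
#' @export
transform_inverse <- function(tf) {
  rigid_transform(t(tf$R), -as.numeric(t(tf$R) %*% tf$t), tf$fit_rms)
}

#' Apply a rigid transform to points
#' @param tf a \code{rigid_transform}.
#' @param pts n x 3 matrix or length-3 vector.
#' @export
transform_points <- function(tf, pts) {
  if (is.matrix(pts)) sweep(pts %*% t(tf$R), 2, -tf$t)
  else as.numeric(tf$R %*% pts + tf$t)
}

#' Co-register data into the optical frame
#'
#' Composes every position/orientation with the transform. Methods exist for
#' pose trajectories, marker sets and bare point matrices; the operation is
#' exactly invertible via \code{transform_inverse}.
#'
#' @param x a \code{pose_trajectory}, \code{marker_set} or n x 3 matrix.
#' @param tf a \code{rigid_transform}.
#' @return same type as \code{x}, expressed in the target frame.
#' @export
coregister <- function(x, tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  if (inherits(x, "pose_trajectory")) {
    qT <- matrix_to_quat(tf$R)
    Q <- t(apply(x$Q, 1, function(q) quat_multiply(qT, q)))
    Tr <- sweep(x$Tr %*% t(tf$R), 2, -tf$t)
    return(pose_trajectory(x$bone, Q, Tr, x$frame_rate, x$tracked, x$frames))
  }
  if (inherits(x, "marker_set")) {
    pos <- x$pos
    for (m in x$names) pos[, , m] <- transform_points(tf, pos[, , m])
    return(marker_set(pos, x$frame_rate, x$occluded))
  }
  if (is.matrix(x)) return(transform_points(tf, x))
  if (inherits(x, "rigid_pose")) {
    return(rigid_pose(quat_multiply(matrix_to_quat(tf$R), x$q),
                      transform_points(tf, x$t), x$frame, x$tracked))
  }
  stop("cannot co-register objects of class ", paste(class(x), collapse = "/"))
}

#' Seed virtual markers from a static trial
#'
#' Expresses each static marker in the local frame of its parent bone:
#' \code{local = pose^-1 (marker)}. Replaying the definitions at the static
#' poses reproduces the static markers exactly.
#'
#' @param static_markers single-frame \code{marker_set} (co-registered frame).
#' @param static_poses named list of \code{rigid_pose} per bone at the static
#'   trial.
#' @param assignment named character vector marker -> bone (default the
#'   Rizzoli segment map).
#' @return data.frame (marker, bone, lx, ly, lz): the virtual marker
#'   definitions.
#' @export
seed_virtual_markers <- function(static_markers, static_poses,
                                 assignment = rizzoli_marker_map()) {
  M <- marker_frame(static_markers, 1)
  defs <- lapply(rownames(M), function(m) {
    bone <- assignment[m]
    if (is.na(bone)) stop("marker ", m, " has no bone assignment")
    if (is.null(static_poses[[bone]])) {
      stop("no static pose for bone ", bone, " (marker ", m, ")")
    }
    local <- pose_apply(pose_inverse(static_poses[[bone]]), M[m, ])
    data.frame(marker = m, bone = unname(bone), lx = local[1],
               ly = local[2], lz = local[3], stringsAsFactors = FALSE)
  })
  do.call(rbind, defs)
}

#' Replay virtual markers through bone pose trajectories
#'
#' \code{marker(t) = pose_bone(t) (local)}; frames where the parent bone is
#' untracked become occlusion gaps.
#'
#' @param defs virtual marker definitions from \code{seed_virtual_markers}.
#' @param trajectories named list of \code{pose_trajectory} per bone.
#' @return a \code{marker_set}.
#' @export
replay_virtual_markers <- function(defs, trajectories) {
  n <- n_frames(trajectories[[1]])
  fr <- trajectories[[1]]$frame_rate
  nm <- defs$marker
  pos <- array(0, c(n, 3, length(nm)),
               dimnames = list(NULL, c("X", "Y", "Z"), nm))
  occ <- matrix(FALSE, n, length(nm), dimnames = list(NULL, nm))
  for (r in seq_len(nrow(defs))) {
    tr <- trajectories[[defs$bone[r]]]
    if (is.null(tr)) stop("no trajectory for bone ", defs$bone[r])
    local <- c(defs$lx[r], defs$ly[r], defs$lz[r])
    for (i in seq_len(n)) {
      if (!tr$tracked[i]) {
        occ[i, r] <- TRUE
        next
      }
      pos[i, , r] <- quat_to_matrix(tr$Q[i, ]) %*% local + tr$Tr[i, ]
    }
  }
  marker_set(pos, fr, occ)
}
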