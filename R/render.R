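#' Radiograph rendering
#'
#' Forward model for the captured x-rays: each pixel of a digitally
#' reconstructed radiograph (DRR) is the line integral of the posed
#' attenuation volume along the ray from the x-ray source through that
#' pixel, sampled trilinearly at a fixed step. Scenes sum the DRRs of all
#' bones; optional additive Gaussian pixel noise emulates detector noise.
#'
#' @name render
NULL

# world-frame corners of a bone's volume bounding box under a pose
posed_bbox_corners <- function(bone, pose) {
  ext <- (dim(bone$volume) - 1) * bone$voxel_spacing
  corners <- as.matrix(expand.grid(x = c(0, ext[1]), y = c(0, ext[2]),
                                   z = c(0, ext[3])))
  corners <- sweep(corners, 2, -bone$origin)
  pose_apply(pose, corners)
}

# TRUE when the projected bounding box misses the detector entirely
bone_out_of_view <- function(bone, pose, camera) {
  uv <- project_points(camera, posed_bbox_corners(bone, pose))
  w <- camera$image_size[1]; h <- camera$image_size[2]
  all(uv[, 1] < 0) || all(uv[, 1] > w - 1) ||
    all(uv[, 2] < 0) || all(uv[, 2] > h - 1)
}

#' Render the DRR of one bone
#'
#' @param bone a \code{phantom_bone}.
#' @param pose a \code{rigid_pose} (bone local frame -> world).
#' @param camera a \code{camera_model}.
#' @param step ray-marching step, mm.
#' @return height x width image matrix; attribute \code{out_of_view} is TRUE
#'   (and the image all-zero) when the bone misses the detector entirely.
#' @export
render_drr <- function(bone, pose, camera, step = 1.0) {
  stopifnot(inherits(bone, "phantom_bone"), inherits(pose, "rigid_pose"))
  w <- camera$image_size[1]; h <- camera$image_size[2]
  if (bone_out_of_view(bone, pose, camera)) {
    img <- matrix(0, h, w)
    attr(img, "out_of_view") <- TRUE
    return(img)
  }
  R <- quat_to_matrix(pose$q)
  # C++ kernel marches in grid coordinates anchored at voxel (1,1,1):
  # world = R (origin + grid) + t = R grid + (t + R origin)
  t_eff <- pose$t + as.numeric(R %*% bone$origin)
  img <- .drr_render_cpp(bone$volume, bone$voxel_spacing, R, t_eff,
                         camera_center(camera), camera_ray_matrix(camera),
                         w, h, step)
  attr(img, "out_of_view") <- FALSE
  img
}

# DRR of a multi-bone scene at one frame (poses: named list of rigid_pose)
render_scene <- function(bones, poses, camera, step = 1.0) {
  img <- matrix(0, camera$image_size[2], camera$image_size[1])
  for (b in bones) {
    d <- render_drr(b, poses[[b$name]], camera, step)
    img <- img + d
  }
  img
}

#' Render the two radiograph stacks of a trial
#'
#' @param bones named list of \code{phantom_bone}s (may be empty).
#' @param poses named list of \code{pose_trajectory}, one per bone, all on
#'   the same frame grid.
#' @param cameras list of two \code{camera_model}s.
#' @param step ray-marching step, mm.
#' @param noise_sd additive Gaussian pixel noise SD (same units as the line
#'   integrals); 0 disables noise.
#' @param seed seed for the noise stream.
#' @return list: \code{stacks} (per camera, a list of image matrices),
#'   \code{visible} (array frames x bones x cameras of in-view flags).
#' @export
render_trial_images <- function(bones, poses, cameras, step = 1.0,
                                noise_sd = 0, seed = 1L) {
  n <- if (length(bones)) n_frames(poses[[bones[[1]]$name]]) else
    if (length(poses)) n_frames(poses[[1]]) else 1L
  rnorm_fun <- if (noise_sd > 0) make_rng_norm(seed, "pixels") else NULL
  visible <- array(TRUE, c(n, max(1, length(bones)), length(cameras)),
                   dimnames = list(NULL,
                                   if (length(bones)) names(bones) else "none",
                                   vapply(cameras, `[[`, "", "id")))
  stacks <- lapply(seq_along(cameras), function(ci) {
    cam <- cameras[[ci]]
    lapply(seq_len(n), function(i) {
      img <- matrix(0, cam$image_size[2], cam$image_size[1])
      for (bi in seq_along(bones)) {
        b <- bones[[bi]]
        d <- render_drr(b, traj_pose(poses[[b$name]], i), cam, step)
        if (isTRUE(attr(d, "out_of_view"))) visible[i, b$name, ci] <<- FALSE
        img <- img + d
      }
      if (!is.null(rnorm_fun)) {
        img <- img + noise_sd * matrix(rnorm_fun(length(img)), nrow(img))
      }
      img
    })
  })
  names(stacks) <- vapply(cameras, `[[`, "", "id")
  list(stacks = stacks, visible = visible)
}
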