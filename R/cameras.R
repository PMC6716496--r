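#' Camera models for the biplanar x-ray rig
#'
#' A camera is a 3x4 projective matrix mapping world millimetres to
#' homogeneous pixel coordinates, plus the detector size and an optional
#' distortion map. The synthetic rig places two source/detector pairs as
#' lateral-oblique views separated by 130 degrees about the global vertical
#' axis, mirroring a standard biplanar videoradiography layout.
#'
#' @name cameras
NULL

#' Construct a camera model
#' @param projection 3x4 matrix, world mm -> homogeneous pixels.
#' @param image_size c(width, height) in pixels.
#' @param id camera label.
#' @param distortion optional distortion map (see \code{fit_undistortion}).
#' @export
camera_model <- function(projection, image_size, id = "cam",
                         distortion = NULL) {
  projection <- as.matrix(projection)
  stopifnot(all(dim(projection) == c(3, 4)), length(image_size) == 2)
  if (qr(projection)$rank < 3) stop("projection matrix must have rank 3")
  structure(list(projection = projection,
                 image_size = as.integer(image_size),
                 id = id, distortion = distortion),
            class = "camera_model")
}

#' Build a perspective camera from an orbit specification
#'
#' The source sits at \code{distance} mm from \code{target}, at the given
#' azimuth about the global vertical (Z) axis and elevation above the
#' horizontal plane; the optical axis points at the target.
#'
#' @param azimuth_deg azimuth about +Z, degrees (0 = looking from +X).
#' @param target 3-vector, mm; the point the camera looks at.
#' @param distance source-to-target distance, mm.
#' @param focal_px focal length in pixels.
#' @param image_size c(width, height) pixels.
#' @param elevation_deg elevation of the source above the horizontal, degrees.
#' @param id camera label.
#' @export
make_camera <- function(azimuth_deg, target = c(30, 0, 60), distance = 600,
                        focal_px = 320, image_size = c(128, 128),
                        elevation_deg = 15, id = "cam") {
  az <- azimuth_deg * pi / 180
  el <- elevation_deg * pi / 180
  src <- target + distance * c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
  zc <- (target - src) / sqrt(sum((target - src)^2))   # optical axis
  up <- c(0, 0, 1)
  xc <- pracma_cross(zc, up)
  if (sqrt(sum(xc^2)) < 1e-9) stop("camera looking straight down the vertical")
  xc <- xc / sqrt(sum(xc^2))
  yc <- pracma_cross(zc, xc)
  R <- rbind(xc, yc, zc)                               # world -> camera
  K <- matrix(c(focal_px, 0, (image_size[1] - 1) / 2,
                0, focal_px, (image_size[2] - 1) / 2,
                0, 0, 1), 3, 3, byrow = TRUE)
  P <- K %*% cbind(R, -R %*% src)
  camera_model(P, image_size, id = id)
}

# cross product (kept local; avoids pulling a dependency for one primitive)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' The standard two-view biplanar rig
#' @param separation_deg angular separation of the imaging planes about the
#'   global vertical axis (default 130).
#' @param ... passed to \code{make_camera}.
#' @return list of two \code{camera_model}s.
#' @export
make_bvr_cameras <- function(separation_deg = 130, ...) {
  half <- separation_deg / 2
  list(make_camera(azimuth_deg = -half, id = "cam1", ...),
       make_camera(azimuth_deg = +half, id = "cam2", ...))
}

#' Project world points to pixel coordinates
#' @param camera a \code{camera_model}.
#' @param pts n x 3 matrix or length-3 vector, world mm.
#' @return n x 2 matrix of (u, v) pixels (zero-based pixel centers).
#' @export
project_points <- function(camera, pts) {
  if (!is.matrix(pts)) pts <- matrix(pts, nrow = 1)
  X <- cbind(pts, 1)
  h <- X %*% t(camera$projection)
  h[, 1:2, drop = FALSE] / h[, 3]
}

#' Camera center (x-ray source position) in world coordinates
#' @param camera a \code{camera_model}.
#' @export
camera_center <- function(camera) {
  M <- camera$projection[, 1:3]
  as.numeric(-solve(M, camera$projection[, 4]))
}

#' Inverse of the left 3x3 projection block
#'
#' Maps homogeneous pixel coordinates to world ray directions from the
#' camera center; used by the DRR renderer.
#' @param camera a \code{camera_model}.
#' @export
camera_ray_matrix <- function(camera) solve(camera$projection[, 1:3])
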