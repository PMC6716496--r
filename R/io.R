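#' On-disk artifact formats
#'
#' Radiograph stacks as multi-page TIFF (one file per camera, float samples
#' scaled by a sidecar factor), markers as wide CSV (frame, time_s, then
#' X/Y/Z per marker), poses as CSV (frame, qw..qz, tx..tz, tracked), and
#' cameras / rigid transforms / synchronization results as JSON.
#'
#' @name io
NULL

#' Write a radiograph stack as multi-page TIFF
#'
#' Pixel values are scaled into [0, 1] by the stack maximum; the scale is
#' returned (and stored in a JSON sidecar) so intensities round-trip.
#' @param stack list of image matrices.
#' @param path output .tif path.
#' @return the scale factor, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  mx <- max(1e-12, max(vapply(stack, max, numeric(1))))
  tiff::writeTIFF(lapply(stack, function(im) im / mx), path,
                  bits.per.sample = 16L)
  jsonlite::write_json(list(scale = mx, n = length(stack)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(mx)
}

#' Read a radiograph stack written by \code{write_image_stack}
#' @param path .tif path.
#' @return list of image matrices.
#' @export
read_image_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  imgs <- tiff::readTIFF(path, all = TRUE)
  lapply(imgs, function(im) im * meta$scale)
}

#' Write a marker set as wide CSV
#' @param markers a \code{marker_set}.
#' @param path output .csv path.
#' @export
write_marker_csv <- function(markers, path) {
  n <- dim(markers$pos)[1]
  df <- data.frame(frame = seq_len(n),
                   time_s = (seq_len(n) - 1) / markers$frame_rate)
  for (m in markers$names) {
    xyz <- markers$pos[, , m, drop = FALSE]
    dim(xyz) <- c(n, 3)
    xyz[markers$occluded[, m], ] <- NA
    df[[paste0(m, "_X")]] <- xyz[, 1]
    df[[paste0(m, "_Y")]] <- xyz[, 2]
    df[[paste0(m, "_Z")]] <- xyz[, 3]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a marker CSV written by \code{write_marker_csv}
#' @param path .csv path.
#' @return a \code{marker_set}.
#' @export
read_marker_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  cols <- setdiff(names(df), c("frame", "time_s"))
  nm <- unique(sub("_[XYZ]$", "", cols))
  n <- nrow(df)
  fr <- if (n > 1) 1 / diff(df$time_s[1:2]) else 250
  pos <- array(0, c(n, 3, length(nm)),
               dimnames = list(NULL, c("X", "Y", "Z"), nm))
  occ <- matrix(FALSE, n, length(nm), dimnames = list(NULL, nm))
  for (m in nm) {
    xyz <- as.matrix(df[paste0(m, c("_X", "_Y", "_Z"))])
    occ[, m] <- apply(is.na(xyz), 1, any)
    xyz[is.na(xyz)] <- 0
    pos[, , m] <- xyz
  }
  marker_set(pos, round(fr, 6), occ)
}

#' Write a pose trajectory as CSV
#' @param traj a \code{pose_trajectory}.
#' @param path output .csv path.
#' @export
write_pose_csv <- function(traj, path) {
  df <- data.frame(frame = traj$frames,
                   qw = traj$Q[, 1], qx = traj$Q[, 2], qy = traj$Q[, 3],
                   qz = traj$Q[, 4],
                   tx = traj$Tr[, 1], ty = traj$Tr[, 2], tz = traj$Tr[, 3],
                   tracked = traj$tracked)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a pose trajectory CSV
#' @param path .csv path.
#' @param bone bone label.
#' @param frame_rate Hz.
#' @export
read_pose_csv <- function(path, bone = "bone", frame_rate = 250) {
  df <- utils::read.csv(path)
  pose_trajectory(bone, as.matrix(df[c("qw", "qx", "qy", "qz")]),
                  as.matrix(df[c("tx", "ty", "tz")]), frame_rate,
                  tracked = df$tracked, frames = df$frame)
}

#' Write camera models as JSON
#' @param cameras list of \code{camera_model}s.
#' @param path output .json path.
#' @export
write_cameras_json <- function(cameras, path) {
  payload <- lapply(cameras, function(cam) {
    list(id = cam$id,
         projection = as.numeric(t(cam$projection)),  # row-major
         image_size = cam$image_size)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read camera models written by \code{write_cameras_json}
#' @param path .json path.
#' @export
read_cameras_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(payload)), function(i) {
    camera_model(matrix(unlist(payload$projection[i]), 3, 4, byrow = TRUE),
                 unlist(payload$image_size[i]), id = payload$id[i])
  })
}

#' Write a rigid transform as JSON
#' @param tf a \code{rigid_transform}.
#' @param path output .json path.
#' @export
write_transform_json <- function(tf, path) {
  jsonlite::write_json(list(R = as.numeric(t(tf$R)), t = tf$t,
                            fit_rms = tf$fit_rms),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rigid transform written by \code{write_transform_json}
#' @param path .json path.
#' @export
read_transform_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(p$R, 3, 3, byrow = TRUE), p$t, p$fit_rms)
}
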