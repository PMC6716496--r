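#' System calibration and synchronization
#'
#' Undistortion of the radiographs from a perforated-grid image, camera
#' calibration from the bead cube by normalized direct linear transformation
#' (DLT), and temporal alignment of the optical and radiographic systems
#' from dropped-marker trials.
#'
#' @name calibration
NULL

# full bivariate polynomial design matrix of the given degree
poly2d_design <- function(x, y, degree) {
  cols <- list()
  for (i in 0:degree) for (j in 0:(degree - i)) {
    cols[[length(cols) + 1]] <- x^i * y^j
  }
  do.call(cbind, cols)
}

poly2d_eval <- function(coef, x, y, degree) {
  A <- poly2d_design(x, y, degree)
  cbind(A %*% coef[, 1], A %*% coef[, 2])
}

# blob centroids of a grid image via threshold + connected components
detect_grid_holes <- function(img, min_px = 3) {
  thr <- 0.5 * max(img)
  if (max(img) <= 0) return(matrix(numeric(0), 0, 2))
  # EBImage images index [x, y]; transpose our [row = v, col = u] matrices
  lab <- EBImage::bwlabel(EBImage::Image(t(img > thr) * 1))
  n <- max(lab)
  if (n == 0) return(matrix(numeric(0), 0, 2))
  labv <- as.integer(EBImage::imageData(lab))
  w <- ncol(img); h <- nrow(img)
  ug <- rep(0:(w - 1), times = h)      # x index fastest in t(img)
  vg <- rep(0:(h - 1), each = w)
  wt <- as.numeric(t(img))
  keep <- labv > 0
  cx <- tapply(wt[keep] * ug[keep], labv[keep], sum) /
    tapply(wt[keep], labv[keep], sum)
  cy <- tapply(wt[keep] * vg[keep], labv[keep], sum) /
    tapply(wt[keep], labv[keep], sum)
  sz <- tabulate(labv[keep])
  cbind(cx, cy)[sz >= min_px, , drop = FALSE]
}

#' Fit a distortion map from an undistortion-grid image
#'
#' Detects the grid holes, matches each to its nearest ideal lattice
#' position, and fits bivariate polynomial displacement fields in both
#' directions (ideal -> observed and observed -> ideal).
#'
#' @param grid_image height x width image matrix.
#' @param grid_spec list with \code{ideal} (n x 2 ideal lattice positions,
#'   zero-based pixels) and \code{pitch}; as produced by
#'   \code{make_undistortion_grid}.
#' @param degree polynomial degree of the displacement model (default 3,
#'   reduced automatically if too few holes are detected).
#' @return a \code{distortion_map}: forward/inverse coefficients, degree,
#'   and the RMS residual (px) of the inverse fit on the grid.
#' @export
fit_undistortion <- function(grid_image, grid_spec, degree = 3) {
  det <- detect_grid_holes(grid_image)
  if (nrow(det) < 4) {
    stop("fewer than 4 grid holes detected; cannot fit a distortion map")
  }
  ideal <- grid_spec$ideal
  # match detected blobs to ideal positions (nearest neighbour; valid while
  # distortion is small relative to the pitch)
  nn <- apply(det, 1, function(p) {
    which.min((ideal[, 1] - p[1])^2 + (ideal[, 2] - p[2])^2)
  })
  if (anyDuplicated(nn)) {
    keep <- !duplicated(nn) & !duplicated(nn, fromLast = TRUE)
    det <- det[keep, , drop = FALSE]; nn <- nn[keep]
  }
  idl <- ideal[nn, , drop = FALSE]
  nterms <- function(d) (d + 1) * (d + 2) / 2
  while (degree > 1 && nrow(det) < nterms(degree)) degree <- degree - 1
  if (nrow(det) < nterms(degree)) stop("too few holes for the fit")
  fit_dir <- function(from, to, deg) {
    A <- poly2d_design(from[, 1], from[, 2], deg)
    qr.solve(A, to)
  }
  fwd <- fit_dir(idl, det, degree)    # ideal -> observed
  # the inverse is fit against the *fitted* forward map (two extra degrees,
  # data permitting), so forward-then-inverse closes to the inverse-fit
  # residual rather than to twice the detection noise
  inv_deg <- degree
  while (inv_deg < degree + 2 &&
         nrow(det) >= nterms(inv_deg + 1)) inv_deg <- inv_deg + 1
  fwd_on_grid <- poly2d_eval(fwd, idl[, 1], idl[, 2], degree)
  inv <- fit_dir(fwd_on_grid, idl, inv_deg)
  pred <- poly2d_eval(inv, det[, 1], det[, 2], inv_deg)
  resid <- sqrt(mean(rowSums((pred - idl)^2)))
  structure(list(forward = fwd, inverse = inv, degree = degree,
                 inverse_degree = inv_deg, residual = resid,
                 n_holes = nrow(det)),
            class = "distortion_map")
}

#' Apply a distortion map to pixel coordinates
#' @param map a \code{distortion_map}.
#' @param uv n x 2 pixel coordinates.
#' @param direction "inverse" (observed -> ideal, i.e. undistort; default)
#'   or "forward" (ideal -> observed).
#' @export
apply_distortion <- function(map, uv, direction = c("inverse", "forward")) {
  direction <- match.arg(direction)
  if (direction == "inverse") {
    poly2d_eval(map$inverse, uv[, 1], uv[, 2], map$inverse_degree)
  } else {
    poly2d_eval(map$forward, uv[, 1], uv[, 2], map$degree)
  }
}

#' Calibrate a camera from 3D-2D bead correspondences
#'
#' Normalized direct linear transformation: homogeneous least squares on the
#' 2n x 12 system, with Hartley normalization of both point sets.
#'
#' @param beads_3d n x 3 known bead positions, world mm (n >= 6, not all
#'   coplanar).
#' @param beads_2d n x 2 detected image positions, pixels.
#' @param image_size c(width, height) for the returned model.
#' @param id camera label.
#' @return a \code{camera_model} with attributes \code{reprojection_rms}
#'   (px).
#' @export
calibrate_camera <- function(beads_3d, beads_2d, image_size = c(128, 128),
                             id = "cam") {
  beads_3d <- as.matrix(beads_3d); beads_2d <- as.matrix(beads_2d)
  n <- nrow(beads_3d)
  if (n < 6 || nrow(beads_2d) != n) {
    stop("need >= 6 paired 3D-2D correspondences")
  }
  sv <- svd(scale(beads_3d, scale = FALSE))$d
  if (sv[3] < 1e-8 * sv[1]) {
    stop("bead set is (nearly) coplanar; calibration is degenerate")
  }
  # Hartley normalization
  c3 <- colMeans(beads_3d)
  s3 <- sqrt(3) / mean(sqrt(rowSums(sweep(beads_3d, 2, c3)^2)))
  T3 <- rbind(cbind(diag(3) * s3, -s3 * c3), c(0, 0, 0, 1))
  c2 <- colMeans(beads_2d)
  s2 <- sqrt(2) / mean(sqrt(rowSums(sweep(beads_2d, 2, c2)^2)))
  T2 <- rbind(cbind(diag(2) * s2, -s2 * c2), c(0, 0, 1))
  Xn <- cbind(beads_3d, 1) %*% t(T3)
  xn <- cbind(beads_2d, 1) %*% t(T2)
  A <- matrix(0, 2 * n, 12)
  for (i in seq_len(n)) {
    X <- Xn[i, ]
    A[2 * i - 1, ] <- c(X, rep(0, 4), -xn[i, 1] * X)
    A[2 * i, ] <- c(rep(0, 4), X, -xn[i, 2] * X)
  }
  p <- svd(A, nu = 0)$v[, 12]
  Pn <- matrix(p, 3, 4, byrow = TRUE)
  P <- solve(T2) %*% Pn %*% T3
  P <- P / sqrt(sum(P[3, 1:3]^2))
  proj <- cbind(beads_3d, 1) %*% t(P)
  uv <- proj[, 1:2] / proj[, 3]
  rms <- sqrt(mean(rowSums((uv - beads_2d)^2)))
  cam <- camera_model(P, image_size, id = id)
  attr(cam, "reprojection_rms") <- rms
  cam
}

# sub-frame position of the interior minimum of a series, by quadratic
# interpolation through the discrete minimum and its neighbours
subframe_minimum <- function(z) {
  i <- which.min(z)
  if (i == 1 || i == length(z)) {
    stop("series has no interior minimum")
  }
  y1 <- z[i - 1]; y2 <- z[i]; y3 <- z[i + 1]
  den <- y1 - 2 * y2 + y3
  if (den <= 0) return(i)
  i + 0.5 * (y1 - y3) / den
}

#' Estimate the temporal alignment between the two systems
#'
#' Each drop trial contributes one impact-time pair (sub-frame minima of the
#' vertical coordinate in both series). The frame offset is taken from trial
#' 1; the rate ratio is the least-squares slope of optical impact frames on
#' radiographic impact frames across trials.
#'
#' @param drop_trials list of trials, each \code{list(bvr =, omc =)} vertical
#'   coordinate series (>= 2 trials).
#' @return a \code{sync_result}: \code{frame_offset}, \code{rate_ratio},
#'   \code{anchor_bvr}, \code{anchor_omc}, and per-drop fit residuals
#'   (frames).
#' @export
estimate_sync <- function(drop_trials) {
  if (length(drop_trials) < 2) {
    stop("rate-ratio estimation needs at least 2 drop trials")
  }
  bvr <- vapply(drop_trials, function(tr) subframe_minimum(tr$bvr),
                numeric(1))
  omc <- vapply(drop_trials, function(tr) subframe_minimum(tr$omc),
                numeric(1))
  if (stats::var(bvr) < 1e-12) {
    ratio <- 1
    resid <- omc - bvr - (omc[1] - bvr[1])
  } else {
    fit <- stats::lm.fit(cbind(1, bvr), omc)
    ratio <- fit$coefficients[2]
    resid <- fit$residuals
  }
  if (!all(is.finite(resid))) stop("non-finite synchronization residuals")
  if (ratio <= 0) stop("estimated rate ratio is not positive")
  structure(list(frame_offset = omc[1] - bvr[1],
                 rate_ratio = as.numeric(ratio),
                 anchor_bvr = bvr[1], anchor_omc = omc[1],
                 residuals = as.numeric(resid)),
            class = "sync_result")
}

#' Identity synchronization (offset 0, ratio 1)
#' @export
sync_identity <- function() {
  structure(list(frame_offset = 0, rate_ratio = 1, anchor_bvr = 0,
                 anchor_omc = 0, residuals = numeric(0)),
            class = "sync_result")
}

#' Resample optical markers onto the radiographic time base
#'
#' Radiographic frame k maps to the (fractional) optical frame
#' \code{anchor_omc + rate_ratio * (k - anchor_bvr)}; positions are linearly
#' interpolated there. Frames mapping outside the optical record are marked
#' occluded.
#'
#' @param markers a \code{marker_set} sampled on the optical grid.
#' @param sync a \code{sync_result}.
#' @param n_frames number of radiographic frames to produce.
#' @return a \code{marker_set} on the radiographic grid.
#' @export
resample_to_bvr <- function(markers, sync, n_frames = dim(markers$pos)[1]) {
  stopifnot(inherits(sync, "sync_result"))
  n_omc <- dim(markers$pos)[1]
  k <- seq_len(n_frames)
  f_omc <- sync$anchor_omc + sync$rate_ratio * (k - sync$anchor_bvr)
  inside <- f_omc >= 1 & f_omc <= n_omc
  if (!any(inside)) stop("no overlap between the two time bases")
  nm <- markers$names
  pos <- array(NA_real_, c(n_frames, 3, length(nm)),
               dimnames = list(NULL, c("X", "Y", "Z"), nm))
  occ <- matrix(TRUE, n_frames, length(nm), dimnames = list(NULL, nm))
  for (m in nm) {
    vis <- !markers$occluded[, m]
    if (sum(vis) < 2) next
    for (ax in 1:3) {
      pos[inside, ax, m] <- stats::approx(which(vis),
                                          markers$pos[vis, ax, m],
                                          xout = f_omc[inside])$y
    }
    occ[, m] <- !inside | apply(is.na(pos[, , m, drop = FALSE]), 1, any)
  }
  pos[is.na(pos)] <- 0
  marker_set(pos, markers$frame_rate, occ)
}
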