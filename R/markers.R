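#' Marker trajectory sets
#'
#' Named 3D marker positions (mm) over frames at a known sampling rate, with
#' occlusion flags. Axes follow the global convention used throughout:
#' X anterior-posterior, Y medial-lateral, Z superior-inferior.
#'
#' @name markers
NULL

#' Construct a marker trajectory set
#' @param pos array \code{[frames, 3, markers]} of positions in mm, with
#'   marker names on the third dimension.
#' @param frame_rate sampling rate, Hz.
#' @param occluded logical \code{[frames, markers]} matrix (default none).
#' @export
marker_set <- function(pos, frame_rate, occluded = NULL) {
  stopifnot(length(dim(pos)) == 3, dim(pos)[2] == 3, frame_rate > 0)
  nms <- dimnames(pos)[[3]]
  if (is.null(nms) || anyDuplicated(nms)) {
    stop("markers must carry unique names on the third dimension")
  }
  if (is.null(occluded)) {
    occluded <- matrix(FALSE, dim(pos)[1], dim(pos)[3],
                       dimnames = list(NULL, nms))
  }
  stopifnot(all(dim(occluded) == dim(pos)[c(1, 3)]))
  vis <- !occluded
  for (m in seq_len(dim(pos)[3])) {
    if (any(!is.finite(pos[vis[, m], , m]))) {
      stop("non-finite position at an unoccluded frame for marker ", nms[m])
    }
  }
  structure(list(pos = pos, frame_rate = frame_rate,
                 occluded = occluded, names = nms),
            class = "marker_set")
}

#' Marker names of a set
#' @param ms a \code{marker_set}.
#' @export
marker_names <- function(ms) ms$names

#' One marker's trajectory as an n x 3 matrix
#' @param ms a \code{marker_set}.
#' @param name marker name.
#' @export
marker_xyz <- function(ms, name) {
  if (!name %in% ms$names) stop("unknown marker: ", name)
  ms$pos[, , name, drop = TRUE]
}

#' Subset a marker set by frame indices
#' @param ms a \code{marker_set}.
#' @param idx frame indices to keep.
#' @export
marker_subset_frames <- function(ms, idx) {
  marker_set(ms$pos[idx, , , drop = FALSE], ms$frame_rate,
             ms$occluded[idx, , drop = FALSE])
}

#' One frame of all markers as a named n x 3 matrix
#' @param ms a \code{marker_set}.
#' @param i frame index.
#' @param drop_occluded drop occluded markers (default TRUE).
#' @export
marker_frame <- function(ms, i, drop_occluded = TRUE) {
  M <- t(ms$pos[i, , ])
  rownames(M) <- ms$names
  if (drop_occluded) M <- M[!ms$occluded[i, ], , drop = FALSE]
  M
}
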