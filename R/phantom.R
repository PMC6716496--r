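#' Parametric bone phantoms carrying the Rizzoli marker landmarks
#'
#' Four voxel attenuation volumes (shank, calcaneus, navicular, metatarsal
#' segment) stand in for segmented CT bone volumes. Shapes are unions of
#' ellipsoids with deliberate asymmetries so all six pose degrees of freedom
#' are observable in a two-view radiograph. Each bone carries the landmarks
#' of the 14-marker Rizzoli multi-segment foot model that belong to its
#' segment: 3 on the shank (LtS, MdS, Shk), 4 on the calcaneus (SCR, ICR,
#' ST, PT), 1 on the navicular (TN) and 6 on the metatarsal segment (FMB,
#' SMB, VMB, FMH, SMH, VMH).
#'
#' @name phantom
NULL

#' Rizzoli marker-to-segment assignment
#'
#' Named character vector: marker name -> parent segment.
#' @export
rizzoli_marker_map <- function() {
  c(LtS = "shank", MdS = "shank", Shk = "shank",
    SCR = "calcaneus", ICR = "calcaneus", ST = "calcaneus", PT = "calcaneus",
    TN = "navicular",
    FMB = "metatarsal", SMB = "metatarsal", VMB = "metatarsal",
    FMH = "metatarsal", SMH = "metatarsal", VMH = "metatarsal")
}

# Anatomical rest-pose marker positions (world mm; X anterior-posterior,
# Y medial-lateral, Z superior-inferior; origin under the ankle at ground
# level). Single source of truth for phantom landmark placement.
rizzoli_rest_markers <- function() {
  rbind(
    LtS = c(0, -45, 110), MdS = c(0, 45, 110), Shk = c(0, 0, 70),
    SCR = c(-55, 0, 45), ICR = c(-57, 0, 20), ST = c(0, 30, 35),
    PT = c(-5, -30, 30),
    TN = c(35, 15, 40),
    FMB = c(60, 25, 30), SMB = c(65, 8, 32), VMB = c(60, -30, 25),
    FMH = c(120, 30, 20), SMH = c(125, 10, 22), VMH = c(115, -35, 15))
}

# Rest-pose volume centers per segment (world mm)
segment_rest_centers <- function() {
  rbind(shank = c(0, 0, 110), calcaneus = c(-30, 0, 35),
        navicular = c(35, 12, 40), metatarsal = c(90, 0, 25))
}

#' Construct a phantom bone
#' @param name segment label.
#' @param volume 3D non-negative attenuation array (mm^-1).
#' @param voxel_spacing mm per voxel along each axis.
#' @param landmarks named n x 3 matrix, local mm.
#' @param origin local-frame position of the center of voxel (1,1,1); the
#'   default centers the volume on the local origin.
#' @export
phantom_bone <- function(name, volume, voxel_spacing, landmarks,
                         origin = NULL) {
  stopifnot(length(dim(volume)) == 3, length(voxel_spacing) == 3)
  if (any(voxel_spacing <= 0)) stop("voxel_spacing must be > 0 on all axes")
  if (any(volume < 0)) stop("attenuation values must be >= 0")
  ext <- (dim(volume) - 1) * voxel_spacing
  if (is.null(origin)) origin <- -ext / 2
  lo <- origin; hi <- origin + ext
  bad <- apply(landmarks, 1, function(p) any(p < lo - 1e-9 | p > hi + 1e-9))
  if (any(bad)) {
    stop("landmark(s) outside the bone volume bounding box: ",
         paste(rownames(landmarks)[bad], collapse = ", "))
  }
  structure(list(name = name, volume = volume,
                 voxel_spacing = as.numeric(voxel_spacing),
                 origin = as.numeric(origin),
                 landmarks = as.matrix(landmarks)),
            class = "phantom_bone")
}

# add an ellipsoid of given attenuation to a voxel grid (local mm coords)
add_ellipsoid <- function(vol, spacing, origin, center, semi, value) {
  d <- dim(vol)
  x <- origin[1] + (seq_len(d[1]) - 1) * spacing[1]
  y <- origin[2] + (seq_len(d[2]) - 1) * spacing[2]
  z <- origin[3] + (seq_len(d[3]) - 1) * spacing[3]
  dx2 <- ((x - center[1]) / semi[1])^2
  dy2 <- ((y - center[2]) / semi[2])^2
  dz2 <- ((z - center[3]) / semi[3])^2
  inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
  vol[inside] <- vol[inside] + value
  vol
}

#' Default phantom configuration
#'
#' Per-segment grid sizes, voxel spacings and shape primitives. Volumes stay
#' at or below 96^3 voxels so DRR rendering remains desk-scale.
#' @export
phantom_config <- function() {
  list(
    shank = list(dim = c(36, 68, 68), spacing = c(1.5, 1.5, 1.5),
                 shapes = list(
                   list(center = c(0, 0, 10), semi = c(12, 14, 38), value = 0.025),
                   list(center = c(6, 10, -25), semi = c(7, 7, 12), value = 0.02),
                   list(center = c(-4, -16, 28), semi = c(6, 9, 8), value = 0.015))),
    calcaneus = list(dim = c(52, 52, 52), spacing = c(1.4, 1.4, 1.4),
                     shapes = list(
                       list(center = c(-5, 0, 0), semi = c(24, 14, 13), value = 0.03),
                       list(center = c(18, 14, -4), semi = c(10, 9, 7), value = 0.025),
                       list(center = c(-18, -6, 12), semi = c(8, 8, 10), value = 0.02))),
    navicular = list(dim = c(26, 26, 26), spacing = c(1.1, 1.1, 1.1),
                     shapes = list(
                       list(center = c(0, 0, 0), semi = c(10, 8, 6), value = 0.03),
                       list(center = c(4, 4, 3), semi = c(4, 4, 4), value = 0.02))),
    metatarsal = list(dim = c(58, 58, 26), spacing = c(1.4, 1.4, 1.4),
                      shapes = list(
                        list(center = c(0, 18, 0), semi = c(34, 6, 6), value = 0.03),
                        list(center = c(0, 0, 1), semi = c(32, 5, 5), value = 0.028),
                        list(center = c(-2, -22, -2), semi = c(30, 6, 6), value = 0.026),
                        list(center = c(-26, 0, 2), semi = c(9, 26, 7), value = 0.02)))
  )
}

#' Generate the four-bone phantom foot
#'
#' @param config shape configuration, see \code{phantom_config}.
#' @param seed integer seed; adds seeded small-amplitude attenuation texture
#'   so volumes are not piecewise-constant (helps the NCC cost distinguish
#'   in-plane rolls). Same seed, same config: bit-identical output.
#' @return named list of \code{phantom_bone}s (shank, calcaneus, navicular,
#'   metatarsal).
#' @export
make_phantom_foot <- function(config = phantom_config(), seed = 1L) {
  rest <- rizzoli_rest_markers()
  centers <- segment_rest_centers()
  mmap <- rizzoli_marker_map()
  rng <- make_rng(seed, "phantom")
  bones <- lapply(names(config), function(nm) {
    cfg <- config[[nm]]
    if (any(cfg$dim <= 1)) stop("zero- or degenerate-size volume requested")
    vol <- array(0, cfg$dim)
    ext <- (cfg$dim - 1) * cfg$spacing
    # bone local frame = anatomical rest frame: the volume is centered on
    # the segment's rest center, landmarks are stored at their rest-world
    # coordinates, and the rest pose of every bone is the identity
    origin <- centers[nm, ] - ext / 2
    for (sh in cfg$shapes) {
      vol <- add_ellipsoid(vol, cfg$spacing, origin,
                           centers[nm, ] + sh$center, sh$semi, sh$value)
    }
    # seeded low-amplitude texture inside the bone only
    tex <- array(rng(prod(cfg$dim)), cfg$dim)
    vol <- vol * (1 + 0.08 * (tex - 0.5))
    marks <- names(mmap)[mmap == nm]
    local <- rest[marks, , drop = FALSE]
    phantom_bone(nm, vol, cfg$spacing, local, origin = origin)
  })
  names(bones) <- names(config)
  bones
}

# deterministic sub-stream RNG: a stage label plus the user seed define an
# independent uniform stream, so stages can be re-run in any order
make_rng <- function(seed, label) {
  sub <- as.integer((as.numeric(seed) +
                       sum(utf8ToInt(label)) * 2654435) %% 2147483647)
  env <- new.env()
  env$state <- sub
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(env$state)
    out <- stats::runif(n + 1)
    env$state <- as.integer(floor(out[1] * (.Machine$integer.max - 1)))
    out[-1]
  }
}

# seeded standard normals from the same sub-stream mechanism
make_rng_norm <- function(seed, label) {
  u <- make_rng(seed, label)
  function(n) stats::qnorm(u(n))
}
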