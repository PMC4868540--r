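#' @import methods
NULL

#' Arena geometry
#'
#' Circular arena in which a single fly walks, with a central odor zone.
#' All radii are in cm; the coordinate system is arena-centred Cartesian.
#' The nominal odor-zone radius bounds the region of constant odor
#' concentration; the odor-boundary radius is the (possibly more
#' conservative) radius used to score entries/exits and the sharp-turn ring.
#'
#' @slot arenaRadius arena radius (cm).
#' @slot odorZoneRadius nominal odor-zone radius (cm).
#' @slot odorBoundaryRadius boundary radius used for transit scoring (cm).
#' @export
setClass("ArenaGeometry",
  representation(arenaRadius = "numeric",
                 odorZoneRadius = "numeric",
                 odorBoundaryRadius = "numeric"))

setValidity("ArenaGeometry", function(object) {
  msg <- character()
  for (s in c("arenaRadius", "odorZoneRadius", "odorBoundaryRadius")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a single positive number", s))
  }
  if (!length(msg) && object@odorZoneRadius >= object@arenaRadius)
    msg <- c(msg, "odorZoneRadius must be smaller than arenaRadius")
  if (!length(msg) && object@odorBoundaryRadius >= object@arenaRadius)
    msg <- c(msg, "odorBoundaryRadius must be smaller than arenaRadius")
  if (length(msg)) msg else TRUE
})

#' Construct an ArenaGeometry
#'
#' Defaults correspond to the ring assay: a 6.4 cm diameter arena with a
#' 1.2 cm odor-zone radius. The conservative odor boundary estimated from
#' stopping behavior with undiluted attractant is 1.9 cm; pass
#' \code{odorBoundaryRadius = 1.9} for such configurations.
#'
#' @param arenaRadius arena radius in cm.
#' @param odorZoneRadius odor-zone radius in cm.
#' @param odorBoundaryRadius radius used for entry/exit scoring in cm.
#' @return An \linkS4class{ArenaGeometry}.
#' @examples
#' arenaGeometry()
#' arenaGeometry(odorBoundaryRadius = 1.9)
#' @export
arenaGeometry <- function(arenaRadius = 3.2, odorZoneRadius = 1.2,
                          odorBoundaryRadius = odorZoneRadius) {
  new("ArenaGeometry", arenaRadius = arenaRadius,
      odorZoneRadius = odorZoneRadius,
      odorBoundaryRadius = odorBoundaryRadius)
}

#' Per-context walker parameters
#'
#' One block of locomotor statistics for the semi-Markov run/stop walker,
#' applying in one of the four contexts {before, during} x {inside,
#' outside odor zone}.
#'
#' @slot medianRunDuration median run duration (s).
#' @slot medianStopDuration median stop duration (s).
#' @slot medianRunSpeed median within-run speed (cm/s).
#' @slot headingDiffusion heading diffusion during runs (rad^2/s).
#' @slot sharpTurnRate Poisson rate of discrete sharp-turn events (events/s).
#' @slot sharpTurnAngle magnitude of a sharp-turn heading jump (rad).
#' @slot wallAttraction probability in [0,1] of aligning tangentially on
#'   wall contact (otherwise the heading is reflected).
#' @slot boundaryTurnBias per-frame probability of an inward-directed sharp
#'   turn while within 2 mm of the odor boundary (0 disables the bias).
#' @export
setClass("ContextParams",
  representation(medianRunDuration = "numeric",
                 medianStopDuration = "numeric",
                 medianRunSpeed = "numeric",
                 headingDiffusion = "numeric",
                 sharpTurnRate = "numeric",
                 sharpTurnAngle = "numeric",
                 wallAttraction = "numeric",
                 boundaryTurnBias = "numeric"))

setValidity("ContextParams", function(object) {
  msg <- character()
  for (s in c("medianRunDuration", "medianStopDuration", "medianRunSpeed")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be positive", s))
  }
  for (s in c("headingDiffusion", "sharpTurnRate", "sharpTurnAngle")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      msg <- c(msg, sprintf("%s must be non-negative", s))
  }
  for (s in c("wallAttraction", "boundaryTurnBias")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must lie in [0, 1]", s))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ContextParams block
#'
#' Defaults are the no-odor baseline of walking flies in the ring assay:
#' median run duration 4.81 s, median stop duration 0.67 s, median run
#' speed 0.57 cm/s.
#'
#' @param medianRunDuration,medianStopDuration median episode durations (s).
#' @param medianRunSpeed median within-run speed (cm/s).
#' @param headingDiffusion heading diffusion during runs (rad^2/s).
#' @param sharpTurnRate rate of sharp-turn events (events/s).
#' @param sharpTurnAngle sharp-turn magnitude (rad).
#' @param wallAttraction tangential-alignment probability at the wall.
#' @param boundaryTurnBias inward sharp-turn probability near the boundary.
#' @return A \linkS4class{ContextParams}.
#' @export
contextParams <- function(medianRunDuration = 4.81,
                          medianStopDuration = 0.67,
                          medianRunSpeed = 0.57,
                          headingDiffusion = 0.2,
                          sharpTurnRate = 0.25,
                          sharpTurnAngle = 1.6,
                          wallAttraction = 0.7,
                          boundaryTurnBias = 0) {
  new("ContextParams",
      medianRunDuration = medianRunDuration,
      medianStopDuration = medianStopDuration,
      medianRunSpeed = medianRunSpeed,
      headingDiffusion = headingDiffusion,
      sharpTurnRate = sharpTurnRate,
      sharpTurnAngle = sharpTurnAngle,
      wallAttraction = wallAttraction,
      boundaryTurnBias = boundaryTurnBias)
}

#' Walker configuration
#'
#' Full configuration of the semi-Markov run/stop walker: arena geometry,
#' trial timing and the four per-context parameter blocks. Episode
#' durations are log-normal with the configured medians and a common
#' log-scale sd; per-run speeds likewise.
#'
#' @slot frameRate sampling rate (frames/s).
#' @slot durationBefore,durationDuring trial phase lengths (s).
#' @slot arena an \linkS4class{ArenaGeometry}.
#' @slot contexts named list with elements \code{before_inside},
#'   \code{before_outside}, \code{during_inside}, \code{during_outside},
#'   each a \linkS4class{ContextParams}.
#' @slot durationSdlog log-scale sd of episode durations.
#' @slot speedSdlog log-scale sd of per-run speeds.
#' @export
setClass("WalkerConfig",
  representation(frameRate = "numeric",
                 durationBefore = "numeric",
                 durationDuring = "numeric",
                 arena = "ArenaGeometry",
                 contexts = "list",
                 durationSdlog = "numeric",
                 speedSdlog = "numeric"))

setValidity("WalkerConfig", function(object) {
  msg <- character()
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be positive")
  minDur <- 2 / max(object@frameRate, .Machine$double.eps)
  if (object@durationBefore < minDur || object@durationDuring < minDur)
    msg <- c(msg, "phase durations must span at least 2 frames")
  need <- c("before_inside", "before_outside", "during_inside",
            "during_outside")
  if (!all(need %in% names(object@contexts)))
    msg <- c(msg, paste("contexts must contain", paste(need, collapse = ", ")))
  else if (!all(vapply(object@contexts[need], is, TRUE, "ContextParams")))
    msg <- c(msg, "every context block must be a ContextParams")
  if (object@durationSdlog < 0 || object@speedSdlog < 0)
    msg <- c(msg, "log-scale sds must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Single-fly trajectory
#'
#' Time-stamped arena-centred positions of one fly at uniform frame
#' spacing, with per-frame validity flags and the arena geometry.
#'
#' @slot flyId character identifier.
#' @slot time time stamps (s), 0-based, uniformly spaced at 1/frameRate.
#' @slot x,y arena-centred coordinates (cm); NA where position is missing.
#' @slot flagged logical; TRUE where the position was repaired or suspect.
#' @slot frameRate frames per second.
#' @slot arena an \linkS4class{ArenaGeometry}.
#' @export
setClass("FlyTrajectory",
  representation(flyId = "character",
                 time = "numeric",
                 x = "numeric",
                 y = "numeric",
                 flagged = "logical",
                 frameRate = "numeric",
                 arena = "ArenaGeometry"))

setValidity("FlyTrajectory", function(object) {
  msg <- character()
  n <- length(object@time)
  if (length(object@x) != n || length(object@y) != n ||
      length(object@flagged) != n)
    msg <- c(msg, "time, x, y and flagged must have equal length")
  if (n >= 2) {
    dt <- diff(object@time)
    if (any(dt <= 0)) msg <- c(msg, "time must be strictly increasing")
    expected <- 1 / object@frameRate
    if (max(abs(dt - expected)) > 1e-6)
      msg <- c(msg, "time must be uniformly spaced at 1/frameRate")
  }
  r <- .radial(object@x, object@y)
  # tolerance of one nominal step length (generously, 1 cm/s / frameRate)
  tol <- max(1 / object@frameRate, 0.05)
  if (any(r > object@arena@arenaRadius + tol, na.rm = TRUE))
    msg <- c(msg, "positions lie outside the arena radius")
  if (length(msg)) msg else TRUE
})

#' Ground-truth labels for a simulated trajectory
#'
#' @slot state per-frame locomotor state, "run" or "stop".
#' @slot turn per-frame turn label, "none", "smooth" or "sharp".
#' @slot context per-frame context label, e.g. "before_outside".
#' @slot events data.frame of sharp-turn events (frame, time_s, x_cm,
#'   y_cm, magnitude_rad).
#' @export
setClass("GroundTruth",
  representation(state = "character",
                 turn = "character",
                 context = "character",
                 events = "data.frame"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  n <- length(object@state)
  if (length(object@turn) != n || length(object@context) != n)
    msg <- c(msg, "state, turn and context must have equal length")
  if (!all(object@state %in% c("run", "stop")))
    msg <- c(msg, "state must be 'run' or 'stop'")
  if (!all(object@turn %in% c("none", "smooth", "sharp")))
    msg <- c(msg, "turn must be 'none', 'smooth' or 'sharp'")
  if (length(msg)) msg else TRUE
})

#' Video rendering configuration
#'
#' Parameters for rendering a trajectory as a stack of grayscale frames
#' with a single bright Gaussian blob (the fly) over a static textured
#' dark background plus i.i.d. sensor noise. Intensities are on [0, 1].
#'
#' @slot imageSize square image side length (px).
#' @slot pixelScale mm per pixel.
#' @slot blobSigma Gaussian blob sd (px).
#' @slot blobIntensity peak blob intensity.
#' @slot backgroundIntensity mean background level.
#' @slot noiseSd per-frame additive noise sd.
#' @slot textureSd sd of the static background texture.
#' @slot textureSeed seed fixing the static texture.
#' @export
setClass("VideoConfig",
  representation(imageSize = "integer",
                 pixelScale = "numeric",
                 blobSigma = "numeric",
                 blobIntensity = "numeric",
                 backgroundIntensity = "numeric",
                 noiseSd = "numeric",
                 textureSd = "numeric",
                 textureSeed = "integer"))

setValidity("VideoConfig", function(object) {
  msg <- character()
  if (object@imageSize < 8L) msg <- c(msg, "imageSize too small")
  if (object@pixelScale <= 0) msg <- c(msg, "pixelScale must be positive")
  if (object@blobIntensity <= object@backgroundIntensity + 3 * object@noiseSd)
    msg <- c(msg,
      "blobIntensity must exceed backgroundIntensity + 3 * noiseSd")
  if (length(msg)) msg else TRUE
})

#' Construct a VideoConfig
#'
#' @param imageSize image side length in px.
#' @param pixelScale mm per pixel.
#' @param blobSigma blob sd in px.
#' @param blobIntensity,backgroundIntensity intensities on [0, 1].
#' @param noiseSd per-frame noise sd.
#' @param textureSd static texture sd.
#' @param textureSeed seed of the static texture.
#' @return A \linkS4class{VideoConfig}.
#' @export
videoConfig <- function(imageSize = 180L, pixelScale = 0.4,
                        blobSigma = 1.5, blobIntensity = 0.9,
                        backgroundIntensity = 0.1, noiseSd = 0.01,
                        textureSd = 0.02, textureSeed = 99L) {
  new("VideoConfig", imageSize = as.integer(imageSize),
      pixelScale = pixelScale, blobSigma = blobSigma,
      blobIntensity = blobIntensity,
      backgroundIntensity = backgroundIntensity, noiseSd = noiseSd,
      textureSd = textureSd, textureSeed = as.integer(textureSeed))
}

#' Stack of grayscale video frames
#'
#' @slot frames numeric array (rows x cols x frames), intensities on [0, 1].
#' @slot frameRate frames per second.
#' @export
setClass("FrameStack",
  representation(frames = "array", frameRate = "numeric"))

setValidity("FrameStack", function(object) {
  if (length(dim(object@frames)) != 3L)
    return("frames must be a rows x cols x frames array")
  if (object@frameRate <= 0) return("frameRate must be positive")
  TRUE
})

#' Pixel calibration of an arena video
#'
#' @slot pixelScale mm per pixel.
#' @slot centerPx arena centre as (row, col) pixel coordinates.
#' @slot arenaRadiusPx arena radius in pixels.
#' @export
setClass("Calibration",
  representation(pixelScale = "numeric",
                 centerPx = "numeric",
                 arenaRadiusPx = "numeric"))

setValidity("Calibration", function(object) {
  if (length(object@pixelScale) != 1L || object@pixelScale <= 0)
    return("pixelScale must be a single positive number")
  if (length(object@centerPx) != 2L)
    return("centerPx must be (row, col)")
  TRUE
})

#' Raw pixel-space track
#'
#' Per-frame centroid in pixel coordinates with flags for repaired frames
#' and markers for frames on which no fly was found.
#'
#' @slot rowPx,colPx centroid pixel coordinates; NA where missing.
#' @slot flagged TRUE where the jump rule fired and the position was
#'   replaced by interpolation.
#' @slot missing TRUE where no bright object was found.
#' @slot reason per-frame reason string for flagged/missing frames.
#' @slot frameRate frames per second.
#' @export
setClass("RawTrack",
  representation(rowPx = "numeric", colPx = "numeric",
                 flagged = "logical", missing = "logical",
                 reason = "character", frameRate = "numeric"))

setValidity("RawTrack", function(object) {
  n <- length(object@rowPx)
  if (length(object@colPx) != n || length(object@flagged) != n ||
      length(object@missing) != n || length(object@reason) != n)
    return("all per-frame slots must have equal length")
  if (any((object@flagged | object@missing) & !nzchar(object@reason)))
    return("flagged or missing frames must carry a reason")
  TRUE
})

#' Run/stop and turn segmentation of a trajectory
#'
#' @slot state per-frame locomotor state, "run" or "stop".
#' @slot turn per-frame turn label, "none", "smooth" or "sharp" (empty
#'   character vector until turns have been classified).
#' @slot runs,stops data.frames of episodes (start_frame, end_frame,
#'   start_time, end_time, duration_s).
#' @slot events data.frame of sharp-turn events (frame, time_s, x_cm,
#'   y_cm, magnitude_rad).
#' @export
setClass("SegmentLabeling",
  representation(state = "character",
                 turn = "character",
                 runs = "data.frame",
                 stops = "data.frame",
                 events = "data.frame"))

setValidity("SegmentLabeling", function(object) {
  msg <- character()
  if (!all(object@state %in% c("run", "stop")))
    msg <- c(msg, "state must be 'run' or 'stop'")
  if (length(object@turn) &&
      length(object@turn) != length(object@state))
    msg <- c(msg, "turn labels must match state length")
  if (length(object@turn) &&
      !all(object@turn %in% c("none", "smooth", "sharp")))
    msg <- c(msg, "turn must be 'none', 'smooth' or 'sharp'")
  nState <- length(object@state)
  covered <- sum(object@runs$end_frame - object@runs$start_frame + 1L) +
    sum(object@stops$end_frame - object@stops$start_frame + 1L)
  if (covered != nState)
    msg <- c(msg, "episodes must tile the record without overlap")
  if (length(msg)) msg else TRUE
})

#' Trial epochs of one fly
#'
#' Half-open intervals [start, end) in seconds. The during epoch starts at
#' odor-on + latency if the fly is inside the odor zone at odor-on,
#' otherwise at its first subsequent entry; flies that never enter are
#' excluded.
#'
#' @slot before,during,after numeric length-2 intervals (s); during is
#'   c(NA, NA) for excluded flies.
#' @slot excluded logical.
#' @slot reason exclusion reason ("" if not excluded).
#' @export
setClass("EpochSet",
  representation(before = "numeric", during = "numeric",
                 after = "numeric", excluded = "logical",
                 reason = "character"))

setValidity("EpochSet", function(object) {
  if (length(object@before) != 2L || length(object@during) != 2L ||
      length(object@after) != 2L)
    return("before, during and after must be length-2 intervals")
  if (object@excluded && all(is.finite(object@during)))
    return("excluded flies must have an undefined during epoch")
  TRUE
})

#' Canonical variate analysis result
#'
#' @slot eigenvalues canonical eigenvalues (length = number of groups - 1).
#' @slot axes matrix of canonical axes (parameters x variates).
#' @slot projections per-fly scores on canonical variate 1.
#' @slot groups factor of group labels for the projected flies.
#' @slot distance observed distance between group medians on CV1.
#' @slot permutationP permutation p-value (fraction of shuffles with a
#'   larger median distance); NA until a permutation test has been run.
#' @slot permutationPPlusOne the (k+1)/(n+1) convention for the same test.
#' @slot nPerm number of permutations (0 if none).
#' @slot seed RNG seed of the permutation test (NA if none).
#' @export
setClass("CVAResult",
  representation(eigenvalues = "numeric",
                 axes = "matrix",
                 projections = "numeric",
                 groups = "factor",
                 distance = "numeric",
                 permutationP = "numeric",
                 permutationPPlusOne = "numeric",
                 nPerm = "integer",
                 seed = "integer"))

setValidity("CVAResult", function(object) {
  msg <- character()
  nGroups <- nlevels(object@groups)
  if (ncol(object@axes) != nGroups - 1L)
    msg <- c(msg, "number of canonical dimensions must be nGroups - 1")
  if (length(object@projections) != length(object@groups))
    msg <- c(msg, "one projection per labelled fly required")
  if (!is.na(object@permutationP) && object@nPerm > 0) {
    lo <- 0
    hi <- 1
    if (object@permutationP < lo || object@permutationP > hi)
      msg <- c(msg, "permutationP must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})
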