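# Accessor and show methods for the S4 containers.

#' @rdname accessors
#' @export
setMethod("flyId", "FlyTrajectory", function(x) x@flyId)

#' @rdname accessors
#' @export
setMethod("frameRate", "FlyTrajectory", function(x) x@frameRate)

#' @rdname accessors
#' @export
setMethod("frameRate", "FrameStack", function(x) x@frameRate)

#' @rdname accessors
#' @export
setMethod("frameRate", "RawTrack", function(x) x@frameRate)

#' @rdname accessors
#' @export
setMethod("arena", "FlyTrajectory", function(x) x@arena)

#' @rdname accessors
#' @export
setMethod("arena", "WalkerConfig", function(x) x@arena)

#' @rdname accessors
#' @export
setMethod("coords", "FlyTrajectory",
          function(x) cbind(x = x@x, y = x@y))

#' @rdname accessors
#' @export
setMethod("coords", "RawTrack",
          function(x) cbind(row = x@rowPx, col = x@colPx))

#' @rdname accessors
#' @export
setMethod("nFrames", "FlyTrajectory", function(x) length(x@time))

#' @rdname accessors
#' @export
setMethod("nFrames", "FrameStack", function(x) dim(x@frames)[3L])

#' @rdname accessors
#' @export
setMethod("nFrames", "RawTrack", function(x) length(x@rowPx))

#' @rdname accessors
#' @export
setMethod("states", "SegmentLabeling", function(x) x@state)

#' @rdname accessors
#' @export
setMethod("states", "GroundTruth", function(x) x@state)

#' @rdname accessors
#' @export
setMethod("turnLabels", "SegmentLabeling", function(x) x@turn)

#' @rdname accessors
#' @export
setMethod("turnLabels", "GroundTruth", function(x) x@turn)

#' @rdname accessors
#' @export
setMethod("runEpisodes", "SegmentLabeling", function(x) x@runs)

#' @rdname accessors
#' @export
setMethod("stopEpisodes", "SegmentLabeling", function(x) x@stops)

#' @rdname accessors
#' @export
setMethod("sharpTurnEvents", "SegmentLabeling", function(x) x@events)

#' @rdname accessors
#' @export
setMethod("sharpTurnEvents", "GroundTruth", function(x) x@events)

#' @rdname accessors
#' @export
setMethod("epochInterval", "EpochSet", function(x, which = c("before",
                                                  "during", "after")) {
  which <- match.arg(which)
  slot(x, which)
})

#' @rdname accessors
#' @export
setMethod("isExcluded", "EpochSet", function(x) x@excluded)

#' @rdname accessors
#' @export
setMethod("canonicalAxes", "CVAResult", function(x) x@axes)

#' @rdname accessors
#' @export
setMethod("canonicalProjections", "CVAResult", function(x) x@projections)

#' @rdname accessors
#' @export
setMethod("groupDistance", "CVAResult", function(x) x@distance)

#' @rdname accessors
#' @export
setMethod("permutationP", "CVAResult", function(x) x@permutationP)

setMethod("show", "FlyTrajectory", function(object) {
  n <- length(object@time)
  cat(sprintf("FlyTrajectory '%s': %d frames at %g fps (%.1f s)\n",
              object@flyId, n, object@frameRate,
              if (n) n / object@frameRate else 0))
  cat(sprintf("  arena radius %.2f cm, odor zone %.2f cm, boundary %.2f cm\n",
              object@arena@arenaRadius, object@arena@odorZoneRadius,
              object@arena@odorBoundaryRadius))
  cat(sprintf("  flagged frames: %d; missing frames: %d\n",
              sum(object@flagged), sum(is.na(object@x))))
})

setMethod("show", "SegmentLabeling", function(object) {
  cat(sprintf("SegmentLabeling: %d frames, %d runs, %d stops\n",
              length(object@state), nrow(object@runs), nrow(object@stops)))
  if (length(object@turn)) {
    cat(sprintf("  turn frames: %d smooth, %d sharp (%d events)\n",
                sum(object@turn == "smooth"), sum(object@turn == "sharp"),
                nrow(object@events)))
  } else {
    cat("  turns not yet classified\n")
  }
})

setMethod("show", "EpochSet", function(object) {
  fmt <- function(iv) {
    if (any(!is.finite(iv))) "undefined"
    else sprintf("[%.1f, %.1f) s", iv[1], iv[2])
  }
  cat("EpochSet:\n")
  cat("  before:", fmt(object@before), "\n")
  cat("  during:", fmt(object@during), "\n")
  cat("  after: ", fmt(object@after), "\n")
  if (object@excluded) cat("  excluded:", object@reason, "\n")
})

setMethod("show", "CVAResult", function(object) {
  cat(sprintf("CVAResult: %d groups, %d canonical dimension(s)\n",
              nlevels(object@groups), ncol(object@axes)))
  cat(sprintf("  CV1 median group distance: %.4g\n", object@distance))
  if (!is.na(object@permutationP)) {
    cat(sprintf("  permutation p = %.4g (%d shuffles, seed %d)\n",
                object@permutationP, object@nPerm, object@seed))
  }
})

setMethod("show", "WalkerConfig", function(object) {
  cat(sprintf("WalkerConfig: %g fps, before %g s, during %g s\n",
              object@frameRate, object@durationBefore,
              object@durationDuring))
  for (nm in names(object@contexts)) {
    p <- object@contexts[[nm]]
    cat(sprintf("  %-15s run %.2f s, stop %.2f s, speed %.2f cm/s\n",
                nm, p@medianRunDuration, p@medianStopDuration,
                p@medianRunSpeed))
  }
})

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameStack: %d frames of %d x %d px at %g fps\n",
              d[3], d[1], d[2], object@frameRate))
})

setMethod("show", "RawTrack", function(object) {
  cat(sprintf("RawTrack: %d frames, %d flagged, %d missing\n",
              length(object@rowPx), sum(object@flagged),
              sum(object@missing)))
})
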