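# Shared fixtures and small utilities for the test suite.

# short-trial configuration: 1 min before + 1 min during
shortConfig <- function(...) {
  walkerConfig(durationBefore = 60, durationDuring = 60, ...)
}

# pipeline configuration matching a short trial; smoothing disabled by
# default because synthetic trajectories carry no positional noise
shortPipelineConfig <- function(smoothingWindow = 1L, nPerm = 200L) {
  conf <- defaultPipelineConfig()
  conf$epochs$odorOn <- 60
  conf$epochs$duringLength <- 60
  conf$kinematics$smoothingWindow <- smoothingWindow
  conf$stats$nPerm <- nPerm
  conf
}

# full-length trial config with smoothing disabled (noise-free tracks)
fullPipelineConfig <- function(nPerm = 150L) {
  conf <- defaultPipelineConfig()
  conf$kinematics$smoothingWindow <- 1L
  conf$stats$nPerm <- nPerm
  conf
}

# trajectory built directly from coordinate vectors
makeTrajectory <- function(x, y, frameRate = 30, geom = arenaGeometry(),
                           flyId = "test") {
  n <- length(x)
  new("FlyTrajectory", flyId = flyId, time = (seq_len(n) - 1) / frameRate,
      x = x, y = y, flagged = rep(FALSE, n), frameRate = frameRate,
      arena = geom)
}

# scale-invariant separation of two group medians on a 1-d projection
projSeparation <- function(proj, groups) {
  med <- tapply(proj, groups, median)
  abs(diff(range(med))) / stats::sd(proj - stats::ave(proj, groups))
}

# walker config whose during blocks scale run duration, stop duration,
# run speed and sharp-turn rate by a common fold-change
foldChangeConfig <- function(fold, ...) {
  base <- contextParams()
  mod <- contextParams(medianRunDuration = base@medianRunDuration * fold,
                       medianStopDuration = base@medianStopDuration * fold,
                       medianRunSpeed = base@medianRunSpeed * fold,
                       sharpTurnRate = base@sharpTurnRate * fold)
  walkerConfig(before = base, during = mod, ...)
}
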