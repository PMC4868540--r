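# Agent-based walker: semi-Markov run/stop alternation with log-normal
# episode durations, smooth heading diffusion, discrete sharp-turn events,
# wall-biased motion and context switching at the odor-zone boundary.

#' Construct a WalkerConfig
#'
#' The default configuration is a null walker: all four context blocks
#' equal the no-odor baseline (median run 4.81 s, stop 0.67 s, run speed
#' 0.57 cm/s), so behavior is statistically identical before and during
#' the odor period. Trials follow the ring-assay protocol: 3 min with no
#' odor followed by 3 min of odor, sampled at 30 frames/s in a 6.4 cm
#' diameter arena.
#'
#' @param frameRate frames per second.
#' @param durationBefore,durationDuring phase durations (s).
#' @param arena an \linkS4class{ArenaGeometry}.
#' @param before,during \linkS4class{ContextParams} applied outside and
#'   inside the odor zone in each phase, unless the zone-specific
#'   arguments are given.
#' @param beforeInside,beforeOutside,duringInside,duringOutside optional
#'   zone-specific overrides.
#' @param durationSdlog log-scale sd of episode durations (default 0.8,
#'   giving the heavy right tails seen in walking flies).
#' @param speedSdlog log-scale sd of per-run speeds.
#' @return A \linkS4class{WalkerConfig}.
#' @examples
#' walkerConfig()             # null walker
#' acvWalkerConfig()          # attractant-like modulation
#' @export
walkerConfig <- function(frameRate = 30, durationBefore = 180,
                         durationDuring = 180,
                         arena = arenaGeometry(),
                         before = contextParams(),
                         during = before,
                         beforeInside = before, beforeOutside = before,
                         duringInside = during, duringOutside = during,
                         durationSdlog = 0.8, speedSdlog = 0.3) {
  new("WalkerConfig", frameRate = frameRate,
      durationBefore = durationBefore, durationDuring = durationDuring,
      arena = arena,
      contexts = list(before_inside = beforeInside,
                      before_outside = beforeOutside,
                      during_inside = duringInside,
                      during_outside = duringOutside),
      durationSdlog = durationSdlog, speedSdlog = speedSdlog)
}

#' Attractant-like walker configuration
#'
#' A configuration emulating the response to an attractive odor such as
#' apple cider vinegar: inside the odor zone during the odor period, runs
#' shorten (median 1.0 s), stops shorten (median 0.3 s) and run speed
#' drops (median 0.18 cm/s); outside, speed increases and edge dwelling
#' weakens; sharp turns near the odor boundary are biased inward.
#'
#' @param ... passed on to \code{\link{walkerConfig}}.
#' @return A \linkS4class{WalkerConfig}.
#' @export
acvWalkerConfig <- function(...) {
  base <- contextParams()
  duringIn <- contextParams(medianRunDuration = 1.0,
                            medianStopDuration = 0.3,
                            medianRunSpeed = 0.18,
                            wallAttraction = 0.3,
                            boundaryTurnBias = 0.05)
  duringOut <- contextParams(medianStopDuration = 0.3,
                             medianRunSpeed = 0.7,
                             wallAttraction = 0.3,
                             boundaryTurnBias = 0.05)
  walkerConfig(beforeInside = base, beforeOutside = base,
               duringInside = duringIn, duringOutside = duringOut, ...)
}

# draw one episode duration in frames (at least 1 frame)
.drawEpisodeFrames <- function(medianS, sdlog, frameRate) {
  max(1L, as.integer(round(.rlnormMedian(1L, medianS, sdlog) * frameRate)))
}

#' Simulate one fly
#'
#' Runs the semi-Markov walker at frame resolution. Run and stop episodes
#' alternate with log-normal durations whose medians equal the current
#' context's configured medians; during runs the heading performs a
#' Gaussian random walk (variance headingDiffusion/frameRate per frame)
#' punctuated by Poisson sharp-turn events that add +/- sharpTurnAngle in
#' a single frame; at the arena wall the heading either aligns with the
#' tangent (probability wallAttraction) or is reflected about it. The
#' active context switches instantaneously when the fly crosses the
#' odor-zone boundary or the odor turns on, resampling the ongoing
#' episode from the new context.
#'
#' @param config a \linkS4class{WalkerConfig}.
#' @param seed integer seed fixing all randomness.
#' @param flyId identifier stored in the trajectory.
#' @return A list with elements \code{trajectory}
#'   (\linkS4class{FlyTrajectory}) and \code{truth}
#'   (\linkS4class{GroundTruth}).
#' @examples
#' sim <- simulateFly(walkerConfig(durationBefore = 10,
#'                                 durationDuring = 10), seed = 1)
#' sim$trajectory
#' @export
simulateFly <- function(config, seed, flyId = sprintf("fly_%06d", seed)) {
  stopifnot(is(config, "WalkerConfig"))
  validObject(config)
  seed <- as.integer(seed)
  set.seed(seed)

  fps <- config@frameRate
  nBefore <- as.integer(round(config@durationBefore * fps))
  nTotal <- nBefore + as.integer(round(config@durationDuring * fps))
  geom <- config@arena
  R <- geom@arenaRadius
  zoneR <- geom@odorZoneRadius
  boundR <- geom@odorBoundaryRadius

  x <- numeric(nTotal); y <- numeric(nTotal)
  state <- character(nTotal); turn <- rep("none", nTotal)
  ctxLab <- character(nTotal)
  evFrame <- integer(0); evMag <- numeric(0)

  # start away from the wall with a uniformly random heading
  startR <- 0.8 * R * sqrt(stats::runif(1))
  startA <- stats::runif(1, 0, 2 * pi)
  px <- startR * cos(startA); py <- startR * sin(startA)
  heading <- stats::runif(1, 0, 2 * pi)

  curState <- "run"
  curCtx <- ""
  remaining <- 0L
  runSpeed <- NA_real_

  for (i in seq_len(nTotal)) {
    phase <- if (i <= nBefore) "before" else "during"
    inside <- .radial(px, py) <= zoneR
    ctxName <- paste(phase, if (inside) "inside" else "outside", sep = "_")
    ctx <- config@contexts[[ctxName]]

    if (ctxName != curCtx) {
      # instantaneous context switch: resample the ongoing episode
      curCtx <- ctxName
      median <- if (curState == "run") ctx@medianRunDuration else
        ctx@medianStopDuration
      remaining <- .drawEpisodeFrames(median, config@durationSdlog, fps)
      if (curState == "run")
        runSpeed <- .rlnormMedian(1L, ctx@medianRunSpeed, config@speedSdlog)
    }

    if (remaining <= 0L) {
      curState <- if (curState == "run") "stop" else "run"
      medianS <- if (curState == "run") ctx@medianRunDuration else
        ctx@medianStopDuration
      remaining <- .drawEpisodeFrames(medianS, config@durationSdlog, fps)
      if (curState == "run")
        runSpeed <- .rlnormMedian(1L, ctx@medianRunSpeed, config@speedSdlog)
    }

    x[i] <- px; y[i] <- py
    state[i] <- curState
    ctxLab[i] <- ctxName

    if (curState == "run") {
      r <- .radial(px, py)
      nearBoundary <- abs(r - boundR) <= 0.2
      pTurn <- ctx@sharpTurnRate / fps
      biased <- nearBoundary && ctx@boundaryTurnBias > 0
      if (biased) pTurn <- max(pTurn, ctx@boundaryTurnBias)
      if (stats::runif(1) < pTurn) {
        if (biased) {
          # direct the turn inward: rotate toward the centre
          toCentre <- atan2(-py, -px)
          sgn <- sign(.wrapAngle(toCentre - heading))
          if (sgn == 0) sgn <- sample(c(-1, 1), 1L)
        } else {
          sgn <- sample(c(-1, 1), 1L)
        }
        heading <- heading + sgn * ctx@sharpTurnAngle
        turn[i] <- "sharp"
        evFrame <- c(evFrame, i)
        evMag <- c(evMag, sgn * ctx@sharpTurnAngle)
      }
      if (ctx@headingDiffusion > 0)
        heading <- heading +
          stats::rnorm(1, 0, sqrt(ctx@headingDiffusion / fps))

      step <- runSpeed / fps
      nx <- px + step * cos(heading)
      ny <- py + step * sin(heading)
      if (.radial(nx, ny) >= R) {
        phi <- atan2(py, px)          # outward normal at contact
        tangent <- phi + pi / 2
        if (stats::runif(1) < ctx@wallAttraction) {
          # align with whichever tangent direction is closer
          d1 <- abs(.wrapAngle(heading - tangent))
          d2 <- abs(.wrapAngle(heading - (tangent + pi)))
          heading <- if (d1 <= d2) tangent else tangent + pi
        } else {
          heading <- 2 * tangent - heading   # reflect about the tangent
        }
        nx <- px + step * cos(heading)
        ny <- py + step * sin(heading)
        if (.radial(nx, ny) >= R) {
          # corner case: pull back onto the rim along the current angle
          ang <- atan2(ny, nx)
          nx <- 0.999 * R * cos(ang)
          ny <- 0.999 * R * sin(ang)
        }
      }
      px <- nx; py <- ny
    }
    remaining <- remaining - 1L
  }

  time <- (seq_len(nTotal) - 1L) / fps
  traj <- new("FlyTrajectory", flyId = flyId, time = time, x = x, y = y,
              flagged = rep(FALSE, nTotal), frameRate = fps, arena = geom)
  events <- data.frame(frame = evFrame, time_s = time[evFrame],
                       x_cm = x[evFrame], y_cm = y[evFrame],
                       magnitude_rad = evMag)
  truth <- new("GroundTruth", state = state, turn = turn,
               context = ctxLab, events = events)
  list(trajectory = traj, truth = truth)
}

# per-fly seeds derived deterministically from one master seed,
# kept below 2^31
.deriveSeeds <- function(masterSeed, n) {
  set.seed(as.integer(masterSeed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a cohort of flies
#'
#' Independent walkers with per-fly seeds derived deterministically from
#' one master seed, mirroring the cohort sizes (around 30 flies per odor)
#' used in arena assays.
#'
#' @param config a \linkS4class{WalkerConfig}.
#' @param nFlies number of flies (>= 1).
#' @param seed master seed.
#' @param idPrefix prefix of the generated fly identifiers.
#' @return A list of length \code{nFlies}, each element as returned by
#'   \code{\link{simulateFly}}.
#' @export
simulateCohort <- function(config, nFlies, seed, idPrefix = "fly") {
  if (!is.numeric(nFlies) || nFlies < 1)
    stop("nFlies must be >= 1", call. = FALSE)
  nFlies <- as.integer(nFlies)
  seeds <- .deriveSeeds(seed, nFlies)
  lapply(seq_len(nFlies), function(i) {
    simulateFly(config, seed = seeds[i],
                flyId = sprintf("%s_%03d", idPrefix, i))
  })
}
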