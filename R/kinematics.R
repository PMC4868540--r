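# Track smoothing, speed and angular-speed series, Schmidt-trigger
# run/stop segmentation, turn classification, epoch delineation and
# odor-zone transit detection.

#' Smooth a trajectory with a sliding window
#'
#' Moving average of x and y with a centred window (default 10 frames,
#' i.e. 0.33 s at 30 fps); edge frames use shrunken windows.
#'
#' @param traj a \linkS4class{FlyTrajectory} without missing positions.
#' @param window window length in frames (>= 1).
#' @return A smoothed \linkS4class{FlyTrajectory}.
#' @export
smoothTrack <- function(traj, window = 10L) {
  stopifnot(is(traj, "FlyTrajectory"))
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  n <- nFrames(traj)
  if (n <= window)
    stop("record must be longer than the smoothing window", call. = FALSE)
  if (anyNA(traj@x))
    stop("cannot smooth a trajectory with missing positions", call. = FALSE)
  out <- traj
  out@x <- .movingAverage(traj@x, window)
  out@y <- .movingAverage(traj@y, window)
  out
}

#' Per-frame speed, heading and angular speed
#'
#' Speed is the displacement between consecutive frames times the frame
#' rate; heading is the direction of that displacement; angular speed is
#' the wrapped heading difference times the frame rate, reported only on
#' frames where the fly moves at least \code{minSpeedForAngular} (2 mm/s
#' by default), since heading is unreliable during very slow movement.
#'
#' @param traj a (smoothed) \linkS4class{FlyTrajectory}.
#' @param minSpeedForAngular angular-speed floor in cm/s.
#' @return A data.frame with columns time_s, speed (cm/s), heading (rad)
#'   and angular_speed (rad/s); trailing/leading entries that cannot be
#'   computed are NA.
#' @export
computeKinematics <- function(traj, minSpeedForAngular = 0.2) {
  stopifnot(is(traj, "FlyTrajectory"))
  n <- nFrames(traj)
  if (n < 3L) stop("need at least 3 frames", call. = FALSE)
  fps <- frameRate(traj)
  dx <- diff(traj@x); dy <- diff(traj@y)
  speed <- c(sqrt(dx^2 + dy^2) * fps, NA_real_)
  heading <- c(atan2(dy, dx), NA_real_)
  angular <- rep(NA_real_, n)
  dh <- .wrapAngle(diff(heading[seq_len(n - 1L)]))
  idx <- 2:(n - 1L)
  ok <- speed[idx] >= minSpeedForAngular &
    speed[idx - 1L] >= minSpeedForAngular
  angular[idx[ok]] <- dh[ok] * fps
  data.frame(time_s = traj@time, speed = speed, heading = heading,
             angular_speed = angular)
}

# vectorised Schmidt-trigger state sequence; NA speeds are never decisive
.schmidtStates <- function(speed, stopThreshold, runThreshold) {
  decisive <- rep(NA_character_, length(speed))
  decisive[!is.na(speed) & speed < stopThreshold] <- "stop"
  decisive[!is.na(speed) & speed > runThreshold] <- "run"
  if (all(is.na(decisive)))
    stop("state undeterminable: no frame outside the dead band",
         call. = FALSE)
  st <- .fillForward(decisive)
  rev(.fillForward(rev(st)))     # backfill from the first decisive frame
}

# episode tables from a state vector
.stateEpisodes <- function(state, frameRateHz) {
  mk <- function(flag) {
    ep <- .episodesOf(flag)
    ep$start_time <- (ep$start_frame - 1L) / frameRateHz
    ep$end_time <- ep$end_frame / frameRateHz
    ep$duration_s <- (ep$end_frame - ep$start_frame + 1L) / frameRateHz
    ep
  }
  list(runs = mk(state == "run"), stops = mk(state == "stop"))
}

#' Schmidt-trigger run/stop segmentation
#'
#' Two-threshold hysteresis on instantaneous speed: below
#' \code{stopThreshold} (0.5 mm/s) the fly is at a stop, above
#' \code{runThreshold} (1 mm/s) it is on a run, and in between the
#' previous state continues. The initial state is backfilled from the
#' first decisive frame. Consecutive same-state frames are merged into
#' episodes with durations in seconds.
#'
#' @param speed per-frame speed in cm/s (NA allowed, never decisive).
#' @param stopThreshold,runThreshold hysteresis thresholds in cm/s;
#'   defaults 0.05 and 0.1.
#' @param frameRate frames per second (for episode durations).
#' @return A \linkS4class{SegmentLabeling} with states and episodes
#'   (turn labels empty until \code{\link{classifyTurns}}).
#' @export
segmentRunsStops <- function(speed, stopThreshold = 0.05,
                             runThreshold = 0.1, frameRate = 30) {
  if (stopThreshold >= runThreshold)
    stop("stopThreshold must be below runThreshold", call. = FALSE)
  st <- .schmidtStates(speed, stopThreshold, runThreshold)
  ep <- .stateEpisodes(st, frameRate)
  new("SegmentLabeling", state = st, turn = character(0),
      runs = ep$runs, stops = ep$stops, events = .emptyEvents())
}

.emptyEvents <- function() {
  data.frame(frame = integer(0), time_s = numeric(0), x_cm = numeric(0),
             y_cm = numeric(0), magnitude_rad = numeric(0))
}

#' Classify smooth and sharp turns
#'
#' For each frame, the turn statistic is the absolute value of the sum of
#' signed angular displacement (angular speed / frame rate) over the
#' 5-frame window ending at that frame. Frames exceeding 0.3 rad are
#' turning; frames exceeding 1.3 rad constitute sharp turns. Contiguous
#' sharp frames are merged into a single sharp-turn event located at the
#' frame of maximal statistic. Turning frames that are not sharp are
#' labelled smooth. Only run frames carry turn labels. Set
#' \code{signedSum = FALSE} to sum absolute displacements instead.
#'
#' @param traj the \linkS4class{FlyTrajectory} (for event positions).
#' @param kin kinematics from \code{\link{computeKinematics}}.
#' @param seg a \linkS4class{SegmentLabeling} with run/stop states.
#' @param window window length in frames.
#' @param smoothThreshold,sharpThreshold thresholds in radians.
#' @param signedSum use |sum of signed displacements| (default) rather
#'   than the sum of absolute displacements.
#' @return The \linkS4class{SegmentLabeling} with turn labels and events.
#' @export
classifyTurns <- function(traj, kin, seg, window = 5L,
                          smoothThreshold = 0.3, sharpThreshold = 1.3,
                          signedSum = TRUE) {
  stopifnot(is(traj, "FlyTrajectory"), is(seg, "SegmentLabeling"))
  n <- length(seg@state)
  window <- as.integer(window)
  if (window > n) stop("window longer than record", call. = FALSE)
  disp <- kin$angular_speed / frameRate(traj)
  disp[is.na(disp)] <- 0          # disregarded slow-movement frames
  if (!signedSum) disp <- abs(disp)
  cs <- cumsum(c(0, disp))
  idx <- seq_len(n)
  lo <- pmax(idx - window + 1L, 1L)
  signedS <- cs[idx + 1L] - cs[lo]
  S <- abs(signedS)
  S[idx < window] <- 0            # incomplete leading windows
  isRun <- seg@state == "run"
  turn <- rep("none", n)
  turn[S > smoothThreshold & isRun] <- "smooth"
  sharp <- S > sharpThreshold & isRun
  turn[sharp] <- "sharp"

  events <- .emptyEvents()
  if (any(sharp)) {
    ep <- .episodesOf(sharp)
    peak <- vapply(seq_len(nrow(ep)), function(k) {
      span <- ep$start_frame[k]:ep$end_frame[k]
      span[which.max(S[span])]
    }, integer(1))
    events <- data.frame(frame = peak, time_s = traj@time[peak],
                         x_cm = traj@x[peak], y_cm = traj@y[peak],
                         magnitude_rad = signedS[peak])
  }
  initialize(seg, turn = turn, events = events)
}

#' Delineate before / during / after epochs
#'
#' The before epoch is [0, odorOn). The during epoch starts at
#' odorOn + latency if the fly is inside the odor zone when the odor
#' turns on (the latency being the time the odor takes to reach the
#' arena), otherwise at the fly's first subsequent entry; it ends at
#' odorOn + duringLength. Flies that never enter the odor zone after
#' odor-on are excluded with a recorded reason.
#'
#' @param traj a \linkS4class{FlyTrajectory}.
#' @param odorOn odor-on time (s), default 180.
#' @param latency odor arrival latency (s), default 5.
#' @param duringLength nominal odor-period length (s), default 180.
#' @param zoneRadius radius defining "inside" (default the trajectory's
#'   odor-zone radius).
#' @return An \linkS4class{EpochSet}.
#' @export
delineateEpochs <- function(traj, odorOn = 180, latency = 5,
                            duringLength = 180,
                            zoneRadius = arena(traj)@odorZoneRadius) {
  stopifnot(is(traj, "FlyTrajectory"))
  endT <- nFrames(traj) / frameRate(traj)
  if (odorOn <= 0 || odorOn >= endT)
    stop("odorOn must lie within the record", call. = FALSE)
  r <- .radial(traj@x, traj@y)
  inside <- !is.na(r) & r <= zoneRadius
  onIdx <- which(traj@time >= odorOn)[1L]
  duringEnd <- min(odorOn + duringLength, endT)
  if (inside[onIdx]) {
    duringStart <- odorOn + latency
  } else {
    entry <- which(inside & traj@time >= odorOn)
    if (!length(entry)) {
      return(new("EpochSet", before = c(0, odorOn),
                 during = c(NA_real_, NA_real_),
                 after = c(duringEnd, endT), excluded = TRUE,
                 reason = "fly never entered the odor zone after odor-on"))
    }
    duringStart <- traj@time[entry[1L]]
  }
  if (duringStart >= duringEnd) {
    return(new("EpochSet", before = c(0, odorOn),
               during = c(NA_real_, NA_real_),
               after = c(duringEnd, endT), excluded = TRUE,
               reason = "during epoch collapsed to zero length"))
  }
  new("EpochSet", before = c(0, odorOn),
      during = c(duringStart, duringEnd),
      after = c(duringEnd, endT), excluded = FALSE, reason = "")
}

#' Detect odor-zone transits
#'
#' Entries and exits of the disc of the given boundary radius, listed as
#' transits (entry time, exit time, dwell) together with the intervening
#' outside intervals. Inside or outside spells shorter than the debounce
#' (default 2 frames) are treated as boundary chatter and merged into the
#' surrounding spell. A transit still open at the end of the record has
#' an NA exit time.
#'
#' @param traj a \linkS4class{FlyTrajectory}.
#' @param boundaryRadius radius scoring entries/exits (default the
#'   trajectory's odor-boundary radius).
#' @param debounce minimum spell length in frames.
#' @return A list with data.frames \code{inside} and \code{outside}, each
#'   with columns entry_time, exit_time, dwell_s (NA dwell if open-ended).
#' @export
detectTransits <- function(traj,
                           boundaryRadius = arena(traj)@odorBoundaryRadius,
                           debounce = 2L) {
  stopifnot(is(traj, "FlyTrajectory"))
  if (boundaryRadius >= arena(traj)@arenaRadius)
    stop("boundaryRadius must be inside the arena", call. = FALSE)
  r <- .radial(traj@x, traj@y)
  inside <- r <= boundaryRadius
  inside[is.na(inside)] <- FALSE
  # debounce: short spells are absorbed into the preceding spell
  if (debounce > 1L) {
    rl <- rle(inside)
    if (length(rl$lengths) > 1L) {
      for (k in 2:length(rl$values)) {
        if (rl$lengths[k] < debounce) rl$values[k] <- rl$values[k - 1L]
      }
      inside <- inverse.rle(rl)
      # re-merge adjacent equal spells
      inside <- inverse.rle(rle(inside))
    }
  }
  fps <- frameRate(traj)
  spells <- function(flag) {
    ep <- .episodesOf(flag)
    if (!nrow(ep)) {
      return(data.frame(entry_time = numeric(0), exit_time = numeric(0),
                        dwell_s = numeric(0)))
    }
    entry <- traj@time[ep$start_frame]
    exit <- ifelse(ep$end_frame < length(flag),
                   traj@time[pmin(ep$end_frame + 1L, length(flag))],
                   NA_real_)
    data.frame(entry_time = entry, exit_time = exit,
               dwell_s = exit - entry)
  }
  list(inside = spells(inside), outside = spells(!inside))
}
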