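# Trajectory-table and configuration file formats.
#
# Trajectory tables are TSV with header
#   fly_id  frame  time_s  x_cm  y_cm  flagged
# frames 0-based, coordinates arena-centred cm, missing positions as
# empty fields.

#' Write trajectories to a TSV table
#'
#' @param trajs a \linkS4class{FlyTrajectory} or list of them.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeTrajectoryTable <- function(trajs, path) {
  if (is(trajs, "FlyTrajectory")) trajs <- list(trajs)
  tabs <- lapply(trajs, function(tr) {
    data.frame(fly_id = flyId(tr),
               frame = seq_len(nFrames(tr)) - 1L,
               time_s = tr@time, x_cm = tr@x, y_cm = tr@y,
               flagged = as.integer(tr@flagged))
  })
  tab <- do.call(rbind, tabs)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read trajectories from a TSV table
#'
#' @param path file written by \code{\link{writeTrajectoryTable}}.
#' @param geom an \linkS4class{ArenaGeometry} for the loaded flies.
#' @param frameRate frames per second of the recording.
#' @return Named list of \linkS4class{FlyTrajectory} objects.
#' @export
readTrajectoryTable <- function(path, geom = arenaGeometry(),
                                frameRate = 30) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c(fly_id = "character"),
                           na.strings = "")
  need <- c("fly_id", "frame", "time_s", "x_cm", "y_cm", "flagged")
  missingCols <- setdiff(need, names(tab))
  if (length(missingCols))
    stop(sprintf("malformed trajectory table '%s': missing column(s) %s",
                 path, paste(missingCols, collapse = ", ")), call. = FALSE)
  out <- lapply(split(tab, tab$fly_id), function(d) {
    d <- d[order(d$frame), ]
    new("FlyTrajectory", flyId = d$fly_id[1L], time = d$time_s,
        x = d$x_cm, y = d$y_cm,
        flagged = as.logical(d$flagged) %in% TRUE,
        frameRate = frameRate, arena = geom)
  })
  out[unique(tab$fly_id)]
}

#' Write per-frame segmentation labels
#'
#' Parallel per-frame label table (TSV): frame, time_s, state, turn.
#'
#' @param seg a \linkS4class{SegmentLabeling} or \linkS4class{GroundTruth}.
#' @param path output path.
#' @param frameRate frames per second.
#' @return Invisibly, the path.
#' @export
writeLabelTable <- function(seg, path, frameRate = 30) {
  state <- states(seg)
  turn <- turnLabels(seg)
  if (!length(turn)) turn <- rep(NA_character_, length(state))
  tab <- data.frame(frame = seq_along(state) - 1L,
                    time_s = (seq_along(state) - 1L) / frameRate,
                    state = state, turn = turn)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Default analysis configuration
#'
#' All thresholds of the processing chain with their standard values:
#' 10-frame smoothing; Schmidt-trigger thresholds 0.05 and 0.1 cm/s;
#' 5-frame turn window with 0.3/1.3 rad thresholds; 2 mm/s angular-speed
#' floor; odor-on at 180 s with 5 s latency; odor zone 1.2 cm with a
#' conservative boundary option of 1.9 cm; 2 mm sharp-turn ring; alpha
#' 0.05; 50,000 permutations.
#'
#' @return Nested named list; the \code{stats$nPerm} entry is the one
#'   most commonly overridden for quick analyses.
#' @export
defaultPipelineConfig <- function() {
  list(
    arena = list(arenaRadius = 3.2, odorZoneRadius = 1.2,
                 odorBoundaryRadius = 1.2),
    epochs = list(odorOn = 180, latency = 5, duringLength = 180),
    kinematics = list(smoothingWindow = 10L, stopThreshold = 0.05,
                      runThreshold = 0.1, turnWindow = 5L,
                      smoothTurnThreshold = 0.3,
                      sharpTurnThreshold = 1.3,
                      minSpeedForAngular = 0.2,
                      transitDebounce = 2L,
                      ringHalfWidth = 0.2),
    stats = list(alpha = 0.05, nPerm = 50000L, ridge = 0,
                 standardize = TRUE),
    seed = 1L)
}

#' Read / write a pipeline configuration
#'
#' Configurations are stored as structured YAML mirroring
#' \code{\link{defaultPipelineConfig}}; absent entries fall back to the
#' defaults.
#'
#' @param path YAML file path.
#' @param config configuration list to write.
#' @return \code{readPipelineConfig}: the merged configuration list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  config <- defaultPipelineConfig()
  for (sec in names(user)) {
    if (is.list(user[[sec]]) && is.list(config[[sec]])) {
      for (key in names(user[[sec]]))
        config[[sec]][[key]] <- user[[sec]][[key]]
    } else {
      config[[sec]] <- user[[sec]]
    }
  }
  config
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
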