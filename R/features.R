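# The 17 motor parameters and auxiliary behavioral profiles.

#' Names of the 17 motor parameters
#'
#' Canonical order of the 17-dimensional behavioral representation.
#' Normalized-change parameters are (during - before)/before; ratio
#' parameters are during/before; turn-fraction parameters are computed on
#' the during period alone.
#'
#' @return Character vector of length 17.
#' @export
motorParameterNames <- function() {
  c("attraction_index", "time_inside_per_transit", "time_to_return",
    "radial_density_shift", "speed_inside", "speed_outside",
    "speed_crossing_inside", "speed_crossing_outside",
    "run_duration_ratio", "stop_duration_ratio",
    "run_probability_in", "run_probability_out",
    "angular_speed_inside", "angular_speed_outside",
    "smooth_turns_in", "smooth_turns_out", "sharp_turns_at_boundary")
}

# frames (indices) of traj falling in the half-open interval [a, b)
.epochFrames <- function(traj, interval) {
  which(traj@time >= interval[1] & traj@time < interval[2])
}

# normalized change (d - b)/b; NA when the denominator is not positive
.normChange <- function(d, b) {
  if (!is.finite(b) || b <= 0 || !is.finite(d)) return(NA_real_)
  (d - b) / b
}

.ratioOf <- function(d, b) {
  if (!is.finite(b) || b <= 0 || !is.finite(d)) return(NA_real_)
  d / b
}

# per-crossing mean speed in a window after the crossing; the fly value
# is the mean of per-crossing means
.crossingSpeed <- function(kin, times, crossTimes, winFrom = 1,
                           winTo = 2) {
  if (!length(crossTimes)) return(NA_real_)
  vals <- vapply(crossTimes, function(t0) {
    sel <- times >= t0 + winFrom & times <= t0 + winTo
    if (!any(sel)) return(NA_real_)
    mean(kin$speed[sel], na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

#' Compute the 17 motor parameters for one fly
#'
#' Implements the per-fly behavioral parameterization: occupancy change
#' in the odor zone (attraction index), transit statistics, radial
#' density shift, speeds inside/outside and on crossings, run/stop
#' duration and run-probability ratios, angular-speed changes, and turn
#' fractions. The attraction index compares raw times inside the zone;
#' the during epoch is shorter than before, but its entry-conditioned
#' start compensates, so the index is centred for unchanged behavior.
#' Parameters whose
#' before-period denominator is zero, or whose required events are
#' absent, are NA with the reason recorded in the \code{reasons}
#' attribute; excluded flies yield all-NA vectors.
#'
#' @param traj a (smoothed) \linkS4class{FlyTrajectory}.
#' @param kin kinematics from \code{\link{computeKinematics}}.
#' @param seg a turn-classified \linkS4class{SegmentLabeling}.
#' @param epochs an \linkS4class{EpochSet}.
#' @param transits optional transit list from \code{\link{detectTransits}};
#'   computed from the trajectory's odor-boundary radius if NULL.
#' @param ringHalfWidth half-width of the boundary ring for the
#'   sharp-turn fraction (cm; default 0.2, i.e. 2 mm).
#' @return Named numeric vector of length 17 with attributes
#'   \code{flyId}, \code{excluded} and \code{reasons}.
#' @export
computeFeatureVector <- function(traj, kin, seg, epochs, transits = NULL,
                                 ringHalfWidth = 0.2) {
  stopifnot(is(traj, "FlyTrajectory"), is(seg, "SegmentLabeling"),
            is(epochs, "EpochSet"))
  nm <- motorParameterNames()
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  reasons <- character(0)
  if (isExcluded(epochs)) {
    attributes(out) <- c(attributes(out),
                         list(flyId = flyId(traj), excluded = TRUE,
                              reasons = c(excluded = epochs@reason)))
    return(out)
  }
  if (is.null(transits)) transits <- detectTransits(traj)

  geomA <- arena(traj)
  zoneR <- geomA@odorZoneRadius
  boundR <- geomA@odorBoundaryRadius
  r <- .radial(traj@x, traj@y)
  insideZone <- !is.na(r) & r <= zoneR
  isRun <- seg@state == "run"
  before <- epochInterval(epochs, "before")
  during <- epochInterval(epochs, "during")
  fb <- .epochFrames(traj, before)
  fd <- .epochFrames(traj, during)

  epochStat <- function(frames, fun) fun(frames)

  # 1. attraction index: change in total time inside the odor zone.
  # Raw times are used (not per-second rates): the during epoch is
  # shorter than before, but its entry-conditioned start compensates,
  # leaving the index unbiased for behaviorally unchanged flies.
  occ <- function(fr) sum(insideZone[fr]) / frameRate(traj)
  out["attraction_index"] <- .normChange(occ(fd), occ(fb))

  # 2-3. transit medians (dwell inside / time outside per transit).
  # Spells are right-censored at the epoch end in BOTH epochs: dropping
  # spells that outlast the record would censor the shorter during
  # epoch more heavily and bias its median downward.
  medDwell <- function(tab, iv) {
    sel <- tab$entry_time >= iv[1] & tab$entry_time < iv[2]
    if (!any(sel)) return(NA_real_)
    entry <- tab$entry_time[sel]
    exitT <- tab$exit_time[sel]
    exitT[is.na(exitT)] <- iv[2]
    stats::median(pmin(exitT, iv[2]) - entry)
  }
  out["time_inside_per_transit"] <-
    .normChange(medDwell(transits$inside, during),
                medDwell(transits$inside, before))
  out["time_to_return"] <-
    .normChange(medDwell(transits$outside, during),
                medDwell(transits$outside, before))

  # 4. radial density shift: normalized change in mean radial distance
  out["radial_density_shift"] <-
    .normChange(mean(r[fd], na.rm = TRUE), mean(r[fb], na.rm = TRUE))

  # 5-6. mean speed inside / outside the odor zone
  mSpeed <- function(fr, inz) {
    sel <- intersect(fr, which(insideZone == inz))
    if (!length(sel)) NA_real_ else mean(kin$speed[sel], na.rm = TRUE)
  }
  out["speed_inside"] <- .normChange(mSpeed(fd, TRUE), mSpeed(fb, TRUE))
  out["speed_outside"] <- .normChange(mSpeed(fd, FALSE), mSpeed(fb, FALSE))

  # 7-8. crossing speeds (window 1-2 s after the crossing)
  crossIn <- function(iv) transits$inside$entry_time[
    transits$inside$entry_time >= iv[1] & transits$inside$entry_time < iv[2]]
  crossOut <- function(iv) transits$outside$entry_time[
    transits$outside$entry_time >= iv[1] &
      transits$outside$entry_time < iv[2]]
  out["speed_crossing_inside"] <-
    .normChange(.crossingSpeed(kin, traj@time, crossIn(during)),
                .crossingSpeed(kin, traj@time, crossIn(before)))
  out["speed_crossing_outside"] <-
    .normChange(.crossingSpeed(kin, traj@time, crossOut(during)),
                .crossingSpeed(kin, traj@time, crossOut(before)))

  # 9-10. median run / stop duration ratios
  epMedian <- function(tab, iv) {
    sel <- tab$start_time >= iv[1] & tab$start_time < iv[2]
    if (!any(sel)) NA_real_ else stats::median(tab$duration_s[sel])
  }
  out["run_duration_ratio"] <-
    .ratioOf(epMedian(seg@runs, during), epMedian(seg@runs, before))
  out["stop_duration_ratio"] <-
    .ratioOf(epMedian(seg@stops, during), epMedian(seg@stops, before))

  # 11-12. run probability in / out
  pRun <- function(fr, inz) {
    sel <- intersect(fr, which(insideZone == inz))
    if (!length(sel)) NA_real_ else mean(isRun[sel])
  }
  out["run_probability_in"] <- .ratioOf(pRun(fd, TRUE), pRun(fb, TRUE))
  out["run_probability_out"] <- .ratioOf(pRun(fd, FALSE), pRun(fb, FALSE))

  # 13-14. mean absolute angular speed inside / outside
  mAng <- function(fr, inz) {
    sel <- intersect(fr, which(insideZone == inz))
    v <- abs(kin$angular_speed[sel])
    if (!length(v) || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  out["angular_speed_inside"] <- .normChange(mAng(fd, TRUE), mAng(fb, TRUE))
  out["angular_speed_outside"] <-
    .normChange(mAng(fd, FALSE), mAng(fb, FALSE))

  # 15-16. smooth-turn fractions (during period): smooth frames / run frames
  if (length(seg@turn)) {
    smoothFrac <- function(inz) {
      sel <- intersect(fd, which(insideZone == inz & isRun))
      if (!length(sel)) NA_real_ else mean(seg@turn[sel] == "smooth")
    }
    out["smooth_turns_in"] <- smoothFrac(TRUE)
    out["smooth_turns_out"] <- smoothFrac(FALSE)

    # 17. fraction of during-period sharp turns within the boundary ring
    ev <- seg@events
    evDuring <- ev[ev$time_s >= during[1] & ev$time_s < during[2], ,
                   drop = FALSE]
    if (nrow(evDuring)) {
      evR <- .radial(evDuring$x_cm, evDuring$y_cm)
      out["sharp_turns_at_boundary"] <-
        mean(abs(evR - boundR) <= ringHalfWidth)
    } else {
      reasons <- c(reasons,
                   sharp_turns_at_boundary = "no sharp turns during odor")
    }
  } else {
    reasons <- c(reasons, turns = "turns not classified")
  }

  undef <- nm[is.na(out)]
  for (u in setdiff(undef, names(reasons)))
    reasons[u] <- "undefined (zero denominator or no events)"
  attributes(out) <- c(attributes(out),
                       list(flyId = flyId(traj), excluded = FALSE,
                            reasons = reasons))
  out
}

#' Assemble a feature matrix from per-fly vectors
#'
#' @param featureList list of vectors from
#'   \code{\link{computeFeatureVector}}.
#' @return Numeric matrix (flies x 17) with fly ids as row names.
#' @export
featureMatrix <- function(featureList) {
  m <- do.call(rbind, lapply(featureList, as.numeric))
  colnames(m) <- motorParameterNames()
  rownames(m) <- vapply(featureList, function(f) {
    id <- attr(f, "flyId")
    if (is.null(id)) NA_character_ else id
  }, character(1))
  m
}

.profileFrame <- function(edges, values, n, normalization) {
  structure(data.frame(bin_start = edges[-length(edges)],
                       bin_end = edges[-1L], value = values, n = n),
            normalization = normalization)
}

#' Odor-boundary crossing speed trace
#'
#' Speed around boundary crossings, crossings aligned at t = 0, averaged
#' over crossings within each period in bins of 0.16 s (5 frames at
#' 30 fps). The returned trace is during minus before.
#'
#' @param traj,kin trajectory and kinematics.
#' @param transits transit list from \code{\link{detectTransits}}.
#' @param epochs an \linkS4class{EpochSet}.
#' @param direction "in" (entries) or "out" (exits).
#' @param bin bin width in seconds.
#' @param window alignment window (s) around the crossing.
#' @return Profile data.frame (bin_start, bin_end, value, n) or NULL with
#'   a warning when a period has no crossing.
#' @export
crossingSpeedTrace <- function(traj, kin, transits, epochs,
                               direction = c("in", "out"), bin = 0.16,
                               window = c(-3, 3)) {
  direction <- match.arg(direction)
  if (isExcluded(epochs)) {
    warning("fly excluded: ", epochs@reason)
    return(NULL)
  }
  tab <- if (direction == "in") transits$inside else transits$outside
  edges <- seq(window[1], window[2], by = bin)
  mids <- utils::head(edges, -1L) + bin / 2
  traceFor <- function(iv) {
    cross <- tab$entry_time[tab$entry_time >= iv[1] &
                              tab$entry_time < iv[2]]
    if (!length(cross)) return(NULL)
    acc <- matrix(NA_real_, length(cross), length(mids))
    for (k in seq_along(cross)) {
      rel <- traj@time - cross[k]
      cut <- findInterval(rel, edges, rightmost.closed = TRUE)
      ok <- cut >= 1L & cut <= length(mids) & !is.na(kin$speed)
      if (any(ok))
        acc[k, ] <- tapply(kin$speed[ok],
                           factor(cut[ok], levels = seq_along(mids)),
                           mean)
    }
    colMeans(acc, na.rm = TRUE)
  }
  tb <- traceFor(epochInterval(epochs, "before"))
  td <- traceFor(epochInterval(epochs, "during"))
  if (is.null(tb) || is.null(td)) {
    warning("no ", direction, "-crossing in one of the periods")
    return(NULL)
  }
  .profileFrame(edges, td - tb, n = 1L, normalization = "before-subtracted")
}

#' Area-normalized radial density profile
#'
#' Occupancy fraction per equal-width radial bin, divided by the area of
#' each annulus, so a spatially uniform walker gives a flat profile.
#'
#' @param traj a \linkS4class{FlyTrajectory}.
#' @param interval time interval [start, end) in seconds.
#' @param nBins number of radial bins (default 12).
#' @return Profile data.frame; values integrate (sum of value * area)
#'   to the total occupancy fraction.
#' @export
radialDensityProfile <- function(traj, interval, nBins = 12L) {
  if (nBins < 2L) stop("nBins must be >= 2", call. = FALSE)
  fr <- .epochFrames(traj, interval)
  if (!length(fr)) stop("epoch is empty", call. = FALSE)
  R <- arena(traj)@arenaRadius
  edges <- seq(0, R, length.out = nBins + 1L)
  r <- .radial(traj@x[fr], traj@y[fr])
  r <- r[!is.na(r)]
  r[r >= R] <- R - 1e-9
  counts <- tabulate(findInterval(r, edges), nbins = nBins)
  areas <- pi * diff(edges^2)
  .profileFrame(edges, (counts / length(r)) / areas, n = counts,
                normalization = "area-normalized")
}

#' Cohort occupancy time course
#'
#' Fraction of flies inside the odor zone as a function of time since
#' trial start, averaged within bins (default 5 s).
#'
#' @param cohort list of \linkS4class{FlyTrajectory} objects with aligned
#'   trial clocks.
#' @param bin bin width in seconds.
#' @return Profile data.frame with the mean fraction of flies inside per
#'   bin (column n = number of flies contributing).
#' @export
occupancyTimeCourse <- function(cohort, bin = 5) {
  if (!length(cohort)) stop("empty cohort", call. = FALSE)
  endT <- min(vapply(cohort, function(tr) max(tr@time), numeric(1)))
  edges <- seq(0, endT, by = bin)
  if (length(edges) < 2L) stop("record shorter than one bin", call. = FALSE)
  mids <- utils::head(edges, -1L)
  perFly <- vapply(cohort, function(tr) {
    inz <- .radial(tr@x, tr@y) <= arena(tr)@odorZoneRadius
    cut <- findInterval(tr@time, edges, rightmost.closed = TRUE)
    ok <- cut >= 1L & cut <= length(mids) & !is.na(inz)
    as.numeric(tapply(inz[ok], factor(cut[ok], levels = seq_along(mids)),
                      mean))
  }, numeric(length(mids)))
  .profileFrame(edges, rowMeans(perFly, na.rm = TRUE),
                n = length(cohort), normalization = "fraction-inside")
}

#' Radial speed profile for a point-source arena
#'
#' Mean speed in concentric radial bins (default 10), normalized per fly
#' by the maximum bin speed. Bins the fly never visits are NA.
#'
#' @param traj a \linkS4class{FlyTrajectory} (point-source arenas are
#'   typically 10 cm in diameter).
#' @param kin kinematics from \code{\link{computeKinematics}}.
#' @param nBins number of concentric bins.
#' @return Profile data.frame of max-normalized mean speed per bin.
#' @export
pointSourceRadialSpeed <- function(traj, kin, nBins = 10L) {
  if (nBins < 2L) stop("nBins must be >= 2", call. = FALSE)
  R <- arena(traj)@arenaRadius
  edges <- seq(0, R, length.out = nBins + 1L)
  r <- .radial(traj@x, traj@y)
  r[r >= R] <- R - 1e-9
  cut <- findInterval(r, edges)
  ok <- !is.na(cut) & !is.na(kin$speed)
  means <- as.numeric(tapply(kin$speed[ok],
                             factor(cut[ok], levels = seq_len(nBins)),
                             mean))
  counts <- tabulate(cut[ok], nbins = nBins)
  mx <- max(means, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0)
    stop("no visited bin with positive speed", call. = FALSE)
  .profileFrame(edges, means / mx, n = counts,
                normalization = "max-normalized")
}
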