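# Centroid tracking: background subtraction, thresholding, largest
# connected bright component, jump-rule error flagging and repair.

#' Estimate the static background of a frame stack
#'
#' The pixel-wise mean image across all frames. With a single small
#' moving fly, the fly contributes negligibly to the mean, so subtracting
#' it leaves the fly as the only bright object on a dark background.
#'
#' @param stack a \linkS4class{FrameStack} with at least 2 frames.
#' @return A numeric matrix of the same size as one frame.
#' @export
estimateBackground <- function(stack) {
  stopifnot(is(stack, "FrameStack"))
  if (nFrames(stack) < 2L)
    stop("background estimation needs at least 2 frames", call. = FALSE)
  rowMeans(stack@frames, dims = 2L)
}

#' Pixel calibration from the known arena diameter
#'
#' @param arenaDiameterPx arena diameter measured in the image (px).
#' @param arenaDiameterCm physical arena diameter (cm); 6.4 cm for the
#'   ring assay, giving 0.1 mm/px at 640 px.
#' @param centerPx arena centre as (row, col); defaults to unknown (NA).
#' @return A \linkS4class{Calibration} with pixelScale in mm/px.
#' @examples
#' calibratePixels(640, 6.4)   # 0.1 mm per pixel
#' @export
calibratePixels <- function(arenaDiameterPx, arenaDiameterCm,
                            centerPx = c(NA_real_, NA_real_)) {
  .assertScalarPositive(arenaDiameterPx, "arenaDiameterPx")
  .assertScalarPositive(arenaDiameterCm, "arenaDiameterCm")
  new("Calibration",
      pixelScale = 10 * arenaDiameterCm / arenaDiameterPx,
      centerPx = as.numeric(centerPx),
      arenaRadiusPx = arenaDiameterPx / 2)
}

# threshold a background-subtracted frame; Otsu on the positive part
.frameThreshold <- function(sub, method, fixed) {
  if (method == "fixed") return(fixed)
  mx <- max(sub)
  if (mx <= 0) return(Inf)
  EBImage::otsu(EBImage::Image(sub / mx), range = c(0, 1)) * mx
}

#' Track the fly centroid through a frame stack
#'
#' Per frame: subtract the background, threshold the difference image
#' (Otsu by default), and take the intensity-weighted centroid of the
#' largest connected bright component. Frames whose implied instantaneous
#' speed exceeds \code{jumpLimit} are flagged as tracking errors and
#' their positions replaced by linear interpolation between neighbouring
#' unflagged frames; frames with no bright object are marked missing.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param background matrix from \code{\link{estimateBackground}}.
#' @param calib a \linkS4class{Calibration} (pixelScale in mm/px).
#' @param jumpLimit speed limit in mm/s above which a frame is treated as
#'   a mis-assignment (default 30 mm/s). Set
#'   \code{jumpPerFrame = TRUE} to interpret \code{jumpLimit} as mm per
#'   frame instead, the alternative reading of the published 3 mm figure.
#' @param jumpPerFrame interpret jumpLimit per frame rather than per second.
#' @param thresholdMethod "otsu" or "fixed".
#' @param fixedThreshold threshold used when \code{thresholdMethod = "fixed"}.
#' @param maxMissingFrac error if more than this fraction of frames has
#'   no detectable fly (default 0.2).
#' @param minContrast minimum background-subtracted peak intensity for a
#'   frame to count as containing the fly; below it the frame is marked
#'   missing (guards against thresholding pure sensor noise).
#' @return A \linkS4class{RawTrack}.
#' @export
trackCentroid <- function(stack, background, calib,
                          jumpLimit = 30, jumpPerFrame = FALSE,
                          thresholdMethod = c("otsu", "fixed"),
                          fixedThreshold = 0.1,
                          maxMissingFrac = 0.2, minContrast = 0.05) {
  stopifnot(is(stack, "FrameStack"), is(calib, "Calibration"))
  thresholdMethod <- match.arg(thresholdMethod)
  d <- dim(stack@frames)
  if (!all(dim(background) == d[1:2]))
    stop("background does not match the frame shape", call. = FALSE)
  n <- d[3]
  rowPx <- rep(NA_real_, n); colPx <- rep(NA_real_, n)
  missing <- logical(n); reason <- rep("", n)

  for (i in seq_len(n)) {
    sub <- stack@frames[, , i] - background
    sub[sub < 0] <- 0
    if (max(sub) < minContrast) {
      missing[i] <- TRUE
      reason[i] <- "no object above the contrast floor"
      next
    }
    thr <- .frameThreshold(sub, thresholdMethod, fixedThreshold)
    mask <- sub > thr
    if (!any(mask)) {
      missing[i] <- TRUE
      reason[i] <- "no bright object above threshold"
      next
    }
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    labels <- as.integer(EBImage::imageData(lab))
    sizes <- tabulate(labels)
    keep <- which.max(sizes)
    sel <- which(labels == keep)
    w <- sub[sel]
    rows <- ((sel - 1L) %% d[1]) + 1L
    cols <- ((sel - 1L) %/% d[1]) + 1L
    rowPx[i] <- sum(rows * w) / sum(w)
    colPx[i] <- sum(cols * w) / sum(w)
  }

  if (mean(missing) > maxMissingFrac)
    stop(sprintf("fly not found on %.0f%% of frames (limit %.0f%%)",
                 100 * mean(missing), 100 * maxMissingFrac), call. = FALSE)

  # jump rule: implied instantaneous speed between consecutive present
  # frames; the later frame of an excessive jump is flagged
  limitPerFrame <- if (jumpPerFrame) jumpLimit else
    jumpLimit / stack@frameRate
  flagged <- logical(n)
  present <- which(!missing)
  if (length(present) >= 2L) {
    for (k in 2:length(present)) {
      i0 <- present[k - 1L]; i1 <- present[k]
      distMm <- sqrt((rowPx[i1] - rowPx[i0])^2 +
                       (colPx[i1] - colPx[i0])^2) * calib@pixelScale
      if (distMm / (i1 - i0) > limitPerFrame && !flagged[i0]) {
        flagged[i1] <- TRUE
        reason[i1] <- "instantaneous speed above jump limit"
      }
    }
  }

  # repair flagged frames by linear interpolation between unflagged,
  # present anchors
  anchors <- which(!flagged & !missing)
  if (length(anchors) >= 2L) {
    fix <- which(flagged)
    rowPx[fix] <- stats::approx(anchors, rowPx[anchors], xout = fix,
                                rule = 2)$y
    colPx[fix] <- stats::approx(anchors, colPx[anchors], xout = fix,
                                rule = 2)$y
  }

  new("RawTrack", rowPx = rowPx, colPx = colPx, flagged = flagged,
      missing = missing, reason = reason, frameRate = stack@frameRate)
}

#' Convert a RawTrack to an arena-centred trajectory
#'
#' @param raw a \linkS4class{RawTrack}.
#' @param calib a \linkS4class{Calibration} with a known arena centre.
#' @param geom an \linkS4class{ArenaGeometry}.
#' @param flyId identifier for the resulting trajectory.
#' @return A \linkS4class{FlyTrajectory} (missing frames as NA).
#' @export
asTrajectory <- function(raw, calib, geom = arenaGeometry(),
                         flyId = "tracked") {
  stopifnot(is(raw, "RawTrack"), is(calib, "Calibration"))
  if (any(is.na(calib@centerPx)))
    stop("calibration must carry the arena centre", call. = FALSE)
  cm <- .pxToCm(raw@rowPx, raw@colPx, calib)
  n <- length(raw@rowPx)
  new("FlyTrajectory", flyId = flyId,
      time = (seq_len(n) - 1L) / raw@frameRate,
      x = cm[, "x"], y = cm[, "y"], flagged = raw@flagged,
      frameRate = raw@frameRate, arena = geom)
}
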