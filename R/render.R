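# Rendering of trajectories as synthetic grayscale videos: a single
# bright Gaussian blob over a static textured dark background.

# map arena-centred cm to (row, col) pixel coordinates
.cmToPx <- function(x, y, calib) {
  cbind(row = calib@centerPx[1] - y * 10 / calib@pixelScale,
        col = calib@centerPx[2] + x * 10 / calib@pixelScale)
}

# map (row, col) pixel coordinates to arena-centred cm
.pxToCm <- function(rowPx, colPx, calib) {
  cbind(x = (colPx - calib@centerPx[2]) * calib@pixelScale / 10,
        y = (calib@centerPx[1] - rowPx) * calib@pixelScale / 10)
}

# default calibration placing the arena centre mid-image
.defaultCalibration <- function(vconf, arenaRadiusCm) {
  centre <- (vconf@imageSize + 1) / 2
  new("Calibration", pixelScale = vconf@pixelScale,
      centerPx = c(centre, centre),
      arenaRadiusPx = arenaRadiusCm * 10 / vconf@pixelScale)
}

#' Render a trajectory as a frame stack
#'
#' Produces one grayscale frame per trajectory sample: a Gaussian blob of
#' the configured sigma and intensity at the mapped pixel position, added
#' to a static textured background, plus i.i.d. Gaussian sensor noise.
#'
#' @param traj a \linkS4class{FlyTrajectory} (no missing positions).
#' @param vconf a \linkS4class{VideoConfig}.
#' @param seed seed for the per-frame noise.
#' @param calib optional \linkS4class{Calibration}; by default the arena
#'   centre is placed at the image centre.
#' @return A list with elements \code{stack} (\linkS4class{FrameStack})
#'   and \code{calibration} (\linkS4class{Calibration}).
#' @export
renderVideo <- function(traj, vconf, seed,
                        calib = .defaultCalibration(vconf,
                          arena(traj)@arenaRadius)) {
  stopifnot(is(traj, "FlyTrajectory"), is(vconf, "VideoConfig"))
  validObject(vconf)
  n <- nFrames(traj)
  size <- vconf@imageSize
  pos <- .cmToPx(traj@x, traj@y, calib)
  margin <- 3 * vconf@blobSigma
  bad <- which(pos[, 1] < 1 + margin | pos[, 1] > size - margin |
                 pos[, 2] < 1 + margin | pos[, 2] > size - margin)
  if (length(bad))
    stop(sprintf("blob would leave the image at frame %d", bad[1]),
         call. = FALSE)

  set.seed(vconf@textureSeed)
  background <- matrix(vconf@backgroundIntensity +
                         stats::rnorm(size^2, 0, vconf@textureSd),
                       size, size)

  set.seed(as.integer(seed))
  frames <- array(0, dim = c(size, size, n))
  halfwidth <- ceiling(4 * vconf@blobSigma)
  for (i in seq_len(n)) {
    fr <- background +
      matrix(stats::rnorm(size^2, 0, vconf@noiseSd), size, size)
    r0 <- pos[i, 1]; c0 <- pos[i, 2]
    rows <- max(1L, floor(r0 - halfwidth)):min(size, ceiling(r0 + halfwidth))
    cols <- max(1L, floor(c0 - halfwidth)):min(size, ceiling(c0 + halfwidth))
    blob <- vconf@blobIntensity *
      exp(-(outer((rows - r0)^2, (cols - c0)^2, "+")) /
            (2 * vconf@blobSigma^2))
    fr[rows, cols] <- fr[rows, cols] + blob
    frames[, , i] <- fr
  }
  list(stack = new("FrameStack", frames = frames,
                   frameRate = frameRate(traj)),
       calibration = calib)
}
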