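# Internal numeric helpers shared across modules.

# wrap angle(s) to (-pi, pi]
.wrapAngle <- function(a) {
  ((a + pi) %% (2 * pi)) - pi
}

# forward fill of NA values; leading NAs stay NA
.fillForward <- function(x) {
  ok <- !is.na(x)
  idx <- cummax(ok * seq_along(x))
  idx[idx == 0L] <- NA_integer_
  x[idx]
}

# centred moving average with shrunken symmetric windows at the edges.
# Even window lengths use a centred kernel with half weights on the two
# outermost points (total weight = window), which keeps linear motion
# invariant in the interior.
.movingAverage <- function(x, window) {
  n <- length(x)
  if (window == 1L) return(x)
  w <- if (window %% 2L == 1L) rep(1, window) / window
       else c(0.5, rep(1, window - 1L), 0.5) / window
  sm <- as.numeric(stats::filter(x, w, sides = 2))
  for (i in which(is.na(sm))) {
    h <- min(i - 1L, n - i)
    sm[i] <- mean(x[(i - h):(i + h)])
  }
  sm
}

# log-normal draws parameterised by the median and a log-scale sd
.rlnormMedian <- function(n, median, sdlog) {
  stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
}

.assertScalarPositive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", what),
         call. = FALSE)
  }
  invisible(x)
}

# radial distance from the arena centre
.radial <- function(x, y) sqrt(x^2 + y^2)

# run-length episodes of a logical vector: data.frame of start/end frame
# indices (1-based, inclusive) where the condition holds
.episodesOf <- function(flag) {
  r <- rle(flag)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  keep <- r$values
  data.frame(start_frame = start[keep], end_frame = end[keep])
}
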