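test_that("moving-average smoothing preserves constants and lines, damps noise", {
  n <- 300
  still <- makeTrajectory(rep(1, n), rep(-0.5, n))
  sm <- smoothTrack(still, 10)
  expect_equal(sm@x, rep(1, n))
  expect_equal(sm@y, rep(-0.5, n))

  line <- makeTrajectory(seq(-1, 1, length.out = n),
                         seq(0.5, -0.5, length.out = n))
  smLine <- smoothTrack(line, 10)
  interior <- 11:(n - 11)
  expect_equal(smLine@x[interior], line@x[interior], tolerance = 1e-12)
  expect_equal(smLine@y[interior], line@y[interior], tolerance = 1e-12)

  # white noise of sd sigma on a line: interior residual sd ~ sigma/sqrt(10)
  set.seed(42)
  sigma <- 0.05
  noisy <- makeTrajectory(line@x + rnorm(n, 0, sigma),
                          line@y + rnorm(n, 0, sigma))
  smNoisy <- smoothTrack(noisy, 10)
  resid <- smNoisy@x[interior] - line@x[interior]
  # closed form: sd of a weighted mean is sigma * sqrt(sum(w^2)); the
  # centred 10-frame kernel has half weights on its outer points
  w <- c(0.5, rep(1, 9), 0.5) / 10
  expect_equal(sd(resid), sigma * sqrt(sum(w^2)), tolerance = 0.1)
  # close to the nominal sigma/sqrt(10) of a plain 10-point mean
  expect_equal(sd(resid), sigma / sqrt(10), tolerance = 0.15)

  expect_error(smoothTrack(makeTrajectory(1:5 / 10, 1:5 / 10), 10),
               "longer than")
})

test_that("kinematics: straight motion, circular motion, slow-speed masking", {
  fps <- 30
  n <- 200
  straight <- makeTrajectory((0:(n - 1)) * 0.5 / fps - 1.5, rep(0, n))
  kin <- computeKinematics(straight)
  expect_equal(kin$speed[1:(n - 1)], rep(0.5, n - 1), tolerance = 1e-12)
  expect_equal(kin$angular_speed[2:(n - 1)], rep(0, n - 2),
               tolerance = 1e-12)

  # circle of radius r at speed v: angular speed ~ v / r
  r <- 1.5; v <- 0.6
  omega <- v / r
  tt <- (0:(n - 1)) / fps
  circ <- makeTrajectory(r * cos(omega * tt), r * sin(omega * tt))
  kinC <- computeKinematics(circ)
  expect_equal(mean(kinC$angular_speed, na.rm = TRUE), omega,
               tolerance = 0.01)

  # below the 2 mm/s floor angular speed is masked
  slow <- makeTrajectory((0:(n - 1)) * 0.1 / fps - 0.3, rep(0, n))
  kinS <- computeKinematics(slow)
  expect_true(all(is.na(kinS$angular_speed)))
  expect_error(computeKinematics(makeTrajectory(c(0, 0.1), c(0, 0))),
               "3 frames")
})

test_that("Schmidt trigger: stated examples and hysteresis behavior", {
  fps <- 30
  seg <- segmentRunsStops(rep(0.03, 50), frameRate = fps)
  expect_true(all(states(seg) == "stop"))
  expect_equal(nrow(stopEpisodes(seg)), 1)
  expect_equal(stopEpisodes(seg)$duration_s, 50 / fps)

  # dead-band frames continue the previous state
  seg2 <- segmentRunsStops(c(0.2, 0.2, 0.07, 0.07, 0.2), frameRate = fps)
  expect_true(all(states(seg2) == "run"))
  expect_equal(nrow(runEpisodes(seg2)), 1)

  # initial dead band is backfilled from the first decisive frame
  seg3 <- segmentRunsStops(c(0.07, 0.07, 0.03, 0.2), frameRate = fps)
  expect_equal(states(seg3), c("stop", "stop", "stop", "run"))

  expect_error(segmentRunsStops(rep(0.07, 10)), "undeterminable")
  expect_error(segmentRunsStops(1:5 / 10, stopThreshold = 0.2,
                                runThreshold = 0.1), "below")
})

test_that("Schmidt trigger agrees with a brute-force reference on random traces", {
  set.seed(99)
  for (rep in 1:300) {
    n <- sample(5:40, 1)
    speed <- sample(c(0.03, 0.07, 0.2), n, replace = TRUE)
    oracle <- schmidtOracle(speed, 0.05, 0.1)
    if (is.null(oracle)) {
      expect_error(segmentRunsStops(speed))
    } else {
      expect_identical(states(segmentRunsStops(speed)), oracle)
    }
  }
})

test_that("episodes tile the record and respect the short-stop bias allowance", {
  sim <- simulateFly(shortConfig(), seed = 21)
  a <- analyzeFly(sim$trajectory, shortPipelineConfig())
  seg <- a$segmentation
  covered <- sum(runEpisodes(seg)$end_frame -
                   runEpisodes(seg)$start_frame + 1) +
    sum(stopEpisodes(seg)$end_frame - stopEpisodes(seg)$start_frame + 1)
  expect_equal(covered, nFrames(sim$trajectory))
  # agreement with ground truth ignoring sub-100-ms (<= 3 frame) stops
  gt <- states(sim$truth)
  gtStops <- flywalkr:::.episodesOf(gt == "stop")
  long <- gtStops[gtStops$end_frame - gtStops$start_frame + 1 > 3, ]
  found <- vapply(seq_len(nrow(long)), function(k) {
    mid <- (long$start_frame[k] + long$end_frame[k]) %/% 2
    states(seg)[mid] == "stop"
  }, logical(1))
  expect_gt(mean(found), 0.95)
})

test_that("turn classification: straight walks, injected turns, rotation invariance", {
  fps <- 30
  n <- 200
  straight <- makeTrajectory((0:(n - 1)) * 0.5 / fps - 1.5, rep(0, n))
  kin <- computeKinematics(straight)
  seg <- segmentRunsStops(kin$speed, frameRate = fps)
  seg <- classifyTurns(straight, kin, seg)
  expect_true(all(turnLabels(seg) == "none"))
  expect_equal(nrow(sharpTurnEvents(seg)), 0)

  # a 1.5 rad heading change within 5 frames -> exactly one sharp turn
  heading <- c(rep(0, 100), cumsum(rep(0.3, 5)), rep(1.5, 95))
  step <- 0.5 / fps
  x <- cumsum(c(0, step * cos(heading))) - 1.5
  y <- cumsum(c(0, step * sin(heading))) - 0.5
  turnTraj <- makeTrajectory(x, y)
  kinT <- computeKinematics(turnTraj)
  segT <- segmentRunsStops(kinT$speed, frameRate = fps)
  segT <- classifyTurns(turnTraj, kinT, segT)
  expect_equal(nrow(sharpTurnEvents(segT)), 1)
  expect_equal(abs(sharpTurnEvents(segT)$magnitude_rad), 1.5,
               tolerance = 1e-6)

  # labels invariant under global rotation of the trajectory
  th <- 1.1
  rot <- makeTrajectory(cos(th) * x - sin(th) * y,
                        sin(th) * x + cos(th) * y)
  kinR <- computeKinematics(rot)
  segR <- segmentRunsStops(kinR$speed, frameRate = fps)
  segR <- classifyTurns(rot, kinR, segR)
  expect_identical(turnLabels(segR), turnLabels(segT))

  expect_error(classifyTurns(straight, kin, seg, window = 500), "window")
})

test_that("sharp turns injected by the simulator are recovered at high precision/recall", {
  # The trailing 5-frame statistic localizes an event up to 4 frames
  # after the heading jump, so matches are scored within 5 frames.
  # Wall contacts also turn the heading abruptly; they are genuine sharp
  # direction changes but not labelled events, so the rim is excluded.
  tol <- 5L
  tp <- 0L; fp <- 0L; fn <- 0L
  for (seed in 1:4) {
    sim <- simulateFly(shortConfig(), seed = seed)
    tr <- sim$trajectory
    rimR <- arena(tr)@arenaRadius - 0.15
    kin <- computeKinematics(tr)
    seg <- segmentRunsStops(kin$speed, frameRate = frameRate(tr))
    seg <- classifyTurns(tr, kin, seg)
    ev <- sharpTurnEvents(seg)
    gt <- sharpTurnEvents(sim$truth)
    got <- ev$frame[sqrt(ev$x_cm^2 + ev$y_cm^2) < rimR]
    want <- gt$frame[sqrt(gt$x_cm^2 + gt$y_cm^2) < rimR]
    matched <- vapply(want, function(f) any(abs(got - f) <= tol),
                      logical(1))
    usedGot <- vapply(got, function(f) any(abs(want - f) <= tol),
                      logical(1))
    tp <- tp + sum(matched); fn <- fn + sum(!matched)
    fp <- fp + sum(!usedGot)
  }
  recall <- tp / (tp + fn)
  precision <- tp / (tp + fp)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("epoch delineation follows the entry-conditioned during rule", {
  fps <- 30
  n <- 360 * fps
  # fly inside the zone at odor-on: during = [185, 360)
  inside <- makeTrajectory(rep(0.5, n), rep(0, n))
  epIn <- delineateEpochs(inside)
  expect_equal(epochInterval(epIn, "before"), c(0, 180))
  expect_equal(epochInterval(epIn, "during"), c(185, 360))

  # fly outside until t = 200 s: during starts at first entry
  x <- c(rep(2.5, 200 * fps), rep(0.5, n - 200 * fps))
  outThenIn <- makeTrajectory(x, rep(0, n))
  epOut <- delineateEpochs(outThenIn)
  expect_equal(epochInterval(epOut, "during")[1], 200, tolerance = 1 / fps)
  expect_equal(epochInterval(epOut, "during")[2], 360)

  # never entering -> excluded with reason
  never <- makeTrajectory(rep(2.5, n), rep(0, n))
  epNever <- delineateEpochs(never)
  expect_true(isExcluded(epNever))
  expect_match(epNever@reason, "never entered")

  # epochs partition the record
  iv <- rbind(epochInterval(epIn, "before"), epochInterval(epIn, "during"),
              epochInterval(epIn, "after"))
  expect_equal(iv[1, 1], 0)
  expect_equal(iv[3, 2], n / fps)
  expect_true(all(iv[, 2] >= iv[, 1]))
})

test_that("transit detection: single crossing, debounce, ground-truth recovery", {
  fps <- 30
  # monotone inward crossing -> one open-ended inside transit
  r <- seq(3, 0.2, length.out = 300)
  mono <- makeTrajectory(r, rep(0, 300))
  trs <- detectTransits(mono)
  expect_equal(nrow(trs$inside), 1)
  expect_true(is.na(trs$inside$exit_time))

  # a 1-frame touch with debounce 2 -> no transit
  x <- c(rep(2, 50), 1.15, rep(2, 50))
  touch <- makeTrajectory(x, rep(0, 101))
  expect_equal(nrow(detectTransits(touch, debounce = 2)$inside), 0)
  expect_equal(nrow(detectTransits(touch, debounce = 1)$inside), 1)

  # crossings of a simulated walker recovered within one frame
  sim <- simulateFly(shortConfig(), seed = 31)
  tr <- sim$trajectory
  rr <- sqrt(tr@x^2 + tr@y^2)
  inside <- rr <= arena(tr)@odorBoundaryRadius
  rawEntries <- which(diff(inside) == 1) + 1
  got <- detectTransits(tr, debounce = 1)$inside$entry_time
  gotFrames <- round(got * fps) + 1
  for (f in gotFrames)
    expect_true(any(abs(rawEntries - f) <= 1) || f == 1)
})
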