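# builds a trajectory with prescribed seconds inside the odor zone per
# epoch: circular motion at radius 0.6 (inside) or 2.4 cm (outside);
# the fly is inside at odor-on so the during epoch is [185, 360)
occupancyTrajectory <- function(insideSecBefore, insideSecDuring,
                                fps = 30) {
  n <- 360 * fps
  tt <- (0:(n - 1)) / fps
  inside <- logical(n)
  before <- tt < 180
  inside[before] <- tt[before] < insideSecBefore
  inside[!before] <- tt[!before] < 185 + insideSecDuring
  r <- ifelse(inside, 0.6, 2.4)
  omega <- 0.5 / r   # constant speed 0.5 cm/s along circles
  theta <- cumsum(omega / fps)
  makeTrajectory(r * cos(theta), r * sin(theta))
}

test_that("feature vector has exactly the 17 named motor parameters", {
  expect_length(motorParameterNames(), 17)
  sim <- simulateFly(shortConfig(), seed = 2)
  a <- analyzeFly(sim$trajectory, shortPipelineConfig())
  expect_named(a$features, motorParameterNames())
  expect_length(a$features, 17)
})

test_that("attraction index matches the occupancy-fold construction", {
  # 60 s inside before, 150 s inside during: a 2.5-fold increase in
  # time spent inside, i.e. attraction index 1.5
  traj <- occupancyTrajectory(60, 150)
  conf <- defaultPipelineConfig()
  conf$kinematics$smoothingWindow <- 1L
  a <- analyzeFly(traj, conf)
  expect_false(isExcluded(a$epochs))
  expect_equal(unname(a$features["attraction_index"]), 1.5,
               tolerance = 0.02)
})

test_that("null cohorts give normalized changes near 0 and ratios near 1", {
  # full-length trials: the entry-conditioned during epoch needs the
  # nominal 3-min odor period for its start bias to stay negligible
  sims <- simulateCohort(walkerConfig(), 12, seed = 81)
  conf <- defaultPipelineConfig()
  conf$kinematics$smoothingWindow <- 1L
  M <- featureMatrix(lapply(sims, function(s)
    analyzeFly(s$trajectory, conf)$features))
  changes <- c("attraction_index", "radial_density_shift", "speed_inside",
               "speed_outside", "angular_speed_inside",
               "angular_speed_outside")
  ratios <- c("run_duration_ratio", "stop_duration_ratio",
              "run_probability_in", "run_probability_out")
  for (p in changes)
    expect_lt(abs(median(M[, p], na.rm = TRUE)), 0.35)
  for (p in ratios) {
    v <- median(M[, p], na.rm = TRUE)
    expect_gt(v, 0.6); expect_lt(v, 1.6)
  }
  expect_true(all(M[, "sharp_turns_at_boundary"] >= 0 &
                    M[, "sharp_turns_at_boundary"] <= 1, na.rm = TRUE))
  expect_true(all(M[, c("smooth_turns_in", "smooth_turns_out")] >= 0 &
                    M[, c("smooth_turns_in", "smooth_turns_out")] <= 1,
                  na.rm = TRUE))
})

test_that("a configured during/before fold-change is recovered by the ratios", {
  sims <- simulateCohort(foldChangeConfig(0.5, durationBefore = 60,
                                          durationDuring = 60),
                         12, seed = 17)
  conf <- shortPipelineConfig()
  M <- featureMatrix(lapply(sims, function(s)
    analyzeFly(s$trajectory, conf)$features))
  expect_equal(median(M[, "run_duration_ratio"], na.rm = TRUE), 0.5,
               tolerance = 0.25)
  expect_equal(median(M[, "stop_duration_ratio"], na.rm = TRUE), 0.5,
               tolerance = 0.25)
})

test_that("a configured fold-change in sharp-turn rate is recovered from events", {
  # events within 1.5 mm of the rim are excluded: wall reflections also
  # turn the heading abruptly but are not part of the Poisson turn
  # process whose rate is being estimated
  conf <- fullPipelineConfig()
  rateRatio <- function(a, rimR) {
    seg <- a$segmentation; ep <- a$epochs
    runs <- runEpisodes(seg)
    runTime <- function(iv) sum(pmax(0, pmin(runs$end_time, iv[2]) -
                                         pmax(runs$start_time, iv[1])))
    ev <- sharpTurnEvents(seg)
    ev <- ev[sqrt(ev$x_cm^2 + ev$y_cm^2) < rimR, ]
    nEv <- function(iv) sum(ev$time_s >= iv[1] & ev$time_s < iv[2])
    b <- epochInterval(ep, "before"); d <- epochInterval(ep, "during")
    (nEv(d) / runTime(d)) / (nEv(b) / runTime(b))
  }
  for (fold in c(0.5, 2)) {
    base <- contextParams()
    mod <- contextParams(sharpTurnRate = base@sharpTurnRate * fold)
    cfg <- walkerConfig(before = base, during = mod)
    vals <- c()
    for (sd in c(11, 22)) {
      sims <- simulateCohort(cfg, 15, seed = sd)
      for (s in sims) {
        a <- analyzeFly(s$trajectory, conf)
        if (isExcluded(a$epochs)) next
        vals <- c(vals, rateRatio(a, arena(s$trajectory)@arenaRadius - 0.15))
      }
    }
    est <- median(vals, na.rm = TRUE)
    expect_lt(abs(est / fold - 1), 0.15)
  }
})

test_that("excluded flies yield all-NA features with the recorded reason", {
  n <- 360 * 30
  never <- makeTrajectory(rep(2.5, n), rep(0, n))
  conf <- defaultPipelineConfig()
  conf$kinematics$smoothingWindow <- 1L
  a <- analyzeFly(never, conf)
  expect_true(all(is.na(a$features)))
  expect_true(attr(a$features, "excluded"))
  expect_match(attr(a$features, "reasons")["excluded"], "never entered")
})

test_that("radial density profile is flat for uniform points, concentrated for a ring", {
  set.seed(5)
  n <- 60000
  R <- 3.2
  r <- R * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  geom <- arenaGeometry()
  unif <- new("FlyTrajectory", flyId = "u", time = (0:(n - 1)) / 30,
              x = r * cos(th), y = r * sin(th),
              flagged = rep(FALSE, n), frameRate = 30, arena = geom)
  prof <- radialDensityProfile(unif, c(0, n / 30))
  dens <- prof$value * pi * R^2   # flat profile should sit near 1/area
  expect_true(all(abs(dens - 1) < 0.15))
  # profile integrates to total occupancy
  areas <- pi * (prof$bin_end^2 - prof$bin_start^2)
  expect_equal(sum(prof$value * areas), 1, tolerance = 1e-9)

  ring <- makeTrajectory(rep(1.5, 100), rep(0, 100))
  profR <- radialDensityProfile(ring, c(0, 100 / 30))
  expect_equal(sum(profR$value > 0), 1)
  expect_error(radialDensityProfile(ring, c(200, 300)), "empty")
})

test_that("wall-attracted null walkers concentrate density in the outer bins", {
  sim <- simulateFly(shortConfig(), seed = 55)
  prof <- radialDensityProfile(sim$trajectory, c(0, 120))
  expect_gt(mean(prof$value[11:12]), mean(prof$value[1:4]))
})

test_that("crossing speed trace is near zero for identical periods and negative when slowing inside", {
  sims <- simulateCohort(shortConfig(), 4, seed = 23)
  conf <- shortPipelineConfig()
  for (s in sims) {
    a <- analyzeFly(s$trajectory, conf)
    if (isExcluded(a$epochs)) next
    tra <- suppressWarnings(
      crossingSpeedTrace(a$trajectory, a$kinematics, a$transits,
                         a$epochs, "in"))
    if (is.null(tra)) next
    expect_lt(abs(median(tra$value, na.rm = TRUE)), 0.3)
  }

  # walker that halves speed inside during odor: entry-aligned trace
  # negative after t = 0
  slowCfg <- walkerConfig(durationBefore = 60, durationDuring = 60,
    duringInside = contextParams(medianRunSpeed = 0.57 / 2))
  post <- c()
  for (seed in 41:44) {
    s <- simulateFly(slowCfg, seed = seed)
    a <- analyzeFly(s$trajectory, conf)
    if (isExcluded(a$epochs)) next
    tra <- suppressWarnings(
      crossingSpeedTrace(a$trajectory, a$kinematics, a$transits,
                         a$epochs, "in"))
    if (is.null(tra)) next
    post <- c(post, tra$value[tra$bin_start >= 0.5 & tra$bin_end <= 3])
  }
  expect_lt(median(post, na.rm = TRUE), 0)
})

test_that("occupancy time course: all-inside cohort is 1; null cohort near area fraction", {
  n <- 900
  insideCohort <- lapply(1:3, function(i)
    makeTrajectory(rep(0.5, n), rep(0.2, n)))
  occ <- occupancyTimeCourse(insideCohort)
  expect_true(all(occ$value == 1))

  # uniform (non wall-attracted) walkers dwell inside roughly at the
  # area fraction of the zone
  cfg <- walkerConfig(durationBefore = 90, durationDuring = 90,
                      before = contextParams(wallAttraction = 0))
  cohort <- lapply(simulateCohort(cfg, 8, seed = 61),
                   function(s) s$trajectory)
  occ2 <- occupancyTimeCourse(cohort, bin = 5)
  areaFrac <- (1.2 / 3.2)^2
  expect_equal(mean(occ2$value), areaFrac, tolerance = 0.6)
  expect_error(occupancyTimeCourse(list()), "empty")
})

test_that("point-source radial speed profile is 1 for constant speed and flags unvisited bins", {
  fps <- 30
  n <- 3000
  geom <- arenaGeometry(arenaRadius = 5, odorZoneRadius = 1)
  # spiral covering many radii at constant speed
  tt <- (0:(n - 1)) / fps
  r <- seq(0.3, 4.8, length.out = n)
  th <- cumsum(0.5 / (r * fps))
  traj <- new("FlyTrajectory", flyId = "s", time = tt,
              x = r * cos(th), y = r * sin(th),
              flagged = rep(FALSE, n), frameRate = fps, arena = geom)
  kin <- computeKinematics(traj)
  prof <- pointSourceRadialSpeed(traj, kin)
  visited <- !is.na(prof$value)
  expect_true(all(abs(prof$value[visited] - 1) < 0.2))

  ring <- new("FlyTrajectory", flyId = "r", time = (0:99) / fps,
              x = 2.3 * cos(0.1 * (0:99)), y = 2.3 * sin(0.1 * (0:99)),
              flagged = rep(FALSE, 100), frameRate = fps, arena = geom)
  kinR <- computeKinematics(ring)
  profR <- pointSourceRadialSpeed(ring, kinR)
  expect_equal(sum(!is.na(profR$value)), 1)
  expect_equal(profR$value[!is.na(profR$value)], 1)
})
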