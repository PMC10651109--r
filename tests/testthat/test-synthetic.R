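nullParams <- function(...) {
  trialGeneratorParams(azimuth_shift_deg = 0, elevation_gain = 1,
                       burst_amp_deg = 0, step_slowdown = 1, ...)
}

test_that("null trials drive the change metrics toward zero", {
  effects <- vapply(1:20, function(s) {
    g <- generateTrial(nullParams(), seed = 400 + s)
    nc <- normalizeCoords(g$trial)
    d <- distanceToStream(nc, g$trial)
    cs <- baselineChange(d[, "L"], protocol(g$trial), 100)
    unname(windowMeans(cs)["odour"])
  }, numeric(1))
  expect_lt(abs(mean(effects)), 0.05)
})

test_that("an injected shift pulls the responsive antenna streamward", {
  g <- generateTrial(trialGeneratorParams(azimuth_shift_deg = 15,
                                          responsive = "L"), seed = 6)
  expect_identical(g$truth$responsive, "L")
  nc <- normalizeCoords(g$trial)
  d <- distanceToStream(nc, g$trial)
  cs <- baselineChange(d[, "L"], protocol(g$trial), 100)
  expect_lt(unname(windowMeans(cs)["odour"]), 0)
})

test_that("sham trials carry no odour effects but keep the artifact", {
  g <- generateTrial(trialGeneratorParams(is_sham = TRUE,
                                          artifact_deg = 5), seed = 3)
  expect_true(protocol(g$trial)@isSham)
  expect_identical(g$trial@odour, "air_sham")
  expect_true(is.na(g$truth$responsive))
  expect_equal(g$truth$azimuth_shift_deg, 0)
  expect_equal(g$truth$artifact_deg, 5)
  ## the mechanical artifact moves the azimuth during the window
  ang <- antennalAngles(g$trial)
  odw <- 502:700                           # 5-7 s at 100 fps
  pre <- 302:500
  shift <- mean(azimuth(ang)[odw, "R"]) - mean(azimuth(ang)[pre, "R"])
  expect_gt(shift, 2)
})

test_that("generation is deterministic and seed-splitting reproducible", {
  p <- trialGeneratorParams(duration_s = 3)
  a <- generateTrial(p, seed = 99)
  b <- generateTrial(p, seed = 99)
  expect_identical(a$trial@points, b$trial@points)
  expect_identical(a$truth, b$truth)
  c <- generateTrial(p, seed = 100)
  expect_false(identical(a$trial@points$ant_L$xyz,
                         c$trial@points$ant_L$xyz))
  expect_identical(splitSeed(7, 5), splitSeed(7, 5))
  expect_false(any(splitSeed(7, 5) == splitSeed(8, 5)))
})

test_that("generators reject inconsistent parameters", {
  expect_error(trialGeneratorParams(onset_s = 10, offset_s = 9),
               "inconsistent protocol")
  expect_error(trialGeneratorParams(duration_s = 5, offset_s = 7),
               "inconsistent protocol")
  expect_error(trialGeneratorParams(noise_sd_deg = -1), "nonnegative")
  expect_error(generateArenaTrack(frac_odour = 0.8, frac_control = 0.4))
})

test_that("PID generator couples fluctuations to speed as declared", {
  ## zero coupling: flat regression
  g0 <- generatePidExperiment(rate_per_speed = 0, mag_per_speed = 0,
                              seed = 19)
  w0 <- windowFluctuations(g0$pid, selectSpeedWindows(g0$speed, 100))
  fit0 <- regressFluctuationsOnSpeed(w0, n_boot = 200, seed = 1)
  expect_lt(abs(fit0$slope[fit0$outcome == "rate"]), 0.003)
  ## control mode reproduces the baseline statistics
  gc <- generatePidExperiment(control = TRUE, seed = 20)
  wc <- windowFluctuations(gc$pid,
                           selectSpeedWindows(gc$speed, 100, control = TRUE,
                                              seed = 2))
  expect_equal(mean(wc$rate, na.rm = TRUE), gc$truth$rate0,
               tolerance = 0.15)
  expect_equal(mean(wc$magnitude, na.rm = TRUE), gc$truth$mag0,
               tolerance = 0.15)
})

test_that("smoke generator carves the declared wake from the band", {
  g <- generateSmokeSequence(wake_rows = 20L, seed = 44)
  prof <- smokeProfiles(g$sequence)
  expect_equal(prof$norm_width[1], 1)
  deficit <- prof$width[1] - prof$width[2]
  expect_lt(abs(deficit - 20), 3)
  ## no wake: widths stay at the reference
  g0 <- generateSmokeSequence(wake_rows = 0L, seed = 44)
  prof0 <- smokeProfiles(g0$sequence)
  expect_true(all(abs(prof0$norm_width - 1) < 0.1))
})

test_that("arena generator hits the prescribed occupancy fractions", {
  g <- generateArenaTrack(frac_odour = 0.6, frac_control = 0.2,
                          duration_s = 1800, seed = 12)
  ti <- occupancyTimes(g$track)
  pi <- preferenceIndex(ti["time_odour"], ti["time_control"],
                        ti["time_total"])
  expect_lt(abs(unname(pi) - 0.4), 0.15)
  g5 <- generateArenaTrack(frac_odour = 0.4, frac_control = 0.4,
                           duration_s = 1800, seed = 13)
  ti5 <- occupancyTimes(g5$track)
  expect_lt(abs(preferenceIndex(ti5["time_odour"], ti5["time_control"],
                                ti5["time_total"])), 0.15)
})

test_that("simulated scenarios write the formats the readers consume", {
  d <- withr::local_tempdir()
  simulateScenario("static1", seed = 5, out_dir = d, n_trials = 1)
  files <- list.files(d)
  expect_true("static1_01_tracking.csv" %in% files)
  expect_true("static1_01_sham_protocol.yml" %in% files)
  expect_true("ground_truth.yml" %in% files)
  tr <- readTrial(file.path(d, "static1_01_tracking.csv"),
                  file.path(d, "static1_01_protocol.yml"))
  expect_s4_class(tr, "Trial")
  truth <- yaml::read_yaml(file.path(d, "ground_truth.yml"))
  expect_false(is.null(truth$static1_01$responsive))
})
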