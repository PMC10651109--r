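test_that("threshold-and-mask keeps exactly the supra-threshold smoke pixels", {
  f <- matrix(0, 40, 60)
  mask <- matrix(FALSE, 40, 60)
  roi <- c(5L, 35L, 10L, 50L)
  ## all-black frame: nothing
  s0 <- smokeSequence(list(f), 0.5, roi, mask)
  expect_equal(sum(thresholdAndMask(s0)[[1]]), 0)
  ## k supra-threshold unmasked pixels inside the ROI: exactly k white
  f2 <- f
  f2[10:12, 20:24] <- 0.9                 # 15 pixels
  f2[2, 2] <- 0.9                         # outside the ROI
  s1 <- smokeSequence(list(f2), 0.5, roi, mask)
  expect_equal(sum(thresholdAndMask(s1)[[1]]), 15)
  ## a mask covering the whole ROI removes everything
  maskAll <- mask; maskAll[5:35, 10:50] <- TRUE
  s2 <- smokeSequence(list(f2), 0.5, roi, maskAll)
  expect_equal(sum(thresholdAndMask(s2)[[1]]), 0)
  ## mask-then-threshold equals threshold-then-mask
  set.seed(9)
  f3 <- matrix(runif(40 * 60), 40, 60)
  m3 <- matrix(runif(40 * 60) < 0.3, 40, 60)
  s3 <- smokeSequence(list(f3), 0.5, roi, m3)
  viaA <- thresholdAndMask(s3)[[1]]
  fMaskedFirst <- f3; fMaskedFirst[m3] <- 0
  viaB <- (fMaskedFirst >= 0.5)[5:35, 10:50]
  expect_identical(unname(viaA), unname(viaB))
  ## shape mismatch is an error
  s4 <- s3; s4@frames <- list(matrix(0, 10, 10))
  expect_error(thresholdAndMask(s4), "dimensions")
})

test_that("row profiles count pixels left-to-right and derive widths", {
  bin <- matrix(FALSE, 30, 50)
  bin[10:20, ] <- TRUE                    # uniform band over rows 10-20
  p <- rowProfile(bin)
  expect_equal(p$counts[10:20], rep(50L, 11))
  expect_equal(p$width, 11L)
  expect_equal(rowProfile(bin, reference_width = p$width)$norm_width, 1)
  ## a carved gap splits the band: width and mass drop
  bin2 <- bin; bin2[13:16, ] <- FALSE
  p2 <- rowProfile(bin2, reference_width = p$width)
  expect_lt(p2$width, p$width)
  expect_lt(sum(p2$counts), sum(p$counts))
  expect_equal(p2$width, 4L)              # rows 17-20 is the longest run
  expect_error(rowProfile(bin, reference_width = 0), "reference width")
  ## the left-right axis can run along columns instead
  pc <- rowProfile(t(bin), left_right_axis = "col")
  expect_equal(pc$counts, p$counts)
})

test_that("PID extrema detection equals the brute-force scan", {
  set.seed(14)
  for (i in 1:12) {
    n <- sample(50:1000, 1)
    v <- cumsum(rnorm(n)) + 2 * sin(seq(0, 20, length.out = n))
    tr <- detectPidExtrema(v, min_prominence_frac = 0.02)
    oracle <- bruteExtrema(v, 0.02 * diff(range(v)))
    expect_identical(tr@maxima, as.integer(oracle$maxima))
    expect_identical(tr@minima, as.integer(oracle$minima))
    ## alternation holds
    ev <- sort(c(tr@minima, tr@maxima))
    typ <- ev %in% tr@maxima
    if (length(typ) > 1) expect_true(all(typ[-1] != typ[-length(typ)]))
  }
  expect_identical(detectPidExtrema(seq(0, 1, 0.01))@maxima, integer(0))
  expect_error(detectPidExtrema(c(1, 2)), "at least 3")
})

test_that("a pure sinusoid yields rate 2f and magnitude 2A", {
  fr <- 200
  t <- seq(0, 10, by = 1 / fr)
  for (f in c(0.5, 1, 2, 5)) {
    for (phase in c(0, 1.1)) {
      A <- 0.4
      tr <- detectPidExtrema(A * sin(2 * pi * f * t + phase) + 0.5,
                             min_prominence_frac = 0.02, time_s = t)
      st <- fluctuationStats(tr)
      expect_equal(unname(st["rate"]), 2 * f, tolerance = 0.02)
      expect_equal(unname(st["magnitude"]), 2 * A, tolerance = 0.01)
    }
  }
  ## a flat trace has no defined fluctuation statistics
  flat <- detectPidExtrema(rep(0.5, 100))
  expect_true(is.na(fluctuationStats(flat)["rate"]))
  ## two interleaved sines: rate between the two pure rates (the mean
  ## reciprocal interval is slightly biased high on uneven spacing)
  v <- sin(2 * pi * 1 * t) + sin(2 * pi * 3 * t)
  st2 <- fluctuationStats(detectPidExtrema(v, time_s = t))
  expect_gt(unname(st2["rate"]), 2 * 1)
  expect_lt(unname(st2["rate"]), 2 * 3 * 1.05)
})

test_that("speed windows centre on peaks and span the speed range", {
  fr <- 100
  ## a single bump produces one window centred on it
  t <- seq(0, 20, by = 1 / fr)
  sp <- 100 * exp(-(t - 9)^2 / 0.5)
  w <- selectSpeedWindows(sp, fr, min_prominence = 10)
  expect_equal(nrow(w), 1)
  expect_lt(abs((w$start_s + w$end_s) / 2 - 9), 0.3)
  ## control mode is reproducible under a fixed seed, and windows never
  ## overlap
  w1 <- selectSpeedWindows(sp, fr, control = TRUE, seed = 42, n_windows = 5)
  w2 <- selectSpeedWindows(sp, fr, control = TRUE, seed = 42, n_windows = 5)
  expect_identical(w1, w2)
  expect_true(all(diff(w1$start_s) >= 2 - 1e-9))
  ## multi-regime data: selected means cover most of the speed range
  g <- generatePidExperiment(seed = 33)
  ws <- selectSpeedWindows(g$speed, fr)
  spanned <- diff(range(ws$mean_speed)) / diff(range(g$speed))
  expect_gt(spanned, 0.5)
  expect_error(selectSpeedWindows(sp[1:100], fr), "shorter than")
})

test_that("fluctuation regression matches the normal equations", {
  set.seed(6)
  d <- data.frame(mean_speed = runif(15, 0, 300))
  d$rate <- 4 + 0.01 * d$mean_speed + rnorm(15, 0, 0.1)
  d$magnitude <- 0.05 + 0.001 * d$mean_speed + rnorm(15, 0, 0.003)
  fit <- regressFluctuationsOnSpeed(d, n_boot = 200, seed = 2)
  x <- d$mean_speed
  slopeOracle <- sum((x - mean(x)) * (d$rate - mean(d$rate))) /
    sum((x - mean(x))^2)
  expect_equal(fit$slope[fit$outcome == "rate"], slopeOracle,
               tolerance = 1e-10)
  expect_equal(fit$intercept[fit$outcome == "rate"],
               mean(d$rate) - slopeOracle * mean(x), tolerance = 1e-10)
  ## zero-slope data: r near zero
  d2 <- d; d2$rate <- rnorm(15); d2$magnitude <- rnorm(15)
  fit2 <- regressFluctuationsOnSpeed(d2, n_boot = 100, seed = 3)
  expect_lt(abs(fit2$r[1]), 0.6)
  d3 <- d; d3$mean_speed <- rep(1, 15)
  expect_error(regressFluctuationsOnSpeed(d3), "constant predictor")
})

test_that("static-antenna control windows show weaker fluctuations", {
  g <- generatePidExperiment(seed = 51)
  gc <- generatePidExperiment(control = TRUE, seed = 52)
  w <- windowFluctuations(g$pid, selectSpeedWindows(g$speed, 100))
  wc <- windowFluctuations(gc$pid,
                           selectSpeedWindows(gc$speed, 100, control = TRUE,
                                              seed = 1))
  expect_gt(mean(w$rate, na.rm = TRUE), mean(wc$rate, na.rm = TRUE))
  expect_gt(mean(w$magnitude, na.rm = TRUE),
            mean(wc$magnitude, na.rm = TRUE))
})
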