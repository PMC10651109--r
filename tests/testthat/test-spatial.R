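ncFromXYZ <- function(L, R, frame_rate = 100) {
  new("NormalizedCoords", L = L, R = R,
      valid = matrix(TRUE, nrow(L), 2, dimnames = list(NULL, c("L", "R"))),
      axisScale = c(1, 1, 1), scaleFactor = 50, frameRate = frame_rate)
}

test_that("occupancy maps conserve unit mass and localize correctly", {
  n <- 50
  L <- cbind(rep(0.51, n), rep(0.51, n), 0)   # single bin
  nc <- ncFromXYZ(L, L)
  m <- occupancyMap(nc, plane = "xy")
  expect_equal(sum(m@values), 1)
  expect_equal(max(m@values), 1)
  expect_equal(sum(m@values > 0), 1)
  ## pooled across two trials still sums to 1
  m2 <- occupancyMap(list(nc, ncFromXYZ(-L, -L)), plane = "xy")
  expect_equal(sum(m2@values), 1)
  expect_equal(sum(m2@values > 0), 2)
  expect_error(occupancyMap(nc, window = integer(0)), "empty window")
})

test_that("uniform scatter fills occupancy bins evenly", {
  set.seed(31)
  n <- 60000
  L <- cbind(runif(n, -1, 1), runif(n, -1, 1), runif(n, -1, 1))
  m <- occupancyMap(ncFromXYZ(L, L), plane = "xy")
  ## every proportion near 1/576 within multinomial sampling error
  expect_lt(max(m@values), 1.5 / 576)
  expect_gt(min(m@values), 0.5 / 576)
})

test_that("cross-trial normalization shares one scale over the dataset", {
  g1 <- generateTrial(trialGeneratorParams(duration_s = 3,
                                           antennal_length_mm = 45),
                      seed = 1)
  g2 <- generateTrial(trialGeneratorParams(duration_s = 3,
                                           antennal_length_mm = 55),
                      seed = 2)
  ncs <- lapply(list(g1$trial, g2$trial), normalizeCoords)
  resc <- crossTrialNormalize(ncs)
  allv <- abs(rbind(resc[[1]]@L, resc[[1]]@R, resc[[2]]@L, resc[[2]]@R))
  expect_equal(max(allv, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_identical(resc[[1]]@axisScale, resc[[2]]@axisScale)
  expect_length(attr(resc, "datasetScale"), 3)
})

test_that("density curves integrate to one and match the kernel sum", {
  set.seed(5)
  v <- rnorm(400, sd = 0.3)
  d <- densityCurve(v, bandwidth = 0.2)
  area <- sum(diff(d$x) * (head(d$density, -1) + tail(d$density, -1)) / 2)
  expect_lt(abs(area - 1), 1e-3)
  ## matches the brute-force Gaussian kernel sum at 10 query points
  q <- seq(-0.8, 0.8, length.out = 10)
  interp <- approx(d$x, d$density, xout = q)$y
  expect_equal(interp, bruteKernelDensity(v, 0.2, q), tolerance = 1e-3)
  ## symmetric input gives a symmetric curve
  vs <- c(v, -v)
  ds <- densityCurve(vs, bandwidth = 0.2)
  left <- approx(ds$x, ds$density, xout = -q)$y
  right <- approx(ds$x, ds$density, xout = q)$y
  expect_equal(left, right, tolerance = 1e-6)
  expect_error(densityCurve(rep(1, 10)), "explicit bandwidth")
  expect_silent(densityCurve(rep(1, 10), bandwidth = 0.1))
})

test_that("distance to the stream follows the closed form", {
  n <- 100
  head <- constPoint(n, 0, 0, 0)          # head at the stream height
  tipOn <- head + constPoint(n, 0, 30, 0) # on the stream centre line
  antR <- head + constPoint(n, 40, 10, 3)
  tr <- makeTrial(head, tipOn, antR, stream_x = 0)
  nc <- normalizeCoords(tr)
  d <- distanceToStream(nc, tr)
  expect_equal(unname(d[, "L"]), rep(0, n), tolerance = 1e-12)
  ## right tip: one scale unit lateral of the line (x scale is its 40 mm)
  dx <- distanceToStream(nc, tr, mode = "x_only")
  expect_equal(unname(dx[, "R"]), rep(1, n), tolerance = 1e-12)
  ## and the x-z distance adds the height offset in quadrature
  expect_equal(unname(d[, "R"]), rep(sqrt(1 + (3 / nc@axisScale[3])^2), n),
               tolerance = 1e-12)
  ## moving stream: x-only distance equals |x_tip - x_stream(t)| exactly
  path <- data.frame(time_s = c(0, 1), x_mm = c(0, 30))
  trM <- trial("t", "a", "colony", 100,
               list(head = head, ant_L = tipOn, ant_R = antR),
               stimulusProtocol(0.2, 0.8, stream_x = path))
  ncM <- normalizeCoords(trM)
  dM <- distanceToStream(ncM, trM, mode = "x_only")
  t <- (seq_len(n) - 1) / 100
  sx <- approx(path$time_s, path$x_mm, xout = t, rule = 2)$y
  expect_equal(unname(dM[, "R"]),
               abs(40 - sx) / ncM@axisScale[1], tolerance = 1e-12)
})

test_that("ranges equal the brute-force max-difference oracle", {
  expect_equal(antennalRange(rep(0.2, 10)), 0)
  expect_equal(antennalRange(c(-0.3, 0.5)), 0.8)
  expect_error(antennalRange(c(1)), "at least 2")
  set.seed(77)
  for (i in 1:50) {
    v <- runif(sample(5:50, 1), -1, 1)
    expect_identical(antennalRange(v), bruteRange(v))
  }
  ## overall range bounds each individual range
  expect_equal(overallRange(c(-0.9, -0.1), c(0.1, 0.9)), 1.8)
  expect_equal(overallRange(c(0.1, 0.4), c(0.1, 0.4)),
               antennalRange(c(0.1, 0.4)))
  for (i in 1:50) {
    a <- runif(20, -1, 1); b <- runif(20, -1, 1)
    expect_gte(overallRange(a, b),
               max(antennalRange(a), antennalRange(b)))
  }
  ## translation invariance and linear scaling
  v <- runif(30)
  expect_equal(antennalRange(v + 5), antennalRange(v), tolerance = 1e-12)
  expect_equal(antennalRange(3 * v), 3 * antennalRange(v),
               tolerance = 1e-12)
})

test_that("baseline change zeroes the pre-stimulus window by construction", {
  fr <- 100
  pr <- stimulusProtocol(2, 4)
  n <- 600
  ## constant metric: change identically zero
  cs <- baselineChange(rep(7, n), pr, fr)
  expect_true(all(changeValues(cs) == 0))
  ## step of +2 at onset: odour-window mean change = 2
  metric <- c(rep(1, 200), rep(3, 400))
  cs2 <- baselineChange(metric, pr, fr)
  expect_equal(unname(windowMeans(cs2)["odour"]), 2)
  expect_equal(unname(windowMeans(cs2)["pre"]), 0)
  ## linear ramp: pre-window mean of the change is exactly zero
  cs3 <- baselineChange(seq_len(n) / 100, pr, fr)
  expect_equal(unname(windowMeans(cs3)["pre"]), 0, tolerance = 1e-12)
  ## idempotence: re-applying to its own output changes nothing
  cs4 <- baselineChange(changeValues(cs3), pr, fr)
  expect_equal(changeValues(cs4), changeValues(cs3), tolerance = 1e-12)
  ## truncated pre-window is an error
  expect_error(baselineChange(metric, stimulusProtocol(1, 4), fr),
               "truncated")
})

test_that("windows with too many invalid frames yield missing means", {
  fr <- 100
  pr <- stimulusProtocol(1, 2)
  metric <- rep(1, 300)
  metric[101:180] <- NA                      # 80% of the odour window
  cs <- baselineChange(metric, pr, fr)
  expect_true(is.na(windowMeans(cs)["odour"]))
  metric2 <- rep(1, 300)
  metric2[101:140] <- NA                     # 40%: still summarised
  cs2 <- baselineChange(metric2, pr, fr)
  expect_false(is.na(windowMeans(cs2)["odour"]))
})

test_that("sham correction subtracts the paired control exactly", {
  fr <- 100
  pr <- stimulusProtocol(2, 4)
  odw <- rep(c(0, 1, 0), c(200, 200, 200))
  base <- sin(seq(0, 6, length.out = 600))
  ## the odour trial shows a total +3 change, of which +1 is the shared
  ## mechanical artifact also present in the sham trial
  odour <- baselineChange(base + 3 * odw, pr, fr)
  sham <- baselineChange(base + 1 * odw, pr, fr)
  corr <- shamCorrect(odour, sham)
  expect_true(corr@shamCorrected)
  ## odour trial identical to sham: corrected change identically zero
  same <- shamCorrect(sham, sham)
  expect_true(all(changeValues(same) == 0))
  ## zero sham: identity
  zero <- baselineChange(rep(0, 600), pr, fr)
  expect_equal(changeValues(shamCorrect(odour, zero)),
               changeValues(odour))
  ## artifact +1 with effect +3 recovers a corrected mean of 2
  expect_equal(unname(windowMeans(corr)["odour"]), 2, tolerance = 1e-9)
  ## mismatched timing is an error
  bad <- baselineChange(base, stimulusProtocol(2.5, 4.5), fr)
  expect_error(shamCorrect(odour, bad), "timing differs")
})

test_that("responsive labelling picks the strongest distance decrease", {
  fr <- 100
  pr <- stimulusProtocol(4, 6)
  n <- 800
  t <- (seq_len(n) - 1) / fr
  odw <- t >= 4 & t < 6
  dist <- cbind(L = 0.5 - 0.2 * odw, R = 0.5 + 0.1 * odw)
  lab <- labelResponsive(dist, pr, fr)
  expect_identical(lab$responsive, "L")
  expect_equal(unname(lab$odour_change["L"]), -0.2, tolerance = 1e-9)
  ## ties break to L with a warning
  expect_warning(
    lab2 <- labelResponsive(cbind(L = rep(0.5, n), R = rep(0.5, n)), pr, fr),
    "tie")
  expect_identical(lab2$responsive, "L")
  ## the control split is computed from two consecutive pre-onset windows
  expect_true(lab$control %in% c("L", "R"))
})

test_that("stream-following correlation behaves like Pearson's r", {
  s <- seq(0, 30, length.out = 50)
  expect_equal(streamFollowingCorrelation(s, s), 1)
  expect_equal(streamFollowingCorrelation(-s, s), -1)
  set.seed(3)
  x <- rnorm(40); y <- rnorm(40)
  textbook <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(streamFollowingCorrelation(x, y), textbook,
               tolerance = 1e-12)
  expect_warning(r <- streamFollowingCorrelation(rep(1, 10), s[1:10]),
                 "constant")
  expect_true(is.na(r))
  expect_error(streamFollowingCorrelation(1:2, 2:3), "at least 3")
})
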