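test_that("antennal angle sign conventions follow the head-line geometry", {
  n <- 3
  head <- constPoint(n, 0, 0, 5)
  ## tip straight ahead: azimuth 0, elevation 0
  tr <- makeTrial(head, head + constPoint(n, 0, 30, 0),
                  head + constPoint(n, 30, 0, 0))
  ang <- antennalAngles(tr)
  expect_equal(azimuth(ang)[, "L"], rep(0, n))
  expect_equal(elevation(ang)[, "L"], rep(0, n))
  ## tip straight right: azimuth +90
  expect_equal(azimuth(ang)[, "R"], rep(90, n))
  expect_equal(elevation(ang)[, "R"], rep(0, n))
  ## 45 deg elevation from equal forward and upward components
  tr2 <- makeTrial(head, head + constPoint(n, 0, 30, 30),
                  head + constPoint(n, -30, 0, 0))
  ang2 <- antennalAngles(tr2)
  expect_equal(elevation(ang2)[, "L"], rep(45, n))
  expect_equal(azimuth(ang2)[, "R"], rep(-90, n))
})

test_that("angles match the arctangent oracle on random configurations", {
  set.seed(42)
  n <- 1000
  head <- cbind(x = rnorm(n), y = rnorm(n), z = 5 + rnorm(n))
  d <- cbind(x = runif(n, -40, 40), y = runif(n, 5, 50),
             z = runif(n, -30, 30))
  tr <- makeTrial(head, head + d, head + d)
  ang <- antennalAngles(tr)
  azOracle <- atan2(d[, 1], d[, 2]) * 180 / pi
  elOracle <- atan2(d[, 3], sqrt(d[, 1]^2 + d[, 2]^2)) * 180 / pi
  expect_equal(azimuth(ang)[, "L"], unname(azOracle), tolerance = 1e-12)
  expect_equal(elevation(ang)[, "L"], unname(elOracle), tolerance = 1e-12)
  expect_true(all(azimuth(ang) > -180 & azimuth(ang) <= 180))
  expect_true(all(abs(elevation(ang)) <= 90))
})

test_that("mirror symmetry negates azimuth and heading, fixes elevation", {
  g <- generateTrial(trialGeneratorParams(duration_s = 4), seed = 8)
  tr <- g$trial
  trM <- tr
  for (lab in pointLabels(trM))
    trM@points[[lab]]$xyz[, 1] <- -trM@points[[lab]]$xyz[, 1]
  a <- antennalAngles(tr); aM <- antennalAngles(trM)
  ## mirroring also swaps which physical antenna is labelled L/R is NOT
  ## done here: labels stay, so L's mirrored azimuth equals minus L's
  expect_equal(azimuth(aM)[, "L"], -azimuth(a)[, "L"], tolerance = 1e-10)
  expect_equal(azimuth(aM)[, "R"], -azimuth(a)[, "R"], tolerance = 1e-10)
  expect_equal(elevation(aM), elevation(a), tolerance = 1e-10)
  h <- heading(tr, c(0, -20)); hM <- heading(trM, c(0, -20))
  expect_equal(hM@heading, -h@heading, tolerance = 1e-10)
  sp <- angularSpeed(a); spM <- angularSpeed(aM)
  expect_equal(combinedSpeed(spM), combinedSpeed(sp), tolerance = 1e-10)
})

test_that("elevation is invariant to horizontal rotation of the tip", {
  set.seed(7)
  n <- 200
  head <- constPoint(n, 0, 0, 5)
  r <- 30; elev <- runif(n, -60, 60); theta <- runif(n, -pi, pi)
  tip1 <- head + cbind(r * cos(elev * pi / 180) * sin(theta),
                       r * cos(elev * pi / 180) * cos(theta),
                       r * sin(elev * pi / 180))
  theta2 <- theta + runif(n, -1, 1)
  tip2 <- head + cbind(r * cos(elev * pi / 180) * sin(theta2),
                       r * cos(elev * pi / 180) * cos(theta2),
                       r * sin(elev * pi / 180))
  ang <- antennalAngles(makeTrial(head, tip1, tip2))
  expect_equal(elevation(ang)[, "L"], elevation(ang)[, "R"],
               tolerance = 1e-9)
  expect_equal(elevation(ang)[, "L"], elev, tolerance = 1e-9)
})

test_that("heading is signed against the midline through the tether", {
  n <- 2
  tether <- c(0, -20)
  tr <- makeTrial(constPoint(n, 0, 10, 5), constPoint(n, -5, 40, 5),
                  constPoint(n, 5, 40, 5))
  expect_equal(heading(tr, tether)@heading, rep(0, n))
  ## 30 deg left: head displaced so atan2(dx, dy) = -30
  d <- 30 * pi / 180
  headL <- constPoint(n, -sin(d) * 30, -20 + cos(d) * 30, 5)
  headR <- constPoint(n, sin(d) * 30, -20 + cos(d) * 30, 5)
  trL <- makeTrial(headL, headL + constPoint(n, 0, 30, 0),
                   headL + constPoint(n, 1, 30, 0))
  trR <- makeTrial(headR, headR + constPoint(n, 0, 30, 0),
                   headR + constPoint(n, 1, 30, 0))
  expect_equal(heading(trL, tether)@heading, rep(-30, n), tolerance = 1e-10)
  expect_equal(abs(heading(trL, tether)@heading),
               abs(heading(trR, tether)@heading), tolerance = 1e-10)
})

test_that("zero-length head-to-tip vectors are flagged invalid", {
  n <- 3
  head <- constPoint(n, 0, 0, 5)
  tip <- head; tip[2, ] <- head[2, ]          # coincides at frame 2
  tip[c(1, 3), ] <- head[c(1, 3), ] + c(0, 0, 30, 30, 0, 0)
  ang <- antennalAngles(makeTrial(head, tip, head + constPoint(n, 5, 20, 0)))
  expect_false(ang@valid[2, "L"])
  expect_true(all(ang@valid[c(1, 3), "L"]))
})

test_that("coordinate normalization scales each axis to unit maximum", {
  n <- 2
  head <- constPoint(n, 0, 0, 5)
  antL <- head + rbind(c(10, 10, 0), c(20, 0, 0))
  antR <- head + rbind(c(-5, 10, 2), c(-5, 10, 2))
  nc <- normalizeCoords(makeTrial(head, antL, antR))
  expect_equal(nc@L[, 1], c(0.5, 1.0))
  ## doubling every raw coordinate (about the head) leaves output unchanged
  tr2 <- makeTrial(head, head + 2 * (antL - head), head + 2 * (antR - head))
  nc2 <- normalizeCoords(tr2)
  expect_equal(nc2@L, nc@L, tolerance = 1e-12)
  expect_equal(nc2@R, nc@R, tolerance = 1e-12)
})

test_that("the normalization scale factor recovers the antennal length", {
  g <- generateTrial(trialGeneratorParams(antennal_length_mm = 50), seed = 5)
  nc <- normalizeCoords(g$trial)
  expect_lt(abs(nc@scaleFactor - 50) / 50, 0.05)
  ## every valid normalized coordinate respects |.| <= 1
  expect_lte(max(abs(nc@L), na.rm = TRUE), 1 + 1e-12)
  expect_lte(max(abs(nc@R), na.rm = TRUE), 1 + 1e-12)
  ## head maps to the origin: a tip placed at the head normalizes to 0
  expect_equal(max(abs(nc@axisScale * 0)), 0)
})

test_that("per-antenna normalization is available and differs when asymmetric", {
  n <- 2
  head <- constPoint(n, 0, 0, 5)
  antL <- head + rbind(c(10, 10, 1), c(20, 5, 1))
  antR <- head + rbind(c(-40, 10, 1), c(-10, 20, 1))
  tr <- makeTrial(head, antL, antR)
  joint <- normalizeCoords(tr, axes = "joint")
  per <- normalizeCoords(tr, axes = "per_antenna")
  expect_equal(max(abs(per@L[, 1])), 1)
  expect_equal(max(abs(per@R[, 1])), 1)
  expect_lt(max(abs(joint@L[, 1])), 1)   # left is dominated by right's 40 mm
})

test_that("angular speed matches finite differences and closed forms", {
  fr <- 100
  t <- seq(0, 4, by = 1 / fr)
  ## constant angle: zero speed
  az <- matrix(10, length(t), 2, dimnames = list(NULL, c("L", "R")))
  el <- az * 0
  ang <- new("AngleSeries", azimuth = az, elevation = el,
             valid = az == az, frameRate = fr)
  sp <- angularSpeed(ang)
  expect_true(all(combinedSpeed(sp)[-1, ] == 0))
  ## azimuth advancing 1 deg per frame: 100 deg/s
  ang@azimuth[, "L"] <- seq_along(t)
  sp2 <- angularSpeed(ang)
  expect_equal(sp2@azimuthSpeed[-1, "L"], rep(100, length(t) - 1))
  ## sinusoid A sin(2 pi f t): max combined speed ~ 2 pi f A
  A <- 20; f <- 2
  ang@azimuth[, "L"] <- A * sin(2 * pi * f * t)
  sp3 <- angularSpeed(ang)
  expect_equal(max(combinedSpeed(sp3)[, "L"], na.rm = TRUE),
               2 * pi * f * A, tolerance = 0.01)
  ## combined speed dominates each component and is zero iff both are
  g <- generateTrial(trialGeneratorParams(duration_s = 3), seed = 9)
  spg <- angularSpeed(antennalAngles(g$trial))
  expect_true(all(combinedSpeed(spg) >= abs(spg@azimuthSpeed) - 1e-12,
                  na.rm = TRUE))
  expect_true(all(combinedSpeed(spg) >= abs(spg@elevationSpeed) - 1e-12,
                  na.rm = TRUE))
})

test_that("abs-sum combined speed is an available convention", {
  g <- generateTrial(trialGeneratorParams(duration_s = 2), seed = 10)
  ang <- antennalAngles(g$trial)
  eu <- angularSpeed(ang, combined = "euclidean")
  ab <- angularSpeed(ang, combined = "abs_sum")
  expect_true(all(combinedSpeed(ab) >= combinedSpeed(eu) - 1e-12,
                  na.rm = TRUE))
})

test_that("moving-average smoothing matches the brute-force oracle", {
  expect_equal(smoothSeries(rep(4, 50), 0.5, 100), rep(4, 50))
  imp <- c(rep(0, 10), 1, rep(0, 10))
  sm <- smoothSeries(imp, 0.03, 100)     # 3-frame window
  expect_equal(sm[10:12], rep(1 / 3, 3))
  set.seed(1)
  x <- rnorm(200)
  expect_equal(smoothSeries(x, 0.11, 100), bruteMovingAverage(x, 5),
               tolerance = 1e-12)
  expect_error(smoothSeries(rnorm(10), 1, 100), "longer than the series")
})
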