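## Synthetic stand-ins for every input the pipeline consumes, with
## machine-readable ground truth. The generator emulates the statistical
## structure the analyses assume: slow sinusoidal antennal sweeping around
## +/-50 deg with odour-locked shifts toward the stream, elevation gain and
## band-limited high-frequency bursts; double-tripod stepping around 2 Hz
## with an odour slowdown; PID fluctuations affinely coupled to antennal
## speed; a Gaussian-profile smoke band with a carved antenna wake; and a
## two-shelter arena walk with prescribed occupancy fractions.

#' Parameters of the synthetic trial generator
#'
#' Defaults describe the emulated study conditions: 100 frames/s tracking,
#' a 2 s odour pulse after a 5 s baseline, antennae sweeping about their
#' natural position of ~50 deg from the midline with slow (< 1 Hz) cycles,
#' 50 mm antennae, stepping around 2 Hz that halves during odour, and an
#' odour-locked azimuthal shift of the responsive antenna toward the
#' stream with an elevation gain and a 4 Hz burst.
#'
#' @param duration_s trial length (s).
#' @param frame_rate frames per second.
#' @param onset_s,offset_s stimulus window (s); the defaults keep the
#'   12 s : 5 s : 2 s trial/baseline/stimulus proportions at any duration.
#' @param antennal_length_mm straight-line head-to-tip length.
#' @param mean_azimuth_deg baseline sweep centre (deg from midline; the left
#'   antenna uses the negative).
#' @param sweep_amp_deg,sweep_freq_hz azimuth sweep amplitude / frequency.
#' @param freq_jitter relative s.d. of per-trial sweep-frequency jitter.
#' @param mean_elevation_deg,elev_amp_deg,elev_freq_hz baseline elevation
#'   sweep (negative = below head level).
#' @param noise_sd_deg per-frame white angle noise, degrees.
#' @param head_jitter_mm s.d. of the smoothed head jitter.
#' @param responsive `"L"`, `"R"` or `"random"`: which antenna responds.
#' @param azimuth_shift_deg odour-window azimuthal shift of the responsive
#'   antenna toward the stream (0 = no effect).
#' @param elevation_gain odour-window multiplier on elevation amplitude.
#' @param burst_freq_hz,burst_amp_deg band-limited burst added to the
#'   responsive antenna's angles during odour (0 amp = none).
#' @param contra_range_gain odour-window multiplier on the contralateral
#'   antenna's sweep amplitude.
#' @param step_rate_hz baseline stepping rate.
#' @param step_slowdown odour-window multiplier on the stepping rate.
#' @param step_amp_mm tarsus forward-swing amplitude.
#' @param stream `"static1"` (centre), `"static2"` (30 mm side) or
#'   `"moving"` (centre to edge of reach via the side position).
#' @param is_sham sham trial: all odour effects omitted, mechanical
#'   artifact kept.
#' @param artifact_deg mechanical (non-olfactory) azimuth artifact applied
#'   to both antennae during the stimulus window of every trial, sham
#'   included.
#' @return a validated parameter list.
#' @export
trialGeneratorParams <- function(duration_s = 12, frame_rate = 100,
                                 onset_s = duration_s * 5 / 12,
                                 offset_s = duration_s * 7 / 12,
                                 antennal_length_mm = 50,
                                 mean_azimuth_deg = 50,
                                 sweep_amp_deg = 30, sweep_freq_hz = 0.7,
                                 freq_jitter = 0.1,
                                 mean_elevation_deg = -20,
                                 elev_amp_deg = 8, elev_freq_hz = 1.1,
                                 noise_sd_deg = 2,
                                 head_jitter_mm = 0.3,
                                 responsive = "random",
                                 azimuth_shift_deg = 15,
                                 elevation_gain = 2,
                                 burst_freq_hz = 4, burst_amp_deg = 6,
                                 contra_range_gain = 1,
                                 step_rate_hz = 2, step_slowdown = 0.5,
                                 step_amp_mm = 5,
                                 stream = c("static1", "static2", "moving"),
                                 is_sham = FALSE,
                                 artifact_deg = 0) {
  p <- as.list(environment())
  p$stream <- match.arg(stream)
  if (p$onset_s < 0 || p$onset_s >= p$offset_s || p$offset_s > p$duration_s)
    stop("inconsistent protocol timing for the trial duration")
  amps <- c(p$sweep_amp_deg, p$elev_amp_deg, p$burst_amp_deg,
            p$noise_sd_deg, p$step_amp_mm)
  if (any(amps < 0)) stop("amplitudes must be nonnegative")
  p
}

streamProtocol <- function(p) {
  switch(p$stream,
    static1 = stimulusProtocol(p$onset_s, p$offset_s, stream_x = 0,
                               is_sham = p$is_sham),
    static2 = stimulusProtocol(p$onset_s, p$offset_s, stream_x = 30,
                               is_sham = p$is_sham),
    moving = {
      on <- p$onset_s; off <- p$offset_s
      third <- (off - on) / 3
      path <- data.frame(
        time_s = c(0, on + third, on + third + 1,
                   on + 2 * third, on + 2 * third + 1, p$duration_s),
        x_mm = c(0, 0, 30, 30, 50, 50))
      sp <- data.frame(label = c("P1", "P2", "P3"),
                       start_s = c(on, on + third + 1, on + 2 * third + 1),
                       end_s = c(on + third, on + 2 * third, off))
      stimulusProtocol(on, off, stream_x = path, is_sham = p$is_sham,
                       static_positions = sp)
    })
}

#' Generate one synthetic trial with known ground truth
#'
#' Builds a complete [Trial-class]: a head with smoothed jitter, two
#' antennal tips following sinusoid-plus-noise sweeps (during the odour
#' window the responsive antenna's azimuth shifts toward the stream, its
#' elevation amplitude grows and band-limited bursts appear; the
#' contralateral amplitude is scaled by `contra_range_gain`), and six tarsi
#' stepping in two antiphase tripods with an asymmetric swing/stance cycle,
#' slowed during odour. Sham trials omit all odour effects but keep the
#' declared mechanical artifact. A fixed seed fixes the full realization.
#'
#' @param params from [trialGeneratorParams()].
#' @param seed integer seed.
#' @param trial_id,animal_id identifiers.
#' @param odour odour label (forced to `"air_sham"` for sham trials).
#' @return list: `trial` (a [Trial-class]) and `truth` (injected effects:
#'   responsive side, azimuth shift, elevation gain, burst band/amplitude,
#'   stepping slowdown, stream type).
#' @export
generateTrial <- function(params = trialGeneratorParams(), seed = 1L,
                          trial_id = sprintf("trial_%04d", seed),
                          animal_id = "animal_01", odour = "colony") {
  p <- params
  withSeed(seed, {
    n <- round(p$duration_s * p$frame_rate)
    t <- (seq_len(n) - 1) / p$frame_rate
    odw <- t >= p$onset_s & t < p$offset_s
    effect <- if (p$is_sham) 0 else 1
    responsive <- if (p$responsive == "random")
      sample(c("L", "R"), 1) else p$responsive
    pr <- streamProtocol(p)
    sx <- streamX(pr, t)

    headXYZ <- cbind(
      x = movingAverage(stats::rnorm(n, 0, p$head_jitter_mm), 0.2,
                        p$frame_rate),
      y = movingAverage(stats::rnorm(n, 0, p$head_jitter_mm), 0.2,
                        p$frame_rate),
      z = 5 + movingAverage(stats::rnorm(n, 0, p$head_jitter_mm), 0.2,
                            p$frame_rate))

    ## azimuth of the stream as seen from the head, for the shift target
    streamAz <- atan2(sx - headXYZ[, "x"], 0.6 * p$antennal_length_mm) *
      180 / pi

    makeAntenna <- function(side) {
      sgn <- if (side == "L") -1 else 1
      fAz <- p$sweep_freq_hz * (1 + stats::rnorm(1, 0, p$freq_jitter))
      fEl <- p$elev_freq_hz * (1 + stats::rnorm(1, 0, p$freq_jitter))
      amp <- rep(p$sweep_amp_deg, n)
      isResp <- side == responsive
      if (!isResp && effect > 0)
        amp[odw] <- amp[odw] * p$contra_range_gain
      az <- sgn * p$mean_azimuth_deg +
        amp * sin(2 * pi * fAz * t + stats::runif(1, 0, 2 * pi)) +
        stats::rnorm(n, 0, p$noise_sd_deg)
      elAmp <- rep(p$elev_amp_deg, n)
      if (isResp && effect > 0) elAmp[odw] <- elAmp[odw] * p$elevation_gain
      el <- p$mean_elevation_deg +
        elAmp * sin(2 * pi * fEl * t + stats::runif(1, 0, 2 * pi)) +
        stats::rnorm(n, 0, p$noise_sd_deg)
      if (isResp && effect > 0) {
        toward <- sign(streamAz[odw] - sgn * p$mean_azimuth_deg)
        az[odw] <- az[odw] + toward * p$azimuth_shift_deg
        if (p$burst_amp_deg > 0) {
          burst <- p$burst_amp_deg *
            sin(2 * pi * p$burst_freq_hz * t[odw] + stats::runif(1, 0, 2 * pi))
          az[odw] <- az[odw] + burst
          el[odw] <- el[odw] + burst
        }
      }
      if (p$artifact_deg != 0)
        az[odw] <- az[odw] + sgn * p$artifact_deg
      el <- pmin(pmax(el, -89), 89)
      azr <- az * pi / 180; elr <- el * pi / 180
      headXYZ + p$antennal_length_mm *
        cbind(x = cos(elr) * sin(azr), y = cos(elr) * cos(azr),
              z = sin(elr))
    }
    antL <- makeAntenna("L")
    antR <- makeAntenna("R")

    ## double-tripod stepping with asymmetric swing (25%) / stance cycle
    rate <- rep(p$step_rate_hz, n)
    if (effect > 0) rate[odw] <- rate[odw] * p$step_slowdown
    phase <- cumsum(rate) / p$frame_rate
    swingStance <- function(ph) {
      f <- ph %% 1
      ifelse(f < 0.25, f / 0.25, 1 - (f - 0.25) / 0.75)
    }
    legs <- list()
    legPhase <- c(L1 = 0, R2 = 0, L3 = 0, R1 = 0.5, L2 = 0.5, R3 = 0.5)
    legOffset <- list(L1 = c(-8, 15), L2 = c(-10, 0), L3 = c(-8, -15),
                      R1 = c(8, 15), R2 = c(10, 0), R3 = c(8, -15))
    for (leg in names(legPhase)) {
      y <- legOffset[[leg]][2] +
        p$step_amp_mm * swingStance(phase + legPhase[leg]) +
        stats::rnorm(n, 0, 0.1)
      legs[[leg]] <- cbind(
        x = legOffset[[leg]][1] + stats::rnorm(n, 0, 0.1),
        y = y,
        z = stats::rnorm(n, 0, 0.1))
    }

    points <- c(list(head = headXYZ, ant_L = antL, ant_R = antR), legs)
    tr <- trial(trial_id = trial_id, animal_id = animal_id,
                odour = if (p$is_sham) "air_sham" else odour,
                frame_rate = p$frame_rate, points = points, protocol = pr)
    truth <- list(responsive = if (effect > 0) responsive else NA_character_,
                  azimuth_shift_deg = effect * p$azimuth_shift_deg,
                  elevation_gain = if (effect > 0) p$elevation_gain else 1,
                  burst_freq_hz = p$burst_freq_hz,
                  burst_amp_deg = effect * p$burst_amp_deg,
                  contra_range_gain = if (effect > 0) p$contra_range_gain
                                      else 1,
                  step_slowdown = if (effect > 0) p$step_slowdown else 1,
                  artifact_deg = p$artifact_deg,
                  stream = p$stream, is_sham = p$is_sham, seed = seed)
    list(trial = tr, truth = truth)
  })
}

#' Generate a coupled antennal-speed / PID recording
#'
#' A combined angular speed trace cycling through several movement regimes
#' (slow to fast sweeping), and a PID voltage whose extrema rate and
#' positive contrast scale affinely with the instantaneous speed:
#' `rate = rate0 + rate_per_speed * speed` (Hz) and
#' `contrast = mag0 + mag_per_speed * speed` (V), plus a slow baseline
#' drift and white noise. In control mode the antenna is fixed
#' (speed = 0) throughout.
#'
#' @param duration_s recording length (s).
#' @param frame_rate samples per second.
#' @param rate0,rate_per_speed fluctuation-rate coupling (Hz, Hz per
#'   deg/s).
#' @param mag0,mag_per_speed contrast coupling (V, V per deg/s).
#' @param max_speed peak regime speed (deg/s).
#' @param n_regimes number of movement regimes.
#' @param noise_sd_v PID white-noise s.d. (V).
#' @param control fixed-antenna control mode.
#' @param seed integer seed.
#' @return list: `speed` (numeric per frame), `pid` (a [PIDTrace-class]),
#'   `truth` (the coupling coefficients).
#' @export
generatePidExperiment <- function(duration_s = 60, frame_rate = 100,
                                  rate0 = 4, rate_per_speed = 0.01,
                                  mag0 = 0.05, mag_per_speed = 0.001,
                                  max_speed = 300, n_regimes = 6L,
                                  noise_sd_v = 0.0015, control = FALSE,
                                  seed = 1L) {
  stopifnot(is.finite(rate_per_speed), is.finite(mag_per_speed))
  withSeed(seed, {
    n <- round(duration_s * frame_rate)
    t <- (seq_len(n) - 1) / frame_rate
    speed <- if (control) rep(0, n) else {
      targets <- withSeed(seed + 1L,
                          sample(seq(0.1, 1, length.out = n_regimes)))
      regime <- pmin(floor(t / (duration_s / n_regimes)) + 1L, n_regimes)
      ## quasi-steady regimes with mild modulation: the 2 s analysis
      ## windows are chosen to capture near-constant movement bouts
      base <- max_speed * targets[regime]
      raw <- base * (0.9 + 0.1 * sin(2 * pi * 0.8 * t)) +
        stats::rnorm(n, 0, max_speed * 0.02)
      pmax(movingAverage(raw, 0.2, frame_rate), 0)
    }
    rate <- rate0 + rate_per_speed * speed
    mag <- mag0 + mag_per_speed * speed
    phase <- cumsum(rate / 2) / frame_rate        # extrema rate = 2 * freq
    ## band-limited sensor noise: the PID's response time keeps sample-to-
    ## sample noise from producing spurious extrema
    noise <- movingAverage(stats::rnorm(n, 0, noise_sd_v * 2), 0.05,
                           frame_rate)
    volts <- 0.5 + 0.05 * sin(2 * pi * 0.05 * t) +
      (mag / 2) * sin(2 * pi * phase) + noise
    pid <- new("PIDTrace", time_s = t, volts = volts,
               minima = integer(0), maxima = integer(0))
    list(speed = speed, pid = pid,
         truth = list(rate0 = rate0, rate_per_speed = rate_per_speed,
                      mag0 = mag0, mag_per_speed = mag_per_speed,
                      control = control, seed = seed))
  })
}

#' Generate a smoke-visualisation sequence with a carved wake
#'
#' Frames hold a Gaussian-profile bright band (the smoke stream) running
#' along the flow axis plus uniform speckle noise; from the second frame on,
#' an optional wake — the gap an antenna carves when capturing smoke
#' particles — removes `wake_rows` rows from one edge of the band. The mask
#' holds a synthetic body silhouette. The first frame (no wake) is the
#' reference frame for width normalization.
#'
#' @param n_frames frames in the sequence.
#' @param height,width frame size in pixels (rows run left-to-right across
#'   the stream).
#' @param band_centre_row,band_sd_rows Gaussian band position and width.
#' @param band_intensity peak band intensity in [0, 1].
#' @param noise_max speckle noise upper bound.
#' @param threshold shared binarization threshold.
#' @param wake_rows rows carved out of the band edge (0 = no wake).
#' @param seed integer seed.
#' @return list: `sequence` (a [SmokeSequence-class]) and `truth`
#'   (`wake_rows`, band extent under the threshold).
#' @export
generateSmokeSequence <- function(n_frames = 5L, height = 120L,
                                  width = 160L, band_centre_row = 60,
                                  band_sd_rows = 15, band_intensity = 0.8,
                                  noise_max = 0.08, threshold = 0.3,
                                  wake_rows = 20L, seed = 1L) {
  stopifnot(height > 0, width > 0, band_sd_rows > 0)
  withSeed(seed, {
    rows <- seq_len(height)
    profile <- band_intensity *
      exp(-(rows - band_centre_row)^2 / (2 * band_sd_rows^2))
    ## visible band extent once thresholded: speckle noise lifts edge rows,
    ## so a row shows smoke wherever the profile clears the threshold for a
    ## non-negligible share of its pixels
    bandRows <- range(which(profile >= threshold - 0.95 * noise_max))
    frames <- lapply(seq_len(n_frames), function(i) {
      f <- matrix(profile, height, width) +
        matrix(stats::runif(height * width, 0, noise_max), height, width)
      if (i > 1L && wake_rows > 0L) {
        ## the antenna sweeps in from one side, carving the wake out of the
        ## band edge
        carve <- seq(bandRows[1], length.out = min(wake_rows, diff(bandRows)))
        f[carve, ] <- matrix(stats::runif(length(carve) * width, 0,
                                          noise_max), length(carve), width)
      }
      pmin(pmax(f, 0), 1)
    })
    mask <- matrix(FALSE, height, width)
    mask[, seq_len(25L)] <- TRUE          # body silhouette at the left edge
    roi <- c(max(1L, bandRows[1] - 25L), min(height, bandRows[2] + 25L),
             30L, width - 5L)
    seqn <- smokeSequence(frames, threshold = threshold, roi = roi,
                          mask = mask, left_right_axis = "row")
    list(sequence = seqn,
         truth = list(wake_rows = wake_rows, band_rows = bandRows,
                      seed = seed))
  })
}

#' Generate a two-shelter arena track with prescribed occupancy
#'
#' A Markov state walk over {odour shelter, control shelter, open arena}
#' whose stationary distribution matches the prescribed occupancy
#' fractions; within a state the animal performs a reflected random walk
#' inside the shelter disc or the open arena.
#'
#' @param frac_odour,frac_control expected occupancy fractions (sum <= 1).
#' @param duration_s session length (s).
#' @param frame_rate track sampling rate (Hz).
#' @param switch_prob per-frame probability of resampling the state
#'   (controls visit duration).
#' @param arena_r_mm,zone_r_mm arena and shelter radii.
#' @param seed integer seed.
#' @return list: `track` (an [ArenaTrack-class]) and `truth` (the
#'   fractions).
#' @export
generateArenaTrack <- function(frac_odour = 0.3, frac_control = 0.1,
                               duration_s = 1800, frame_rate = 5,
                               switch_prob = 0.05, arena_r_mm = 450,
                               zone_r_mm = 80, seed = 1L) {
  stopifnot(frac_odour >= 0, frac_control >= 0,
            frac_odour + frac_control <= 1)
  withSeed(seed, {
    n <- round(duration_s * frame_rate)
    probs <- c(odour = frac_odour, control = frac_control,
               open = 1 - frac_odour - frac_control)
    states <- character(n)
    states[1] <- sample(names(probs), 1, prob = probs)
    switch <- stats::runif(n) < switch_prob
    for (i in 2:n)
      states[i] <- if (switch[i]) sample(names(probs), 1, prob = probs)
                   else states[i - 1]
    zones <- list(odour = c(-300, 0, zone_r_mm),
                  control = c(300, 0, zone_r_mm))
    x <- y <- numeric(n)
    pos <- c(0, 0)
    for (i in seq_len(n)) {
      st <- states[i]
      if (st == "open") {
        pos <- pos + stats::rnorm(2, 0, 15)
        if (sqrt(sum(pos^2)) > arena_r_mm * 0.95)
          pos <- pos * (arena_r_mm * 0.9) / sqrt(sum(pos^2))
        for (z in zones)                  # stay out of the shelters
          if (sum((pos - z[1:2])^2) <= z[3]^2) {
            d <- pos - z[1:2]
            nd <- sqrt(sum(d^2))
            if (nd == 0) d <- c(1, 0) else d <- d / nd
            pos <- z[1:2] + d * (z[3] + 1)
          }
      } else {
        z <- zones[[st]]
        if (sum((pos - z[1:2])^2) > z[3]^2) pos <- z[1:2]
        pos <- pos + stats::rnorm(2, 0, 5)
        if (sum((pos - z[1:2])^2) > (0.9 * z[3])^2) {
          d <- pos - z[1:2]
          pos <- z[1:2] + d * (0.85 * z[3]) / sqrt(sum(d^2))
        }
      }
      x[i] <- pos[1]; y[i] <- pos[2]
    }
    track <- new("ArenaTrack", time_s = (seq_len(n) - 1) / frame_rate,
                 x = x, y = y, zones = zones, duration = duration_s)
    list(track = track,
         truth = list(frac_odour = frac_odour, frac_control = frac_control,
                      expected_pi = frac_odour - frac_control, seed = seed))
  })
}

#' Write a simulated scenario to disk in the pipeline's file formats
#'
#' Generates a named scenario and writes exactly the files the readers
#' consume, plus a `ground_truth.yml`. All randomness flows from the single
#' seed via a documented splitting scheme ([splitSeed()]), so each trial is
#' independently reproducible and the output is byte-identical under a
#' fixed seed.
#'
#' @param scenario one of `"static1"`, `"static2"`, `"moving"`, `"pid"`,
#'   `"smoke"`, `"arena"`, `"null"` (a static1 odour/sham pair with all
#'   effect sizes zero).
#' @param seed master seed.
#' @param out_dir output directory (created).
#' @param n_trials trials to generate (trial scenarios only).
#' @return invisibly, the ground-truth list.
#' @export
simulateScenario <- function(scenario = c("static1", "static2", "moving",
                                          "pid", "smoke", "arena", "null"),
                             seed = 1L, out_dir, n_trials = 4L) {
  scenario <- match.arg(scenario)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truths <- list()
  if (scenario %in% c("static1", "static2", "moving", "null")) {
    seeds <- splitSeed(seed, 2L * n_trials)
    base <- if (scenario == "null")
      trialGeneratorParams(azimuth_shift_deg = 0, elevation_gain = 1,
                           burst_amp_deg = 0, step_slowdown = 1)
    else trialGeneratorParams(stream = scenario,
                              duration_s = if (scenario == "moving") 30 else 12,
                              onset_s = 5,
                              offset_s = if (scenario == "moving") 23 else 7)
    for (i in seq_len(n_trials)) {
      id <- sprintf("%s_%02d", scenario, i)
      g <- generateTrial(base, seed = seeds[i], trial_id = id,
                         animal_id = sprintf("animal_%02d", i))
      writeTrial(g$trial, file.path(out_dir, paste0(id, "_tracking.csv")),
                 file.path(out_dir, paste0(id, "_protocol.yml")))
      truths[[id]] <- g$truth
      ## matched sham control for the same animal
      shamP <- base; shamP$is_sham <- TRUE
      gs <- generateTrial(shamP, seed = seeds[n_trials + i],
                          trial_id = paste0(id, "_sham"),
                          animal_id = sprintf("animal_%02d", i))
      writeTrial(gs$trial,
                 file.path(out_dir, paste0(id, "_sham_tracking.csv")),
                 file.path(out_dir, paste0(id, "_sham_protocol.yml")))
      truths[[paste0(id, "_sham")]] <- gs$truth
    }
  } else if (scenario == "pid") {
    g <- generatePidExperiment(seed = seed)
    writePIDTrace(g$pid, file.path(out_dir, "pid_trace.csv"))
    utils::write.csv(data.frame(time_s = g$pid@time_s, speed = g$speed),
                     file.path(out_dir, "antennal_speed.csv"),
                     row.names = FALSE, quote = FALSE)
    gc2 <- generatePidExperiment(control = TRUE, seed = seed + 1L)
    writePIDTrace(gc2$pid, file.path(out_dir, "pid_trace_control.csv"))
    truths$pid <- g$truth
  } else if (scenario == "smoke") {
    g <- generateSmokeSequence(seed = seed)
    writeSmokeSequence(g$sequence, file.path(out_dir, "smoke"))
    truths$smoke <- g$truth
  } else if (scenario == "arena") {
    g <- generateArenaTrack(seed = seed)
    writeArenaTrack(g$track, file.path(out_dir, "arena_track.csv"),
                    file.path(out_dir, "arena_zones.yml"))
    truths$arena <- g$truth
  }
  yaml::write_yaml(truths, file.path(out_dir, "ground_truth.yml"))
  invisible(truths)
}
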