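test_that("ecHT phase hits the landmarks of a pure 1 Hz tone", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  x <- sin(2 * pi * t)                     # rising zero at t = 0
  at <- function(tt) {
    i <- round(tt * fs) + 1
    echt_phase(x[(i - 999):i], c(0.1, 4.5), fs, order = 3)$phase_deg
  }
  expect_equal(at(5.25), 90, tolerance = 5)    # peak
  expect_equal(at(5.75), 270, tolerance = 5)   # trough
  expect_lt(abs(circ_mean_err(at(5.00), 0)), 5)  # rising zero crossing

  expect_error(echt_phase(rnorm(32), fs = 500), "64")
  expect_error(echt_phase(c(rnorm(100), NA), fs = 500), "NaN")
})

test_that("ecHT circular RMS error under noise stays below 20 degrees", {
  fs <- 500
  t <- seq(0, 12, by = 1 / fs)
  clean <- sin(2 * pi * t)
  set.seed(7)
  x <- clean + rnorm(length(t), sd = sqrt(0.5 / 10))  # SNR 10 (power)
  oracle <- instantaneous_phase(clean)
  qs <- seq(3, 11, by = 0.05)
  err <- vapply(qs, function(tt) {
    i <- round(tt * fs) + 1
    p <- echt_phase(x[(i - 999):i], c(0.1, 4.5), fs, order = 3)$phase_deg
    d <- (p - oracle[i]) %% 360
    if (d > 180) d - 360 else d
  }, 0)
  expect_lt(sqrt(mean(err^2)), 20)
})

test_that("online SO candidate arming follows the threshold logic", {
  fs <- 500
  cfg <- stimulation_config("F")
  # constant zero signal: nothing fires
  expect_equal(nrow(detect_so_candidate(rep(0, 5000), fs, cfg)), 0)

  # SO trough -90, PTP 150: down then up, in that order
  w <- c(rep(0, 1000), so_waveform(fs, 1, -90, 150), rep(0, 1000))
  ev <- detect_so_candidate(w, fs, cfg)
  expect_equal(ev$type, c("down_detected", "up_detected"))
  expect_lt(ev$idx[1], which.min(w))          # arming before the trough
  expect_gt(ev$idx[2], which.min(w))          # PTP reached on the rising flank
  expect_equal(w[ev$idx[1]] < -41, TRUE)

  # trough -50 crosses the arming threshold but PTP 60 < 77: down only
  w2 <- c(rep(0, 1000), so_waveform(fs, 1, -50, 60), rep(0, 1000))
  ev2 <- detect_so_candidate(w2, fs, cfg)
  expect_equal(ev2$type, "down_detected")

  expect_error(stimulation_config("X"), "unknown sex")
})

test_that("condition balancing silences down intervals when down leads", {
  expect_equal(balance_conditions(c(up = 10, down = 12), "down"), "silence")
  expect_equal(balance_conditions(c(up = 12, down = 10), "down"), "run")
  expect_equal(balance_conditions(c(up = 10, down = 10), "down"), "run")
  expect_equal(balance_conditions(c(up = 0, down = 100), "up"), "run")
})

test_that("a silenced down interval yields a 5-minute no-stimulation span", {
  fs <- 500
  dur <- 1500
  # plant valid SO trains only inside the first down interval (240-420 s with
  # the default up-first schedule), so validated down cues outnumber up cues
  # and the second down interval is silenced
  times <- as.vector(outer(0:4, seq(250, 400, by = 9), `+`))
  gen <- generate_sleep_eeg(duration_s = dur, fs = fs, channels = "Fpz",
                            so = list(times = times),
                            spindle = list(rate_per_min = 0),
                            noise = list(sd_uV = 3), seed = 21)
  log <- run_closed_loop(gen$recording,
                         stimulation_config("F", echt_filter_order = 3),
                         seed = 1)
  expect_gt(log$counters[["down"]], 0)
  expect_equal(log$counters[["up"]], 0)
  expect_true("silenced_down" %in% log$intervals$type)
  # contiguous rest + silenced-down + rest = 5 min
  iv <- log$intervals[order(log$intervals$start_s), ]
  sil <- which(iv$type == "silenced_down")[1]
  expect_equal(iv$type[c(sil - 1, sil + 1)], c("rest", "rest"))
  expect_equal(iv$end_s[sil + 1] - iv$start_s[sil - 1], 300)
})

test_that("closed loop emits intervals but no cues without slow oscillations", {
  gen <- generate_sleep_eeg(duration_s = 900, fs = 500, channels = "Fpz",
                            so = list(rate_per_min = 0),
                            spindle = list(rate_per_min = 0),
                            noise = list(sd_uV = 5), seed = 6)
  log <- run_closed_loop(gen$recording, stimulation_config("F"), seed = 1)
  expect_equal(nrow(log$cues), 0)
  expect_gt(nrow(log$intervals), 0)
})

test_that("closed loop warns and returns empty log without N2/N3 sleep", {
  gen <- generate_sleep_eeg(duration_s = 120, fs = 500, channels = "Fpz",
                            hypnogram = rep("REM", 4),
                            so = list(rate_per_min = 0),
                            spindle = list(rate_per_min = 0),
                            noise = list(sd_uV = 5), seed = 6)
  expect_warning(log <- run_closed_loop(gen$recording, stimulation_config("F")),
                 "N2/N3")
  expect_equal(nrow(log$cues), 0)
  expect_match(log$status, "no N2/N3")
})

test_that("truncating the recording reproduces the cue-log prefix", {
  gen <- generate_sleep_eeg(duration_s = 1200, fs = 500, channels = "Fpz",
                            so = list(rate_per_min = 6),
                            spindle = list(rate_per_min = 0),
                            noise = list(sd_uV = 5), seed = 11)
  cfg <- stimulation_config("F", echt_filter_order = 3)
  full <- run_closed_loop(gen$recording, cfg, seed = 1)
  half <- eeg_recording(gen$recording$signal[1:(600 * 500), , drop = FALSE],
                        500, "Fpz", gen$recording$hypnogram[1:20])
  pre <- run_closed_loop(half, cfg, seed = 1)
  cutoff <- 595  # leave the validation window clear of the cut edge
  a <- full$cues[full$cues$onset_s < cutoff, ]
  b <- pre$cues[pre$cues$onset_s < cutoff, ]
  expect_equal(a$onset_s, b$onset_s)
  expect_equal(a$condition, b$condition)
  expect_equal(a$phase_deg, b$phase_deg)
})

test_that("phase targeting on clean SO trains is accurate in both conditions", {
  gen <- so_train_recording(duration_s = 600, noise_sd = 0, seed = 1)
  log <- run_closed_loop(gen$recording,
                         stimulation_config("F", echt_filter_order = 3),
                         seed = 1)
  truth <- oracle_phase(gen$recording)[round(log$cues$onset_s * 500) + 1]
  for (cc in c("up", "down")) {
    sel <- log$cues$condition == cc
    expect_gt(sum(sel), 30)
    expect_lt(abs(circ_mean_err(log$cues$phase_deg[sel], truth[sel])), 10)
    expect_gt(resultant_len(truth[sel]), 0.8)
  }
  up_mean <- circ_mean_dir(truth[log$cues$condition == "up"])
  expect_lt(abs(circ_mean_err(up_mean, 90)), 15)
})

test_that("cue spacing rate classification matches the band boundaries", {
  expect_equal(cue_rate_in_band(seq(0, 20, by = 1), seed = 1)$fraction, 1)
  expect_equal(cue_rate_in_band(seq(0, 100, by = 10), seed = 1)$fraction, 1)
  expect_equal(cue_rate_in_band(seq(0, 110, by = 11), seed = 1)$fraction, 0)
  expect_error(cue_rate_in_band(5), "at least 2")

  # mixed spacing: brute-force hand count
  times <- cumsum(c(0, 0.8, 1.2, 11, 0.21, 5, 12, 0.3))
  gaps <- diff(times)
  expected <- mean(1 / gaps >= 0.1 & 1 / gaps <= 4.5)
  r <- cue_rate_in_band(times, n_boot = 200, seed = 2)
  expect_equal(r$fraction, expected)
  expect_true(r$ci[1] <= r$fraction && r$fraction <= r$ci[2])
})
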