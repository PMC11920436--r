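test_that("SO detector applies each logical threshold", {
  fs <- 500
  # single planted SO over a faint 1/f background (a strictly flat background
  # leaves un-physiological filter tails that never recross zero)
  mk <- function(trough, ptp, freq = 1) {
    gen <- generate_sleep_eeg(duration_s = 30, fs = fs, channels = "Fpz",
                              so = list(times = 15, trough_uV = trough,
                                        ptp_uV = ptp, freq_hz = freq),
                              spindle = list(rate_per_min = 0),
                              noise = list(sd_uV = 2), seed = 99)
    detect_slow_oscillations(gen$recording, "Fpz")
  }
  # compliant: trough -80, PTP 120, half-waves 0.5 s
  ev <- mk(-80, 120)
  expect_equal(nrow(ev), 1)
  expect_lt(ev$trough_uV, -40)
  expect_gte(ev$ptp_uV, 75)
  expect_true(audit_so_events(ev))

  # PTP below 75 uV after filtering: rejected
  expect_equal(nrow(mk(-45, 60)), 0)
  # trough too shallow for peak picking
  expect_equal(nrow(mk(-25, 80)), 0)
  # negative half-wave too long (0.3 Hz -> 1.67 s)
  expect_equal(nrow(mk(-80, 120, freq = 0.3)), 0)

  expect_error(detect_slow_oscillations(
    eeg_recording(matrix(0, 1000, 1), 500, "Cz"), "Fpz"), "not in recording")
})

test_that("compliant and non-compliant planted waves separate exactly", {
  fs <- 500
  # 150 compliant + 50 non-compliant (PTP too small after filtering)
  t_comp <- seq(5, 1796, length.out = 150)
  t_non <- t_comp[seq(2, 150, by = 3)] + 6
  sig <- rep(0, 1800 * fs)
  add <- function(sig, tt, w) {
    i0 <- round(tt * fs) - 125           # trough lands at tt
    sig[i0:(i0 + length(w) - 1)] <- sig[i0:(i0 + length(w) - 1)] + w
    sig
  }
  for (tt in t_comp) sig <- add(sig, tt, so_waveform(fs, 1, -80, 150))
  for (tt in t_non) sig <- add(sig, tt, so_waveform(fs, 1, -30, 55))
  set.seed(50)
  sig <- sig + rnorm(length(sig), sd = 1)
  rec <- eeg_recording(matrix(sig, ncol = 1), fs, "Fpz")
  ev <- detect_slow_oscillations(rec, "Fpz")
  expect_equal(nrow(ev), 150)
  d <- vapply(t_comp, function(tt) min(abs(ev$trough_s - tt)), 0)
  expect_true(all(d < 0.2))
})

test_that("SO detection is deterministic and monotone in the PTP threshold", {
  gen <- generate_sleep_eeg(duration_s = 600, fs = 500, channels = "Fpz",
                            so = list(rate_per_min = 5,
                                      amplitude_jitter = 0.25),
                            spindle = list(rate_per_min = 0),
                            noise = list(sd_uV = 6), seed = 51)
  a <- detect_slow_oscillations(gen$recording, "Fpz")
  b <- detect_slow_oscillations(gen$recording, "Fpz")
  expect_identical(a, b)
  counts <- vapply(c(75, 100, 125, 150), function(thr) {
    nrow(detect_slow_oscillations(gen$recording, "Fpz",
                                  so_detection_params(ptp = c(thr, 500))))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
  # audit: every returned event re-passes the logical thresholds
  expect_true(all(audit_so_events(a)))
})

test_that("spindle detector recovers planted bursts and rejects bad durations", {
  gen <- generate_sleep_eeg(duration_s = 600, fs = 500, channels = "C3",
                            so = list(rate_per_min = 0),
                            spindle = list(times = seq(10, 590, by = 12),
                                           freq_hz = 13, dur_s = 1,
                                           amp_uV = 30),
                            noise = list(sd_uV = 5), seed = 2)
  sp <- detect_spindles(gen$recording)
  expect_equal(nrow(sp), nrow(gen$truth$spindle_events))
  expect_true(all(abs(sp$duration_s - 1) <= 0.2))
  expect_true(all(abs(sp$freq_hz - 13) < 1.5))

  for (d in c(0.2, 4)) {
    g <- generate_sleep_eeg(duration_s = 120, fs = 500, channels = "C3",
                            so = list(rate_per_min = 0),
                            spindle = list(times = 30, freq_hz = 13,
                                           dur_s = d, amp_uV = 30),
                            noise = list(sd_uV = 5), seed = 3)
    expect_equal(nrow(detect_spindles(g$recording)), 0)
  }
  expect_error(detect_spindles(
    eeg_recording(matrix(0, 100, 1), 500, "C3")), "shorter than")
})

test_that("cross-channel merging is transitive with a 500 ms window", {
  ev <- data.frame(kind = "spindle", channel = c("C3", "C4"),
                   onset_s = c(0, 0.3), offset_s = c(1, 1.3),
                   duration_s = 1, freq_hz = 13, amp_uV = c(20, 25))
  m <- merge_cross_channel(ev)
  expect_equal(nrow(m), 1)
  expect_equal(m$onset_s, 0)
  expect_equal(m$offset_s, 1.3)
  expect_equal(m$n_channels, 2)

  ev$onset_s <- c(0, 0.6)
  expect_equal(nrow(merge_cross_channel(ev)), 2)

  chain <- data.frame(kind = "spindle", channel = c("C3", "Cz", "C4"),
                      onset_s = c(0, 0.4, 0.8), offset_s = c(1, 1.4, 1.8),
                      duration_s = 1, freq_hz = 13, amp_uV = 20)
  expect_equal(nrow(merge_cross_channel(chain)), 1)
})

test_that("per-interval metrics scale with the planted rate", {
  iv <- data.frame(condition = c("up", "down", "not"),
                   start_s = c(0, 600, 1200), end_s = c(600, 1200, 1800))
  # empty event list -> zero densities
  empty <- clsleep:::empty_osc_events()
  m0 <- event_metrics_by_interval(empty, iv)
  expect_equal(m0$density_per_min, rep(0, 3))

  # 2x planted rate in up intervals
  ev <- data.frame(kind = "spindle", channel = "C3",
                   onset_s = c(seq(5, 595, by = 5), seq(605, 1195, by = 10),
                               seq(1205, 1795, by = 10)),
                   offset_s = 0, duration_s = 1, freq_hz = 13, amp_uV = 20)
  ev$offset_s <- ev$onset_s + 1
  m <- event_metrics_by_interval(ev, iv)
  ratio <- m$density_per_min[m$condition == "up"] /
    m$density_per_min[m$condition == "down"]
  expect_equal(ratio, 2, tolerance = 0.05)

  expect_error(event_metrics_by_interval(ev, data.frame(
    condition = "up", start_s = 0, end_s = 0)), "zero-duration")
})
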