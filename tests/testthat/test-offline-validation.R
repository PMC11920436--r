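test_that("online validation applies the trough and PTP criteria", {
  fs <- 500
  cfg <- stimulation_config("F")
  pad <- rep(0, 5 * fs)
  mk <- function(trough, ptp) c(pad, so_waveform(fs, 1, trough, ptp), pad)

  # boundary: trough -39 uV fails the -40 criterion
  w <- mk(-39, 120)
  expect_false(online_validate(5.25, w, fs, cfg))
  # clear SO: trough -80, PTP 120
  w2 <- mk(-80, 120)
  expect_true(online_validate(5.25, w2, fs, cfg))   # at the trough
  expect_true(online_validate(5.75, w2, fs, cfg))   # at the peak
  # edge transient: indeterminate
  expect_true(is.na(online_validate(0.1, w2, fs, cfg)))
})

test_that("online validation agrees >= 99% with a brute-force window scan", {
  gen <- generate_sleep_eeg(duration_s = 1800, fs = 500, channels = "Fpz",
                            so = list(rate_per_min = 5,
                                      amplitude_jitter = 0.1),
                            spindle = list(rate_per_min = 0),
                            noise = list(sd_uV = 5), seed = 30)
  fs <- 500
  cfg <- stimulation_config("F")
  v <- clsleep:::validation_trace(gen$recording$signal[, 1], fs, cfg)
  # 500 probe cues: 300 on planted SOs (as delivered cues are) and 200 in
  # event-free stretches at least 2.5 s from any trough
  set.seed(31)
  tr_times <- gen$truth$so_events$trough_s
  on_so <- sample(tr_times, 300, replace = TRUE) + runif(300, -0.3, 0.3)
  gaps <- runif(400, 10, 1790)
  gaps <- gaps[vapply(gaps, function(g) min(abs(tr_times - g)) > 2.5, TRUE)]
  cues <- c(on_so, gaps[seq_len(200)])
  impl <- vapply(cues, function(tt) {
    isTRUE(online_validate(tt, v, fs, cfg))
  }, TRUE)
  # oracle: exhaustive trough/peak search in +/- 2 s around the cue
  oracle <- vapply(cues, function(tt) {
    i <- round(tt * fs) + 1
    w <- v[max(1, i - 2 * fs):min(length(v), i + 2 * fs)]
    min(w) <= -40 && (max(w) - min(w)) >= 75
  }, TRUE)
  expect_gte(mean(impl == oracle), 0.99)
})

test_that("cue accuracy classification matches its definition", {
  fs <- 500
  gen <- generate_sleep_eeg(duration_s = 30, fs = fs, channels = "Fpz",
                            so = list(times = 15, trough_uV = -80,
                                      ptp_uV = 150),
                            spindle = list(rate_per_min = 0),
                            noise = list(sd_uV = 2), seed = 98)
  rec <- gen$recording
  ph <- oracle_phase(rec)
  win <- (15 * fs):(16 * fs)            # trough (270) to next peak (90)
  t_peak <- (win[which(ph[win] >= 89.5 & ph[win] < 180)[1]] - 1) / fs
  win0 <- (14.5 * fs):(15 * fs)         # descending flank into the trough
  t_desc <- (win0[which(ph[win0] >= 200 & ph[win0] < 260)[1]] - 1) / fs
  cues <- data.frame(onset_s = c(t_peak, t_desc),
                     condition = c("up", "up"))
  res <- classify_cue_accuracy(cues, rec, "F")
  expect_true(res$records$true_so[1])
  expect_true(res$records$accurate[1])          # phase ~90 inside [0, 180]
  expect_gt(res$records$phase_deg[2], 180)      # well past the up window
  expect_false(res$records$accurate[2])
  expect_equal(res$accuracy_pct, 50)
  expect_error(classify_cue_accuracy(data.frame(onset_s = 99, condition = "up"),
                                     rec, "F"), "outside")
  expect_error(classify_cue_accuracy(cues, rec, "Q"), "unknown sex")
})

test_that("summary accuracy equals the brute-force record count", {
  gen <- so_train_recording(duration_s = 900, noise_sd = 4, seed = 33)
  log <- run_closed_loop(gen$recording,
                         stimulation_config("F", echt_filter_order = 3),
                         seed = 1)
  res <- classify_cue_accuracy(log, gen$recording, "F")
  recs <- res$records
  # recompute from the per-record fields
  byhand <- with(recs, true_so &
                   ifelse(condition == "up",
                          phase_deg >= 0 & phase_deg <= 180,
                          phase_deg >= 180 & phase_deg < 360))
  expect_identical(recs$accurate, byhand)
  expect_equal(res$accuracy_pct, 100 * mean(byhand))
  # idempotent / order-independent
  res2 <- classify_cue_accuracy(log$cues[rev(seq_len(nrow(log$cues))), ],
                                gen$recording, "F")
  expect_equal(sort(res2$records$onset_s), sort(recs$onset_s))
  expect_equal(res2$accuracy_pct, res$accuracy_pct)
})

test_that("circular summary: degenerate and Monte-Carlo cases", {
  r <- circular_summary(rep(90, 50))
  expect_equal(r$mean_deg, 90)
  expect_equal(r$resultant_length, 1)

  r2 <- circular_summary(c(0, 180))
  expect_false(r2$defined)
  expect_true(is.na(r2$mean_deg))

  expect_error(circular_summary(numeric(0)), "empty")

  # von Mises(mu = 93 deg, kappa = 10) via rejection-free wrapped sampling
  set.seed(40)
  n <- 1e4
  # Best-Fisher sampler
  kappa <- 10
  a <- 1 + sqrt(1 + 4 * kappa^2); b <- (a - sqrt(2 * a)) / (2 * kappa)
  r0 <- (1 + b^2) / (2 * b)
  draws <- numeric(n); k <- 0
  while (k < n) {
    u <- runif(3)
    z <- cos(pi * u[1]); f <- (1 + r0 * z) / (r0 + z); cc <- kappa * (r0 - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      k <- k + 1
      draws[k] <- ((sign(u[3] - 0.5) * acos(f)) * 180 / pi + 93) %% 360
    }
  }
  r3 <- circular_summary(draws)
  lo <- r3$ci_deg[1]; hi <- r3$ci_deg[2]
  inside <- if (lo <= hi) 93 >= lo && 93 <= hi else 93 >= lo || 93 <= hi
  expect_true(inside)
  expect_equal(r3$mean_deg, 93, tolerance = 2)
})

test_that("sham cues mirror the true-positive phase distribution", {
  gen <- so_train_recording(duration_s = 900, noise_sd = 3, seed = 44)
  sos <- detect_slow_oscillations(gen$recording, "Fpz")
  expect_gt(nrow(sos), 100)

  # single true up-phase: every up-sham lands on each SO's 90-degree point
  sh <- assign_sham_cues(sos, 90, 270, gen$recording, seed = 2)
  expect_equal(nrow(sh), nrow(sos))
  ph <- oracle_phase(gen$recording)
  up_ph <- ph[round(sh$up_sham_s * 500) + 1]
  expect_lt(abs(circ_mean_err(up_ph, 90)), 6)
  expect_gt(resultant_len(up_ph), 0.99)

  # resampling property: sham phases reproduce the empirical distribution
  set.seed(45)
  true_up <- (rnorm(1000, 90, 25)) %% 360
  sh2 <- assign_sham_cues(sos, true_up, true_up - 180, gen$recording, seed = 3)
  drawn <- sh2$up_phase_deg
  bins <- seq(0, 360, by = 45)
  o <- table(cut(drawn, bins)); e <- table(cut(true_up, bins))
  keep <- e > 0
  p <- suppressWarnings(stats::chisq.test(o[keep],
                                          p = e[keep] / sum(e[keep]))$p.value)
  expect_gt(p, 0.05)

  expect_error(assign_sham_cues(sos, numeric(0), 270, gen$recording),
               "at least one")
})
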