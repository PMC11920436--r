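test_that("epoching arithmetic, edge handling and mask rejection", {
  gen <- generate_sleep_eeg(duration_s = 500, fs = 500, channels = "Fpz",
                            so = list(times = seq(10, 490, by = 4.8)),
                            spindle = list(rate_per_min = 0),
                            noise = list(sd_uV = 3), seed = 60)
  locks <- gen$truth$so_events$trough_s
  ep <- make_epochs(gen$recording, locks, "trough")
  expect_equal(dim(ep$data)[3], 401)       # [-2, 2] s at 100 Hz
  expect_equal(dim(ep$data)[1], length(locks))
  expect_equal(ep$times[201], 0)

  # lock at the recording edge is dropped
  ep2 <- make_epochs(gen$recording, c(0.5, locks), "trough")
  expect_equal(dim(ep2$data)[1], length(locks))
  expect_equal(ep2$n_dropped, 1)

  # cue lock: [-2.5, 2] s -> 451 samples
  ep3 <- make_epochs(gen$recording, locks, "cue")
  expect_equal(dim(ep3$data)[3], 451)

  # mask rejection
  mask <- rep(TRUE, 500 * 500)
  bad <- round(locks[3] * 500) + (-10:10)
  mask[bad] <- FALSE
  ep4 <- make_epochs(gen$recording, locks, "trough", clean_mask = mask)
  expect_equal(dim(ep4$data)[1], length(locks) - 1)

  expect_error(make_epochs(gen$recording, 0.1, "trough"), "zero surviving")
})

test_that("trough-locked ERP recovers the planted waveform", {
  gen <- generate_sleep_eeg(duration_s = 500, fs = 500, channels = "Fpz",
                            so = list(times = seq(10, 490, by = 4.8)),
                            spindle = list(rate_per_min = 0),
                            noise = list(sd_uV = 3), seed = 61)
  ep <- make_epochs(gen$recording, gen$truth$so_events$trough_s, "trough")
  er <- average_erp(ep)
  i0 <- which(ep$times == 0)
  # trough at lock time, near the planted -80 uV (0.1-30 Hz filtering)
  expect_lt(abs(which.min(er$erp[1, ]) - i0), 5)
  expect_lt(er$erp[1, i0], -60)
  # noise averaging: SE shrinks like 1/sqrt(n)
  expect_lt(median(er$se[1, ]), 1)
})

test_that("ERP mean/SE behave on constant, noise and sign-flipped epochs", {
  mk <- function(arr) {
    structure(list(data = arr, times = seq(-2, 2, by = 0.01), fs = 100,
                   lock = "trough", condition = rep("x", dim(arr)[1]),
                   n_dropped = 0), class = "eeg_epochs")
  }
  const <- mk(array(5, c(10, 1, 401)))
  er <- average_erp(const)
  expect_true(all(er$erp == 5))
  expect_true(all(er$se == 0))

  set.seed(62)
  noise <- mk(array(rnorm(500 * 401), c(500, 1, 401)))
  ern <- average_erp(noise)
  expect_gte(mean(abs(ern$erp) < 3 * ern$se), 0.99)

  base <- array(rnorm(10 * 401), c(10, 1, 401))
  flip <- array(0, c(20, 1, 401))
  flip[1:10, , ] <- base
  flip[11:20, , ] <- -base
  expect_true(all(abs(average_erp(mk(flip))$erp) < 1e-12))

  expect_error(average_erp(mk(array(1, c(1, 1, 401)))), "at least 2")
})

test_that("TFR power peaks at the signal frequency and scales quadratically", {
  fs <- 100
  t <- seq(-2, 2, by = 1 / fs)
  mk <- function(x) {
    structure(list(data = array(x, c(1, 1, length(x))), times = t, fs = fs,
                   lock = "trough", condition = "x", n_dropped = 0),
              class = "eeg_epochs")
  }
  tone <- 20 * sin(2 * pi * 10 * t)
  tfr <- compute_tfr(mk(tone))
  mid <- which.min(abs(tfr$times))
  expect_equal(tfr$freqs[which.max(tfr$power[1, , mid])], 10)
  expect_equal(tfr$power[1, tfr$freqs == 10, mid], 200, tolerance = 1)
  # doubling the amplitude quadruples power
  tfr2 <- compute_tfr(mk(2 * tone))
  expect_equal(tfr2$power[1, tfr$freqs == 10, mid] /
                 tfr$power[1, tfr$freqs == 10, mid], 4, tolerance = 1e-6)
  # 20-ms step grid
  expect_equal(unique(round(diff(tfr$times), 10)), 0.02)
  expect_error(compute_tfr(mk(tone), freqs = 2:10), "outside")
})

test_that("TFR ridge follows a chirp's instantaneous frequency", {
  fs <- 100
  t <- seq(-2, 2, by = 1 / fs)
  # linear chirp 8 -> 20 Hz across the epoch
  f_inst <- 8 + (t - t[1]) / 4 * 12
  phase <- 2 * pi * cumsum(f_inst) / fs
  x <- 10 * sin(phase)
  ep <- structure(list(data = array(x, c(1, 1, length(x))), times = t,
                       fs = fs, lock = "trough", condition = "x",
                       n_dropped = 0), class = "eeg_epochs")
  tfr <- compute_tfr(ep)
  sel <- tfr$times > -1 & tfr$times < 1
  ridge <- tfr$freqs[apply(tfr$power[1, , sel], 2, which.max)]
  truth <- 8 + (tfr$times[sel] - t[1]) / 4 * 12
  expect_lt(max(abs(ridge - truth)), 1.5)   # within grid resolution
})

test_that("multi-tone band power matches the closed form within 5%", {
  fs <- 100
  t <- seq(-2, 2, by = 1 / fs)
  amps <- c(12, 8, 5); fqs <- c(10, 15, 20)
  x <- amps[1] * sin(2 * pi * fqs[1] * t) +
    amps[2] * sin(2 * pi * fqs[2] * t + 1) +
    amps[3] * sin(2 * pi * fqs[3] * t + 2)
  ep <- structure(list(data = array(x, c(1, 1, length(x))), times = t,
                       fs = fs, lock = "trough", condition = "x",
                       n_dropped = 0), class = "eeg_epochs")
  tfr <- compute_tfr(ep)
  mid <- which.min(abs(tfr$times))
  got <- sum(tfr$power[1, tfr$freqs %in% fqs, mid])
  expect_equal(got, sum(amps^2 / 2), tolerance = 0.05 * sum(amps^2 / 2))
})

test_that("baseline normalization implements relative change per mode", {
  fs <- 100
  t <- seq(-2.5, 2, by = 1 / fs)
  # power doubles after the lock: amplitude x sqrt(2)
  amp <- ifelse(t < 0, 10, 10 * sqrt(2))
  x <- amp * sin(2 * pi * 10 * t)
  ep <- structure(list(data = array(x, c(1, 1, length(x))), times = t,
                       fs = fs, lock = "cue", condition = "x", n_dropped = 0),
                  class = "eeg_epochs")
  tfr <- baseline_normalize(compute_tfr(ep), "cue")
  f10 <- which(tfr$freqs == 10)
  post <- tfr$times > 0.6 & tfr$times < 1.4
  expect_equal(mean(tfr$power[1, f10, post]), 1, tolerance = 0.05)

  # constant power, whole-epoch baseline: exactly zero
  x2 <- 10 * sin(2 * pi * 10 * t)
  ep2 <- ep; ep2$data <- array(x2, c(1, 1, length(x2)))
  tfr2 <- baseline_normalize(compute_tfr(ep2), "trough")
  expect_lt(max(abs(tfr2$power[1, f10, ])), 0.02)

  expect_error(baseline_normalize(compute_tfr(ep2), "cue",
                                  baseline_window = c(-9, -8)), "outside")
})
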