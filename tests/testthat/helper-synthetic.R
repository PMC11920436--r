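# Shared fixtures, built in code.

# Recording with trains of contiguous SO cycles (5 cycles per train), the
# deep-NREM regime the closed-loop phase tests target.
so_train_recording <- function(duration_s = 600, fs = 500, gap_s = 9,
                               cycles = 5, noise_sd = 0, seed = 1) {
  starts <- seq(10, duration_s - 20, by = gap_s)
  times <- as.vector(outer(0:(cycles - 1), starts, `+`))
  generate_sleep_eeg(duration_s = duration_s, fs = fs, channels = "Fpz",
                     so = list(times = times),
                     spindle = list(rate_per_min = 0),
                     noise = list(sd_uV = noise_sd), seed = seed)
}

# Non-causal oracle phase of the 0.1-4.5 Hz component.
oracle_phase <- function(recording, channel = "Fpz") {
  instantaneous_phase(
    fft_bandpass(recording$signal[, channel], recording$fs, 0.1, 4.5, 0.1))
}

# Signed circular mean error (degrees) folded into (-180, 180].
circ_mean_err <- function(est, truth) {
  d <- (est - truth) %% 360
  d[d > 180] <- d[d > 180] - 360
  m <- atan2(mean(sin(d * pi / 180)), mean(cos(d * pi / 180))) * 180 / pi
  m
}

resultant_len <- function(deg) {
  rad <- deg * pi / 180
  sqrt(mean(sin(rad))^2 + mean(cos(rad))^2)
}

circ_mean_dir <- function(deg) {
  rad <- deg * pi / 180
  (atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi) %% 360
}
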