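# Synthetic sleep EEG with planted slow oscillations and spindles over a 1/f
# background. Ground truth is returned alongside the recording so detector
# recall / false-positive rates can be measured exactly.

#' Construct an EEG recording object
#'
#' @param signal numeric matrix, samples x channels, in microvolts.
#' @param fs sampling rate (Hz).
#' @param channels channel labels (defaults to the matrix column names).
#' @param hypnogram sleep-stage label per 30-s epoch (W/N1/N2/N3/REM); padded
#'   with `"W"`/truncated to `ceiling(duration / 30)` entries.
#' @param start_time recording offset in seconds.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, fs, channels = colnames(signal),
                          hypnogram = NULL, start_time = 0) {
  signal <- as.matrix(signal)
  stopifnot(fs > 0, nrow(signal) > 0)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(signal)))
  stopifnot(length(channels) == ncol(signal))
  colnames(signal) <- channels
  n_epochs <- ceiling(nrow(signal) / fs / 30)
  if (is.null(hypnogram)) hypnogram <- rep("N3", n_epochs)
  check_stages(hypnogram)
  hypnogram <- rep(hypnogram, length.out = n_epochs)
  structure(list(signal = signal, fs = fs, channels = channels,
                 hypnogram = hypnogram, start_time = start_time),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  dur <- nrow(x$signal) / x$fs
  cat(sprintf("<eeg_recording> %d channel(s) [%s], %.1f s @ %g Hz, %d epochs\n",
              length(x$channels), paste(x$channels, collapse = ", "),
              dur, x$fs, length(x$hypnogram)))
  invisible(x)
}

SLEEP_STAGES <- c("W", "N1", "N2", "N3", "REM")

check_stages <- function(stages) {
  bad <- setdiff(unique(stages), SLEEP_STAGES)
  if (length(bad)) stop("unknown sleep stage label(s): ",
                        paste(bad, collapse = ", "))
  invisible(stages)
}

#' Single-cycle biphasic slow-oscillation waveform
#'
#' One period of a raised-cosine biphasic wave: a negative half-wave (trough)
#' followed by a positive half-wave (peak) with independently scalable
#' amplitudes, matching the trough/peak decomposition of the offline
#' detector. The half-wave durations are split inversely to the lobe
#' amplitudes so the cycle integrates to zero; a net-DC transient would
#' otherwise leave a slow rebound after high-pass filtering that distorts the
#' positive half-wave duration seen by the detector.
#'
#' @param fs sampling rate (Hz).
#' @param freq_hz oscillation frequency (Hz); period `1/freq_hz`.
#' @param trough_uV trough amplitude (negative, microvolts).
#' @param ptp_uV peak-to-peak amplitude; the positive peak is
#'   `ptp_uV + trough_uV`.
#' @return numeric vector covering one period.
#' @export
so_waveform <- function(fs, freq_hz = 1, trough_uV = -80, ptp_uV = 150) {
  stopifnot(trough_uV < 0, ptp_uV > -trough_uV)
  amp_neg <- -trough_uV
  amp_pos <- ptp_uV + trough_uV
  period <- 1 / freq_hz
  n_neg <- round(fs * period * amp_pos / (amp_neg + amp_pos))
  n_pos <- round(fs * period) - n_neg
  lobe <- function(n) (1 - cos(2 * pi * seq_len(n) / n)) / 2
  c(trough_uV * lobe(n_neg), amp_pos * lobe(n_pos))
}

#' Tapered sinusoidal spindle waveform
#'
#' Sinusoid under a Tukey (tapered-cosine) envelope: cosine on/off ramps with
#' a flat core, so the burst duration seen by an amplitude-threshold detector
#' matches the nominal duration. A fully Hann-shaped envelope spends most of
#' its span below detection thresholds and systematically shortens detected
#' durations.
#'
#' @param fs sampling rate (Hz).
#' @param freq_hz spindle frequency (Hz), sigma band 11--16 Hz.
#' @param dur_s duration (s).
#' @param amp_uV peak amplitude (microvolts).
#' @param taper_frac fraction of the duration used by each cosine ramp.
#' @return numeric vector.
#' @export
spindle_waveform <- function(fs, freq_hz = 13, dur_s = 1, amp_uV = 30,
                             taper_frac = 0.15) {
  stopifnot(dur_s > 0, amp_uV > 0, taper_frac > 0, taper_frac <= 0.5)
  n <- round(fs * dur_s)
  t <- (seq_len(n) - 1) / fs
  tau <- (seq_len(n) - 1) / (n - 1)
  w <- rep(1, n)
  ramp <- tau < taper_frac
  w[ramp] <- 0.5 * (1 - cos(pi * tau[ramp] / taper_frac))
  ramp <- tau > 1 - taper_frac
  w[ramp] <- 0.5 * (1 - cos(pi * (1 - tau[ramp]) / taper_frac))
  amp_uV * w * sin(2 * pi * freq_hz * t)
}

# Gaussian background scaled to a target broadband SD: an aperiodic neural
# component with power ~ 1/f^exponent above a spectral knee (flat below it)
# plus a white sensor-noise floor carrying `white_frac` of the variance.
# Without the knee and floor, a pure 1/f background concentrates its variance
# in slow (< 1 Hz) half-waves on the SO timescale, which no detector with
# half-wave duration bounds can distinguish from events.
colored_noise <- function(n, fs, sd_uV, exponent = 1, knee_hz = 1,
                          white_frac = 0.5) {
  if (sd_uV == 0) return(numeric(n))
  white <- stats::rnorm(n)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, fs - f)
  w <- pmax(f, knee_hz)^(-exponent / 2)
  w[1] <- 0
  pink <- Re(stats::fft(stats::fft(white) * w, inverse = TRUE)) / n
  pink <- pink / stats::sd(pink)
  x <- sqrt(1 - white_frac) * pink + sqrt(white_frac) * stats::rnorm(n)
  x * sd_uV / stats::sd(x)
}

# Draw event center times uniformly over allowed spans with a minimum
# separation; returns at most n_events times (greedy thinning).
draw_event_times <- function(n_events, spans, min_sep) {
  if (n_events == 0 || nrow(spans) == 0) return(numeric(0))
  total <- sum(spans$end - spans$start)
  u <- sort(stats::runif(n_events * 3, 0, total))
  # map [0, total) onto the union of spans
  offs <- cumsum(c(0, spans$end - spans$start))
  idx <- findInterval(u, offs, rightmost.closed = TRUE)
  idx[idx > nrow(spans)] <- nrow(spans)
  times <- spans$start[idx] + (u - offs[idx])
  keep <- c(TRUE, diff(times) >= min_sep)
  times <- times[keep]
  utils::head(times, n_events)
}

#' Generate synthetic NREM sleep EEG with known ground truth
#'
#' Plants slow oscillations (raised-cosine biphasic cycles) and sleep spindles
#' (Tukey-tapered sigma-band bursts) over a 1/f Gaussian background on a small
#' frontocentral montage. Events are placed only within N2/N3 hypnogram
#' epochs and are identical across channels (no forward modelling).
#'
#' @param duration_s recording length in seconds (default 27000 s = 7.5 h, the
#'   average sleep duration the pipeline is sized for).
#' @param fs sampling rate (Hz), default 1000.
#' @param channels montage labels.
#' @param hypnogram stage per 30-s epoch; default all-N3.
#' @param so list: `rate_per_min`, `trough_uV`, `ptp_uV`, `freq_hz`,
#'   `amplitude_jitter` (fractional SD on amplitudes), or explicit `times`
#'   (trough times, s).
#' @param spindle list: `rate_per_min`, `freq_hz`, `dur_s`, `amp_uV`, or
#'   explicit `times` (onset times, s).
#' @param noise list: `sd_uV` (broadband SD), `exponent` (aperiodic 1/f
#'   slope), `knee_hz` (spectral knee; flat below), `white_frac` (fraction of
#'   variance in the white sensor-noise floor).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return list with elements `recording` (an [eeg_recording]) and `truth`
#'   (ground-truth SO/spindle tables and noise parameters).
#' @export
generate_sleep_eeg <- function(duration_s = 27000, fs = 1000,
                               channels = c("Fpz", "Fz", "C3", "Cz", "C4", "Pz"),
                               hypnogram = NULL,
                               so = list(), spindle = list(), noise = list(),
                               seed = NULL) {
  stopifnot(duration_s > 0, fs > 0)
  so <- utils::modifyList(list(rate_per_min = 5, trough_uV = -80, ptp_uV = 150,
                               freq_hz = 1, amplitude_jitter = 0, times = NULL),
                          so)
  spindle <- utils::modifyList(list(rate_per_min = 2, freq_hz = 13, dur_s = 1,
                                    amp_uV = 30, times = NULL), spindle)
  noise <- utils::modifyList(list(sd_uV = 10, exponent = 1, knee_hz = 1,
                                  white_frac = 0.5), noise)
  if (so$rate_per_min < 0 || spindle$rate_per_min < 0)
    stop("event rates must be non-negative")
  if (noise$sd_uV < 0) stop("noise SD must be non-negative")

  n <- round(duration_s * fs)
  n_epochs <- ceiling(duration_s / 30)
  if (is.null(hypnogram)) hypnogram <- rep("N3", n_epochs)
  check_stages(hypnogram)
  hypnogram <- rep(hypnogram, length.out = n_epochs)

  with_seed(seed, {
    sig <- matrix(0, n, length(channels))
    for (j in seq_along(channels)) {
      sig[, j] <- colored_noise(n, fs, noise$sd_uV, noise$exponent,
                                noise$knee_hz, noise$white_frac)
    }

    nrem <- stage_spans(hypnogram, c("N2", "N3"), duration_s)
    period <- 1 / so$freq_hz
    margin <- period  # keep whole waveform inside the span
    nrem_in <- nrem
    nrem_in$start <- nrem_in$start + margin
    nrem_in$end <- nrem_in$end - margin
    nrem_in <- nrem_in[nrem_in$end > nrem_in$start, , drop = FALSE]

    if (is.null(so$times)) {
      nrem_min <- sum(nrem_in$end - nrem_in$start) / 60
      so_times <- draw_event_times(stats::rpois(1, so$rate_per_min * nrem_min),
                                   nrem_in, 1.5 * period)
    } else so_times <- sort(so$times)

    so_tr <- so$trough_uV * (1 + so$amplitude_jitter * stats::rnorm(length(so_times)))
    so_pp <- so$ptp_uV * (1 + so$amplitude_jitter * stats::rnorm(length(so_times)))
    so_pp <- pmax(so_pp, -so_tr * 1.1)
    for (i in seq_along(so_times)) {
      w <- so_waveform(fs, so$freq_hz, so_tr[i], so_pp[i])
      # place the waveform so its trough lands on the requested time
      i0 <- round(so_times[i] * fs) - which.min(w) + 1
      idx <- i0 + seq_along(w) - 1
      ok <- idx >= 1 & idx <= n
      sig[idx[ok], ] <- sig[idx[ok], ] + w[ok]
    }

    if (is.null(spindle$times)) {
      nrem_min <- sum(nrem_in$end - nrem_in$start) / 60
      sp_times <- draw_event_times(stats::rpois(1, spindle$rate_per_min * nrem_min),
                                   nrem_in, spindle$dur_s + 1)
    } else sp_times <- sort(spindle$times)
    for (tt in sp_times) {
      w <- spindle_waveform(fs, spindle$freq_hz, spindle$dur_s, spindle$amp_uV)
      idx <- round(tt * fs) + seq_along(w)
      ok <- idx >= 1 & idx <= n
      sig[idx[ok], ] <- sig[idx[ok], ] + w[ok]
    }

    rec <- eeg_recording(sig, fs, channels, hypnogram)
    truth <- list(
      so_events = data.frame(
        trough_s = so_times,
        trough_uV = so_tr,
        ptp_uV = so_pp,
        freq_hz = rep(so$freq_hz, length(so_times)),
        onset_s = so_times - 0.5 / so$freq_hz,
        offset_s = so_times + 1.5 / so$freq_hz
      ),
      spindle_events = data.frame(
        onset_s = sp_times,
        duration_s = rep(spindle$dur_s, length(sp_times)),
        freq_hz = rep(spindle$freq_hz, length(sp_times)),
        amp_uV = rep(spindle$amp_uV, length(sp_times))
      ),
      noise_params = noise
    )
    list(recording = rec, truth = truth)
  })
}

# Merge contiguous epochs of the requested stages into time spans (s).
stage_spans <- function(hypnogram, stages, duration_s = NULL) {
  mask <- hypnogram %in% stages
  runs <- logical_runs(mask)
  if (nrow(runs) == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  out <- data.frame(start = (runs$start - 1) * 30, end = runs$end * 30)
  if (!is.null(duration_s)) out$end <- pmin(out$end, duration_s)
  out
}

#' Generate a hypnogram from a stage plan
#'
#' @param duration_s total duration (s).
#' @param plan either a single stage label (whole night), or a data frame with
#'   columns `stage` and `duration_s`, recycled until the duration is covered.
#' @return character vector of stage labels, one per 30-s epoch
#'   (`ceiling(duration_s / 30)` entries).
#' @export
generate_hypnogram <- function(duration_s, plan = "N3") {
  n_epochs <- ceiling(duration_s / 30)
  if (is.character(plan) && length(plan) == 1) {
    check_stages(plan)
    return(rep(plan, n_epochs))
  }
  stopifnot(is.data.frame(plan), all(c("stage", "duration_s") %in% names(plan)))
  check_stages(plan$stage)
  if (sum(plan$duration_s) <= 0) stop("plan must cover a positive duration")
  stages <- character(0)
  while (length(stages) < n_epochs) {
    stages <- c(stages, rep(plan$stage, times = ceiling(plan$duration_s / 30)))
  }
  stages[seq_len(n_epochs)]
}

#' Summary statistics of a hypnogram
#'
#' Sleep efficiency is the percentage of epochs scored as sleep (anything but
#' wake) out of all epochs.
#'
#' @param stages stage labels, one per 30-s epoch.
#' @return list: `n_epochs`, `tst_min` (total sleep time, minutes),
#'   `sleep_efficiency_pct`, `stage_minutes` (named vector).
#' @export
hypnogram_stats <- function(stages) {
  check_stages(stages)
  sleep <- stages != "W"
  list(
    n_epochs = length(stages),
    tst_min = sum(sleep) * 0.5,
    sleep_efficiency_pct = 100 * mean(sleep),
    stage_minutes = vapply(split(stages, factor(stages, SLEEP_STAGES)),
                           length, 0L) * 0.5
  )
}
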