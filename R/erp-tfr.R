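# Cue- and trough-locked epoching, event-related potentials, and
# Hanning-taper time-frequency power with the two baseline-normalization
# modes (pre-cue window for cue-locked data, whole epoch for trough-locked).

#' Build epochs around lock times
#'
#' The signal is band-pass filtered 0.1--30 Hz (zero phase), anti-alias
#' filtered and downsampled to 100 Hz, then segmented around each lock time.
#' Epochs that overlap rejected segments of the clean-data mask, or that run
#' past the recording edge, are dropped.
#'
#' @param recording an [eeg_recording].
#' @param lock_times_s lock times (s).
#' @param lock `"cue"` (window -2.5..2 s) or `"trough"` (window -2..2 s).
#' @param condition condition label stored per epoch.
#' @param clean_mask optional logical vector at the recording's sampling rate;
#'   `FALSE` samples are rejected segments.
#' @param fs_out analysis rate (Hz), default 100.
#' @param window override epoch window `c(lo, hi)` in seconds.
#' @return an `eeg_epochs` object: `data` (epoch x channel x time array, uV),
#'   `times` (s, lock at 0), `fs`, `lock`, `condition`, `n_dropped`.
#' @export
make_epochs <- function(recording, lock_times_s, lock = c("trough", "cue"),
                        condition = "all", clean_mask = NULL, fs_out = 100,
                        window = NULL) {
  lock <- match.arg(lock)
  if (is.null(window)) {
    window <- if (lock == "cue") c(-2.5, 2) else c(-2, 2)
  }
  fs <- recording$fs
  filt <- apply(recording$signal, 2, function(col) {
    fft_bandpass(col, fs, 0.1, 30, transition = 0.1)
  })
  dn <- lapply(seq_len(ncol(filt)), function(j) {
    resample_to(filt[, j], fs, fs_out, cutoff_hz = 40)$x
  })
  sig <- do.call(cbind, dn)
  n <- nrow(sig)
  rel <- seq(round(window[1] * fs_out), round(window[2] * fs_out))
  times <- rel / fs_out

  keep <- logical(length(lock_times_s))
  epochs <- vector("list", length(lock_times_s))
  for (k in seq_along(lock_times_s)) {
    i0 <- round(lock_times_s[k] * fs_out) + 1
    idx <- i0 + rel
    if (idx[1] < 1 || idx[length(idx)] > n) next
    if (!is.null(clean_mask)) {
      src <- round((idx - 1) * fs / fs_out) + 1
      src <- src[src >= 1 & src <= length(clean_mask)]
      if (any(!clean_mask[src])) next
    }
    keep[k] <- TRUE
    epochs[[k]] <- sig[idx, , drop = FALSE]
  }
  if (!any(keep)) stop("zero surviving epochs")
  arr <- array(0, dim = c(sum(keep), ncol(sig), length(rel)),
               dimnames = list(NULL, recording$channels, NULL))
  j <- 0
  for (k in which(keep)) {
    j <- j + 1
    arr[j, , ] <- t(epochs[[k]])
  }
  structure(list(data = arr, times = times, fs = fs_out, lock = lock,
                 condition = rep(condition, sum(keep)),
                 n_dropped = sum(!keep)),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples (%s-locked, %g Hz, %d dropped)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$lock, x$fs,
              x$n_dropped))
  invisible(x)
}

#' Event-related potential: pointwise mean and standard error
#'
#' @param epochs an `eeg_epochs`.
#' @return list: `erp` (channel x time mean, uV), `se` (channel x time
#'   standard error), `times`, `n`.
#' @export
average_erp <- function(epochs) {
  n <- dim(epochs$data)[1]
  if (n < 2) stop("need at least 2 epochs for an ERP with SE")
  erp <- apply(epochs$data, c(2, 3), mean)
  se <- apply(epochs$data, c(2, 3), stats::sd) / sqrt(n)
  list(erp = erp, se = se, times = epochs$times, n = n)
}

# Hann-taper power of one segment at one frequency; power scaled so a
# sinusoid of amplitude A at f gives A^2 / 2.
hann_power_at <- function(seg, fs, f) {
  L <- length(seg)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(L) - 1) / (L - 1)))
  ph <- exp(-2i * pi * f * (seq_len(L) - 1) / fs)
  X <- sum(seg * w * ph)
  2 * Mod(X)^2 / sum(w)^2
}

#' Time-frequency power (Hanning taper, adaptive window)
#'
#' Per frequency `f`, power is estimated in a sliding window of five cycles
#' (`5/f` s) with a Hann taper and a DFT evaluated at `f`, stepped every
#' 20 ms. Power is computed per epoch and then averaged (induced + evoked).
#'
#' @param epochs an `eeg_epochs`.
#' @param freqs frequency grid (Hz), default 5--30 Hz in 1-Hz steps.
#' @param step_s time step (s), default 0.02.
#' @param n_cycles taper length in cycles, default 5.
#' @return a `tfr_array`: `power` (channel x frequency x time, uV^2),
#'   `freqs`, `times`, `n_epochs`, `baseline` (`"none"`).
#' @export
compute_tfr <- function(epochs, freqs = 5:30, step_s = 0.02, n_cycles = 5) {
  if (any(freqs < 5 - 1e-9) || any(freqs > 30 + 1e-9)) {
    stop("frequency grid outside the 5-30 Hz analysis range")
  }
  fs <- epochs$fs
  d <- dim(epochs$data)
  t0 <- epochs$times[1]
  t1 <- epochs$times[length(epochs$times)]
  # centers where the longest (lowest-frequency) window still fits
  half_max <- n_cycles / min(freqs) / 2
  centers <- seq(ceiling((t0 + half_max) / step_s) * step_s,
                 floor((t1 - half_max) / step_s) * step_s, by = step_s)
  pow <- array(0, dim = c(d[2], length(freqs), length(centers)),
               dimnames = list(dimnames(epochs$data)[[2]], NULL, NULL))
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    L <- round(n_cycles / f * fs)
    w <- 0.5 * (1 - cos(2 * pi * (seq_len(L) - 1) / (L - 1)))
    ph <- exp(-2i * pi * f * (seq_len(L) - 1) / fs)
    wph <- w * ph
    scale <- 2 / sum(w)^2
    for (ti in seq_along(centers)) {
      i0 <- round((centers[ti] - t0) * fs) + 1 - L %/% 2
      idx <- i0:(i0 + L - 1)
      seg <- epochs$data[, , idx, drop = FALSE]
      for (ch in seq_len(d[2])) {
        X <- seg[, ch, ] %*% wph
        pow[ch, fi, ti] <- mean(Mod(X)^2) * scale
      }
    }
  }
  structure(list(power = pow, freqs = freqs, times = centers,
                 n_epochs = d[1], baseline = "none"),
            class = "tfr_array")
}

#' @export
print.tfr_array <- function(x, ...) {
  cat(sprintf("<tfr_array> %d channels x %d freqs (%g-%g Hz) x %d times (%.2f..%.2f s), baseline: %s\n",
              dim(x$power)[1], dim(x$power)[2], min(x$freqs), max(x$freqs),
              dim(x$power)[3], min(x$times), max(x$times), x$baseline))
  invisible(x)
}

#' Baseline-normalize a time-frequency array
#'
#' Relative change `(P - B) / B` per channel and frequency, where `B` is the
#' mean power over the baseline window: the pre-cue window (default
#' -2.5..-2 s) in `"cue"` mode, or the entire epoch in `"trough"` mode.
#'
#' @param tfr a `tfr_array`.
#' @param mode `"cue"` or `"trough"`.
#' @param baseline_window `c(lo, hi)` in seconds, for `"cue"` mode.
#' @return the normalized `tfr_array`.
#' @export
baseline_normalize <- function(tfr, mode = c("trough", "cue"),
                               baseline_window = c(-2.5, -2)) {
  mode <- match.arg(mode)
  sel <- if (mode == "cue") {
    tfr$times >= baseline_window[1] & tfr$times <= baseline_window[2]
  } else rep(TRUE, length(tfr$times))
  if (!any(sel)) stop("baseline window outside the epoch")
  B <- apply(tfr$power[, , sel, drop = FALSE], c(1, 2), mean)
  if (any(B == 0)) stop("zero baseline power")
  tfr$power <- sweep(sweep(tfr$power, c(1, 2), B, "-"), c(1, 2), B, "/")
  tfr$baseline <- paste0("relchange-", mode)
  tfr
}
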