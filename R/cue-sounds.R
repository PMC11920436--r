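# The three 100-ms auditory cues used for reactivation: two tonal harmonic
# complexes (low / high fundamental with opposite spectral tilts) and a
# band-passed noise burst.

harmonic_complex <- function(fs, f0, n_harmonics, weights, dur_s) {
  t <- (seq_len(round(fs * dur_s)) - 1) / fs
  freqs <- f0 * seq_len(n_harmonics + 1)
  if (max(freqs) >= fs / 2) {
    stop("highest harmonic (", max(freqs), " Hz) at or above Nyquist (",
         fs / 2, " Hz)")
  }
  x <- numeric(length(t))
  for (k in seq_along(freqs)) x <- x + weights[k] * sin(2 * pi * freqs[k] * t)
  x
}

linear_ramp <- function(x, fs, ramp_s) {
  n <- length(x)
  k <- round(fs * ramp_s)
  ramp <- seq(0, 1, length.out = k)
  x[seq_len(k)] <- x[seq_len(k)] * ramp
  x[(n - k + 1):n] <- x[(n - k + 1):n] * rev(ramp)
  x
}

#' Synthesize the three auditory cue waveforms
#'
#' Sound 1: harmonic complex, fundamental 543 Hz plus 11 harmonics with
#' amplitudes evenly spaced from 1 down to 0.1. Sound 2: white noise
#' band-passed 100--1000 Hz. Sound 3: harmonic complex, fundamental 1480 Hz
#' plus 11 harmonics with amplitudes evenly spaced from 0.1 up to 1. Each cue
#' lasts 100 ms with 10-ms linear onset/offset ramps, peak-normalized to 0.9.
#'
#' @param fs_audio audio sampling rate (Hz); must exceed twice the highest
#'   harmonic (17.76 kHz).
#' @param dur_s cue duration (s).
#' @param ramp_s onset/offset ramp duration (s).
#' @param seed seed for the noise burst.
#' @return named list of numeric waveforms: `low_tone`, `noise`, `high_tone`.
#' @export
synthesize_cue_sounds <- function(fs_audio = 44100, dur_s = 0.1,
                                  ramp_s = 0.01, seed = NULL) {
  stopifnot(fs_audio > 0, dur_s > 2 * ramp_s)
  w_down <- seq(1, 0.1, length.out = 12)
  w_up <- seq(0.1, 1, length.out = 12)
  low <- harmonic_complex(fs_audio, 543, 11, w_down, dur_s)
  high <- harmonic_complex(fs_audio, 1480, 11, w_up, dur_s)
  noise <- with_seed(seed, stats::rnorm(round(fs_audio * dur_s)))
  noise <- fft_bandpass(noise, fs_audio, 100, 1000, transition = 50)
  out <- lapply(list(low_tone = low, noise = noise, high_tone = high),
                function(x) linear_ramp(0.9 * x / max(abs(x)), fs_audio, ramp_s))
  out
}
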