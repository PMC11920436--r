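# Shared signal-processing primitives used across the pipeline.

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded generators do not
#' perturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Zero-phase band-pass filter with raised-cosine transitions
#'
#' Filters in the frequency domain with a flat pass-band and raised-cosine
#' roll-offs of width `transition` Hz, so the half-amplitude (-6 dB) points sit
#' half a transition width outside each pass-band edge (e.g. pass-band
#' 0.3--2 Hz with a 0.2 Hz transition gives -6 dB at 0.2 and 2.1 Hz). The
#' response is applied symmetrically (zero phase).
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param lo,hi pass-band edges (Hz); `lo = 0` gives a low-pass, `hi = Inf` a
#'   high-pass.
#' @param transition transition width (Hz).
#' @return filtered vector, same length as `x`.
#' @export
fft_bandpass <- function(x, fs, lo, hi, transition = 0.2) {
  n <- length(x)
  stopifnot(n > 1, fs > 0, lo < hi, transition > 0)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, fs - f)  # two-sided frequency magnitude
  H <- rep(1, n)
  if (lo > 0) {
    ramp <- f <= lo & f >= lo - transition
    H[f < lo - transition] <- 0
    H[ramp] <- 0.5 * (1 - cos(pi * (f[ramp] - (lo - transition)) / transition))
  }
  if (is.finite(hi) && hi < fs / 2) {
    ramp <- f >= hi & f <= hi + transition
    H[f > hi + transition] <- 0
    H[ramp] <- 0.5 * (1 + cos(pi * (f[ramp] - hi) / transition))
  }
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / n
}

#' Analytic signal via the Hilbert transform
#'
#' One-sided spectrum construction: positive frequencies doubled, negative
#' zeroed. Non-causal (uses the whole record).
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase with the slow-oscillation convention
#'
#' Phase is 0 deg at the negative-to-positive zero crossing, 90 deg at the
#' peak, 180 deg at the positive-to-negative crossing, 270 deg at the trough.
#'
#' @param x real signal (already band-pass filtered) or a complex analytic
#'   signal.
#' @return phase in degrees, in `[0, 360)`.
#' @export
instantaneous_phase <- function(x) {
  a <- if (is.complex(x)) x else analytic_signal(x)
  (Arg(a) * 180 / pi + 90) %% 360
}

# Causal moving-average filter (mean of the current and previous k-1 samples);
# the first k-1 samples use the partial window.
moving_average <- function(x, k) {
  cs <- cumsum(x)
  n <- length(x)
  out <- numeric(n)
  if (n <= k) return(cs / seq_len(n))
  head_idx <- seq_len(k)
  out[head_idx] <- cs[head_idx] / head_idx
  idx <- (k + 1):n
  out[idx] <- (cs[idx] - cs[idx - k]) / k
  out
}

# Integer-factor decimation with an FFT anti-alias low-pass at 0.8 * new
# Nyquist (cutoff_hz overrides). Returns list(x, fs).
resample_to <- function(x, fs, fs_new, cutoff_hz = NULL) {
  if (fs == fs_new) return(list(x = x, fs = fs))
  q <- fs / fs_new
  if (abs(q - round(q)) > 1e-9) {
    stop("resampling requires an integer decimation factor (fs = ", fs,
         ", target = ", fs_new, ")")
  }
  q <- round(q)
  if (is.null(cutoff_hz)) cutoff_hz <- 0.8 * fs_new / 2
  xf <- fft_bandpass(x, fs, 0, cutoff_hz, transition = 0.2 * fs_new / 2)
  list(x = xf[seq(1, length(xf), by = q)], fs = fs_new)
}

# Circular helpers (degrees). mean direction, resultant length.
circ_mean_deg <- function(deg) {
  rad <- deg * pi / 180
  (atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi) %% 360
}

circ_resultant <- function(deg) {
  rad <- deg * pi / 180
  sqrt(mean(sin(rad))^2 + mean(cos(rad))^2)
}

# Signed smallest angular difference a - b in (-180, 180].
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# Run-length extraction: start/end indices of TRUE runs in a logical vector.
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Sign with hysteresis: -1 below -eps, +1 above +eps, previous state in
# between. Keeps small ripples near zero from splitting half-waves.
hysteresis_sign <- function(w, eps) {
  s <- integer(length(w))
  s[w > eps] <- 1L
  s[w < -eps] <- -1L
  # carry the last decided state through the dead band
  decided <- s != 0L
  if (!any(decided)) return(s)
  idx <- cumsum(decided)
  first <- which(decided)[1]
  vals <- s[decided]
  out <- ifelse(idx == 0L, vals[1], vals[pmax(idx, 1L)])
  as.integer(out)
}
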