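# Real-time slow-oscillation phase-targeted stimulation simulator.
#
# The online algorithm mirrors the two-step device logic: threshold-based
# arming on a fast moving-average trace (sex-specific trough and peak-to-peak
# criteria), then firing when the endpoint-corrected Hilbert transform (ecHT)
# phase of the raw stream crosses the target phase (90 deg peak for the up
# condition, 270 deg trough for down). Stimulation runs in alternating 3-min
# up/down intervals separated by 1-min rests, is gated to N2/N3 sleep, locks
# out until the next positive-to-negative zero crossing after each cue, and
# dynamically silences down intervals when validated down cues outnumber
# validated up cues.

#' Stimulation configuration
#'
#' Defaults follow the closed-loop device settings: 0.1--4.5 Hz analysis band,
#' 50-sample moving-average prefilter, sex-specific arming thresholds
#' (trough -41 uV / PTP 77 uV in females, -39.5 uV / 74 uV in males), 3-min
#' stimulation intervals with 1-min rests, online validation at -40 uV trough
#' and 75 uV peak-to-peak with an order-500 FIR, and a 3-h stimulation window
#' from the first cue.
#'
#' @param sex `"F"` or `"M"`; selects the arming thresholds.
#' @param ... overrides for any configuration field.
#' @return a `stim_config` list.
#' @export
stimulation_config <- function(sex = "F", ...) {
  cfg <- list(
    band = c(0.1, 4.5), ma_window = 50L,
    down_threshold_f = -41, down_threshold_m = -39.5,
    ptp_threshold_f = 77, ptp_threshold_m = 74,
    stim_interval_s = 180, rest_min_s = 60,
    online_valid_trough = -40, online_valid_ptp = 75,
    fir_order = 500L,
    target_phase_up = 90, target_phase_down = 270,
    session_limit_s = 3 * 3600,
    fs_online = 500, echt_buffer_s = 2, echt_filter_order = 2L,
    first_interval = "up",
    sex = sex
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(cfg, over)
  if (!cfg$sex %in% c("F", "M")) stop("unknown sex code: ", cfg$sex)
  stopifnot(cfg$band[1] < cfg$band[2], cfg$stim_interval_s > 0,
            cfg$rest_min_s > 0, cfg$down_threshold_f < 0,
            cfg$down_threshold_m < 0)
  structure(cfg, class = "stim_config")
}

down_threshold <- function(config) {
  if (config$sex == "F") config$down_threshold_f else config$down_threshold_m
}

ptp_threshold <- function(config) {
  if (config$sex == "F") config$ptp_threshold_f else config$ptp_threshold_m
}

# Frequency response of the causal Butterworth band-pass used inside the
# ecHT, evaluated at the n FFT bin frequencies, combined with the one-sided
# (analytic) weighting. Precomputable per window length.
echt_response <- function(n, band, fs, order = 2L) {
  bt <- signal::butter(order, band / (fs / 2), type = "pass")
  z <- exp(-1i * 2 * pi * (seq_len(n) - 1) / n)
  H <- vapply(z, function(zz) {
    sum(bt$b * zz^(0:(length(bt$b) - 1))) /
      sum(bt$a * zz^(0:(length(bt$a) - 1)))
  }, complex(1))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  # phasor picking the final sample of the inverse FFT
  e_last <- exp(1i * 2 * pi * (seq_len(n) - 1) * (n - 1) / n)
  # positive-frequency grid for the dominant-frequency phase compensation
  half <- seq(2, ceiling(n / 2))
  list(weight = H * h, e_last = e_last, n = n, bt = bt, fs = fs,
       pos_bins = half, pos_freq = (half - 1) * fs / n)
}

# Complex response of the stored causal filter at an arbitrary frequency.
filter_response_at <- function(bt, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  sum(bt$b * z^(0:(length(bt$b) - 1))) / sum(bt$a * z^(0:(length(bt$a) - 1)))
}

echt_endpoint <- function(window, resp) {
  Y <- stats::fft(window) * resp$weight
  a <- sum(Y * resp$e_last) / resp$n
  # compensate the causal filter's phase lag at the dominant frequency of the
  # (filtered) window -- the band-pass is not centered on the SO band, so its
  # phase response is non-zero there
  p <- Mod(Y[resp$pos_bins])^2
  lag <- if (sum(p) > 0) {
    f_dom <- sum(resp$pos_freq * p) / sum(p)
    Arg(filter_response_at(resp$bt, f_dom, resp$fs)) * 180 / pi
  } else 0
  list(phase_deg = (Arg(a) * 180 / pi - lag + 90) %% 360, amplitude = Mod(a))
}

#' Endpoint-corrected Hilbert transform phase at the last sample
#'
#' Causal instantaneous phase estimate: the analytic signal of the buffer is
#' band-passed in the frequency domain with the complex response of a causal
#' Butterworth filter, which suppresses the Gibbs distortion that a plain
#' windowed Hilbert transform shows at the buffer endpoint. Phase convention:
#' 0 deg at the negative-to-positive zero crossing, 90 deg at the peak,
#' 270 deg at the trough.
#'
#' @param window most recent samples (numeric, length >= 64), oldest first.
#' @param band pass-band `c(lo, hi)` in Hz.
#' @param fs sampling rate (Hz).
#' @param order causal Butterworth order (default 2).
#' @return list with `phase_deg` (degrees in `[0, 360)`) and `amplitude`.
#' @export
echt_phase <- function(window, band = c(0.1, 4.5), fs = 500, order = 2L) {
  if (length(window) < 64) stop("ecHT window must hold at least 64 samples")
  if (anyNA(window)) stop("NaN/NA in ecHT input window")
  resp <- echt_response(length(window), band, fs, order)
  echt_endpoint(window, resp)
}

#' Scan a moving-average-filtered stream for online SO candidates
#'
#' Replays the device's arming logic over a whole trace: a `down_detected`
#' event at each first sample below the sex-specific trough threshold, and --
#' for that oscillation -- an `up_detected` event at the moment the running
#' peak-to-peak amplitude (running max minus running min since the down
#' detection) reaches the sex-specific PTP threshold.
#'
#' @param x moving-average-filtered samples (uV).
#' @param fs sampling rate (Hz).
#' @param config a [stimulation_config()].
#' @return data frame with columns `type` (`down_detected` / `up_detected`),
#'   `idx` (sample) and `time_s`.
#' @export
detect_so_candidate <- function(x, fs, config = stimulation_config()) {
  thr <- down_threshold(config)
  ptp <- ptp_threshold(config)
  below <- x < thr
  crossings <- which(!below[-length(x)] & below[-1]) + 1
  if (below[1]) crossings <- c(1L, crossings)
  out <- list()
  for (k in seq_along(crossings)) {
    i0 <- crossings[k]
    i1 <- if (k < length(crossings)) crossings[k + 1] - 1 else length(x)
    out[[length(out) + 1]] <- data.frame(type = "down_detected", idx = i0)
    seg <- x[i0:i1]
    reach <- which(cummax(seg) - cummin(seg) >= ptp)
    if (length(reach)) {
      out[[length(out) + 1]] <-
        data.frame(type = "up_detected", idx = i0 + reach[1] - 1)
    }
  }
  if (!length(out)) {
    return(data.frame(type = character(0), idx = integer(0),
                      time_s = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$idx), ]
  res$time_s <- (res$idx - 1) / fs
  rownames(res) <- NULL
  res
}

#' Online cue validation against the FIR-filtered trace
#'
#' A cue is valid when it lies within a slow oscillation -- the negative
#' half-wave containing (or immediately preceding) the cue plus the following
#' positive half-wave -- whose trough reaches the validation trough criterion
#' and whose peak-to-peak amplitude reaches the PTP criterion. Cues inside the
#' filter edge-transient region are indeterminate (`NA`), which callers count
#' as invalid.
#'
#' @param cue_time_s cue onset (s).
#' @param trace delay-compensated FIR-filtered signal (0.1--4.5 Hz, uV).
#' @param fs sampling rate of `trace` (Hz).
#' @param config a [stimulation_config()].
#' @param search_s half-width of the local search window (s).
#' @return `TRUE`, `FALSE`, or `NA` (indeterminate).
#' @export
online_validate <- function(cue_time_s, trace, fs,
                            config = stimulation_config(), search_s = 2) {
  i <- round(cue_time_s * fs) + 1
  n <- length(trace)
  edge <- config$fir_order %/% 2
  if (i - search_s * fs < edge || i + search_s * fs > n - edge) return(NA)
  lo <- max(1, i - round(search_s * fs))
  hi <- min(n, i + round(search_s * fs))
  w <- trace[lo:hi]
  ci <- i - lo + 1
  # hysteresis segmentation (+/- 5 uV) so noise ripples near zero do not
  # split half-waves
  m <- local_so_measure(w, ci)
  if (is.null(m)) return(FALSE)
  m[["trough"]] <= config$online_valid_trough &&
    m[["ptp"]] >= config$online_valid_ptp
}

#' Dynamic condition balancing rule
#'
#' A down interval is silenced whenever the running count of online-validated
#' down cues exceeds the up count at decision time; up intervals always run.
#'
#' @param counters named counts, `c(up = ..., down = ...)`.
#' @param upcoming `"up"` or `"down"`.
#' @return `"run"` or `"silence"`.
#' @export
balance_conditions <- function(counters, upcoming) {
  if (upcoming == "down" && counters[["down"]] > counters[["up"]]) "silence"
  else "run"
}

# FIR validation trace: order-500 linear-phase band-pass, delay compensated.
validation_trace <- function(x, fs, config) {
  b <- signal::fir1(config$fir_order, config$band / (fs / 2), type = "pass")
  v <- signal::fftfilt(b, c(x, numeric(config$fir_order %/% 2)))
  v[-seq_len(config$fir_order %/% 2)][seq_along(x)]
}

#' Run the closed-loop stimulation simulation
#'
#' Simulates the full night: interval scheduling (alternating 3-min up/down
#' stimulation with 1-min rests, frozen while the hypnogram is outside N2/N3),
#' threshold arming on the moving-average trace, ecHT phase-targeted firing,
#' per-cue lockout until the next positive-to-negative zero crossing, online
#' validation, dynamic down-interval silencing, and a hard stop 3 h after the
#' first cue.
#'
#' @param recording an [eeg_recording] with a hypnogram.
#' @param config a [stimulation_config()].
#' @param channel detection channel label (default `"Fpz"`).
#' @param seed seed recorded in the log (reserved for stochastic tie-breaks).
#' @return a `cue_log`: list with `cues` (onset_s, condition, phase_deg,
#'   online_valid, interval_id), `intervals` (id, type, start_s, end_s spans),
#'   `counters`, `status`, `fs`, `config`, `seed`.
#' @export
run_closed_loop <- function(recording, config = stimulation_config(),
                            channel = "Fpz", seed = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (!channel %in% recording$channels) {
    stop("detection channel '", channel, "' not in recording")
  }
  rs <- resample_to(recording$signal[, channel], recording$fs, config$fs_online)
  x <- rs$x
  fs <- rs$fs
  n <- length(x)

  gate_epoch <- recording$hypnogram %in% c("N2", "N3")
  if (!any(gate_epoch)) {
    return(empty_cue_log(config, fs, seed, status = "no N2/N3 sleep in hypnogram",
                         warn = TRUE))
  }
  epoch_of <- pmin(((seq_len(n) - 1) %/% (30 * fs)) + 1, length(gate_epoch))
  gate <- gate_epoch[epoch_of]

  x_ma <- moving_average(x, config$ma_window)
  v <- validation_trace(x, fs, config)
  resp <- echt_response(round(config$echt_buffer_s * fs), config$band, fs,
                        config$echt_filter_order)
  buf_n <- resp$n

  thr <- down_threshold(config)
  ptp_thr <- ptp_threshold(config)
  stim_n <- round(config$stim_interval_s * fs)   # gated samples per interval
  rest_n <- round(config$rest_min_s * fs)

  counters <- c(up = 0, down = 0)
  cues <- list()
  intervals <- list()
  session_end <- Inf
  blocks <- logical_runs(gate)

  # schedule state: intervals consume gated samples only
  types <- if (config$first_interval == "up") c("up", "rest", "down", "rest")
           else c("down", "rest", "up", "rest")
  sched_pos <- 0L      # position in `types` cycle (0-based completed count)
  interval_id <- 0L
  remaining <- 0L
  cur_type <- NULL

  advance_interval <- function() {
    slot <- types[(sched_pos %% 4) + 1]
    sched_pos <<- sched_pos + 1L
    interval_id <<- interval_id + 1L
    if (slot == "down" && balance_conditions(counters, "down") == "silence") {
      cur_type <<- "silenced_down"
    } else cur_type <<- slot
    remaining <<- if (slot == "rest") rest_n else stim_n
  }

  # step the ecHT forward from sample i until its phase reaches `target`:
  # fires on a rising crossing, or immediately if the estimate already sits
  # within the quadrant past the target at arming (transient SOs can carry
  # the estimate past the target before the arming criterion is met)
  phase_crossing <- function(i, target, i_max) {
    prev <- NA
    first <- TRUE
    while (i <= i_max) {
      if (i < buf_n) { i <- i + 1; next }
      est <- echt_endpoint(x[(i - buf_n + 1):i], resp)
      d <- circ_diff_deg(est$phase_deg, target)
      if (first && d >= 0 && d < 90) {
        return(list(idx = i, phase = est$phase_deg))
      }
      if (!is.na(prev) && prev < 0 && d >= 0 && (d - prev) < 180) {
        return(list(idx = i, phase = est$phase_deg))
      }
      prev <- d
      first <- FALSE
      i <- i + 1
    }
    NULL
  }

  for (b in seq_len(nrow(blocks))) {
    pos <- blocks$start[b]
    b_end <- blocks$end[b]
    while (pos <= b_end) {
      if (remaining == 0L) advance_interval()
      seg_end <- min(b_end, pos + remaining - 1L)
      seg_start <- pos
      if (cur_type %in% c("up", "down") && seg_start <= session_end) {
        target <- if (cur_type == "up") config$target_phase_up
                  else config$target_phase_down
        scan <- seg_start
        while (scan <= seg_end) {
          if (scan > session_end) break
          # next down-crossing of the MA trace at/after `scan`
          seg <- x_ma[scan:seg_end]
          below <- seg < thr
          k <- if (below[1]) 1L else {
            d <- which(!below[-length(below)] & below[-1])
            if (length(d)) d[1] + 1L else NA_integer_
          }
          if (is.na(k)) break
          i_down <- scan + k - 1L
          arm <- i_down
          if (cur_type == "up") {
            # wait for the running PTP criterion before phase targeting
            seg2 <- x[i_down:seg_end]
            reach <- which(cummax(seg2) - cummin(seg2) >= ptp_thr)
            if (!length(reach)) { scan <- seg_end + 1L; next }
            arm <- i_down + reach[1] - 1L
          }
          hit <- phase_crossing(arm, target,
                                min(seg_end, arm + round(2 * fs), session_end))
          if (is.null(hit)) {
            # abandon this oscillation; resume after the signal re-arms
            scan <- min(seg_end, arm + round(2 * fs)) + 1L
            next
          }
          cue_i <- hit$idx
          cue_t <- (cue_i - 1) / fs
          valid <- online_validate(cue_t, v, fs, config)
          if (isTRUE(valid)) counters[cur_type] <- counters[cur_type] + 1
          cues[[length(cues) + 1]] <- data.frame(
            onset_s = cue_t, condition = cur_type,
            phase_deg = hit$phase, online_valid = isTRUE(valid),
            interval_id = interval_id)
          if (!is.finite(session_end)) {
            session_end <- cue_i + round(config$session_limit_s * fs)
          }
          # lockout: next positive-to-negative zero crossing of the MA trace
          after <- x_ma[cue_i:seg_end]
          zc <- which(after[-length(after)] > 0 & after[-1] <= 0)
          scan <- if (length(zc)) cue_i + zc[1] else seg_end + 1L
        }
      }
      intervals[[length(intervals) + 1]] <- data.frame(
        id = interval_id, type = cur_type,
        start_s = (seg_start - 1) / fs, end_s = seg_end / fs)
      remaining <- remaining - (seg_end - seg_start + 1L)
      pos <- seg_end + 1L
    }
    if (blocks$start[b] > session_end) break
  }

  cue_df <- if (length(cues)) do.call(rbind, cues) else
    data.frame(onset_s = numeric(0), condition = character(0),
               phase_deg = numeric(0), online_valid = logical(0),
               interval_id = integer(0))
  int_df <- if (length(intervals)) do.call(rbind, intervals) else
    data.frame(id = integer(0), type = character(0),
               start_s = numeric(0), end_s = numeric(0))
  structure(list(cues = cue_df, intervals = int_df, counters = counters,
                 status = "ok", fs = fs, config = config, seed = seed),
            class = "cue_log")
}

empty_cue_log <- function(config, fs, seed, status, warn = FALSE) {
  if (warn) warning(status)
  structure(list(
    cues = data.frame(onset_s = numeric(0), condition = character(0),
                      phase_deg = numeric(0), online_valid = logical(0),
                      interval_id = integer(0)),
    intervals = data.frame(id = integer(0), type = character(0),
                           start_s = numeric(0), end_s = numeric(0)),
    counters = c(up = 0, down = 0), status = status, fs = fs,
    config = config, seed = seed), class = "cue_log")
}

#' @export
print.cue_log <- function(x, ...) {
  cat(sprintf("<cue_log> %d cues (%d up / %d down), %d interval spans, status: %s\n",
              nrow(x$cues), sum(x$cues$condition == "up"),
              sum(x$cues$condition == "down"),
              nrow(x$intervals), x$status))
  cat(sprintf("  online-validated: up %d, down %d\n",
              x$counters[["up"]], x$counters[["down"]]))
  invisible(x)
}

#' Fraction of cues delivered at slow-oscillation spacing
#'
#' For consecutive cue pairs, the instantaneous rate `1 / gap` is classified
#' as in-band when it falls inside the analysis band (boundaries inclusive).
#'
#' @param cue_log a `cue_log` or numeric cue times (s).
#' @param band rate band in Hz, default the 0.1--4.5 Hz analysis band.
#' @param n_boot bootstrap replicates for the 95% CI.
#' @param seed bootstrap seed.
#' @return list: `fraction`, `ci` (95% percentile bootstrap), `n_gaps`.
#' @export
cue_rate_in_band <- function(cue_log, band = c(0.1, 4.5), n_boot = 1000,
                             seed = NULL) {
  times <- if (inherits(cue_log, "cue_log")) cue_log$cues$onset_s else cue_log
  if (length(times) < 2) stop("need at least 2 cues")
  rate <- 1 / diff(sort(times))
  inband <- rate >= band[1] & rate <= band[2]
  frac <- mean(inband)
  ci <- with_seed(seed, {
    bs <- replicate(n_boot, mean(sample(inband, replace = TRUE)))
    stats::quantile(bs, c(0.025, 0.975), names = FALSE)
  })
  list(fraction = frac, ci = ci, n_gaps = length(inband))
}
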