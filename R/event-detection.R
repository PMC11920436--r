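# Offline slow-oscillation and sleep-spindle detection.
#
# SO detector: 0.3-2 Hz zero-phase filter (0.2 Hz transition), negative /
# positive peak picking on half-waves, then five logical thresholds
# (half-wave durations, peak amplitudes, peak-to-peak amplitude).
# Spindle detector: sigma-band relative power, moving RMS and broadband/sigma
# moving correlation must exceed their thresholds simultaneously; runs give
# candidate events filtered to 0.3-3 s; near-simultaneous events across
# channels are merged.

#' Slow-oscillation detector parameters
#'
#' `neg_peak_range` / `pos_peak_range` bound the peak-picking stage; the
#' `amp_neg` (magnitude), `amp_pos`, duration and `ptp` entries are the
#' logical thresholds applied to candidate negative/positive half-wave pairs.
#'
#' @param ... overrides.
#' @return parameter list.
#' @export
so_detection_params <- function(...) {
  p <- list(band = c(0.3, 2), transition = 0.2,
            neg_peak_range = c(-200, -40), pos_peak_range = c(10, 150),
            neg_dur = c(0.3, 1.5), pos_dur = c(0.1, 1),
            amp_neg = c(40, 300), amp_pos = c(10, 200), ptp = c(75, 500))
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown SO parameter(s): ", paste(bad, collapse = ", "))
  utils::modifyList(p, over)
}

#' Spindle detector parameters
#'
#' @param ... overrides.
#' @return parameter list.
#' @export
spindle_detection_params <- function(...) {
  p <- list(broad_band = c(1, 30), sigma_band = c(8, 18),
            stft_window_s = 2, stft_step_s = 0.2,
            rel_power_threshold = 0.2,
            rms_window_s = 0.3, rms_step_s = 0.1, rms_sd_factor = 1.5,
            corr_threshold = 0.65,
            duration_s = c(0.3, 3), merge_window_s = 0.5)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown spindle parameter(s): ",
                        paste(bad, collapse = ", "))
  utils::modifyList(p, over)
}

#' Detect slow oscillations on one channel
#'
#' @param recording an [eeg_recording] (signal in uV, fs >= 100 Hz).
#' @param channel channel label.
#' @param params [so_detection_params()].
#' @return data frame of events sorted by trough time: kind, channel,
#'   onset_s, offset_s, trough_s, trough_uV, peak_s, peak_uV, ptp_uV,
#'   neg_dur_s, pos_dur_s, freq_hz.
#' @export
detect_slow_oscillations <- function(recording, channel = "Fpz",
                                     params = so_detection_params()) {
  if (!channel %in% recording$channels) {
    stop("channel '", channel, "' not in recording")
  }
  fs <- recording$fs
  stopifnot(fs >= 100)
  w <- fft_bandpass(recording$signal[, channel], fs,
                    params$band[1], params$band[2], params$transition)
  neg_runs <- logical_runs(w < 0)
  pos_runs <- logical_runs(w > 0)
  if (nrow(neg_runs) == 0 || nrow(pos_runs) == 0) return(empty_osc_events())

  out <- list()
  for (k in seq_len(nrow(neg_runs))) {
    n0 <- neg_runs$start[k]; n1 <- neg_runs$end[k]
    tr_rel <- which.min(w[n0:n1])
    trough <- w[n0 + tr_rel - 1]
    if (trough < params$neg_peak_range[1] || trough > params$neg_peak_range[2])
      next
    # positive half-wave immediately following (before the next negative one)
    j <- which(pos_runs$start > n1)
    if (!length(j)) next
    p0 <- pos_runs$start[j[1]]; p1 <- pos_runs$end[j[1]]
    if (k < nrow(neg_runs) && p0 > neg_runs$start[k + 1]) next
    pk_rel <- which.max(w[p0:p1])
    peak <- w[p0 + pk_rel - 1]
    if (peak < params$pos_peak_range[1] || peak > params$pos_peak_range[2])
      next
    neg_dur <- (n1 - n0 + 1) / fs
    pos_dur <- (p1 - p0 + 1) / fs
    ptp <- peak - trough
    if (neg_dur < params$neg_dur[1] || neg_dur > params$neg_dur[2]) next
    if (pos_dur < params$pos_dur[1] || pos_dur > params$pos_dur[2]) next
    if (-trough < params$amp_neg[1] || -trough > params$amp_neg[2]) next
    if (peak < params$amp_pos[1] || peak > params$amp_pos[2]) next
    if (ptp < params$ptp[1] || ptp > params$ptp[2]) next
    out[[length(out) + 1]] <- data.frame(
      kind = "SO", channel = channel,
      onset_s = (n0 - 1) / fs, offset_s = p1 / fs,
      trough_s = (n0 + tr_rel - 2) / fs, trough_uV = trough,
      peak_s = (p0 + pk_rel - 2) / fs, peak_uV = peak, ptp_uV = ptp,
      neg_dur_s = neg_dur, pos_dur_s = pos_dur,
      freq_hz = 1 / (neg_dur + pos_dur))
  }
  if (!length(out)) return(empty_osc_events())
  res <- do.call(rbind, out)
  res[order(res$trough_s), ]
}

empty_osc_events <- function() {
  data.frame(kind = character(0), channel = character(0),
             onset_s = numeric(0), offset_s = numeric(0),
             trough_s = numeric(0), trough_uV = numeric(0),
             peak_s = numeric(0), peak_uV = numeric(0), ptp_uV = numeric(0),
             neg_dur_s = numeric(0), pos_dur_s = numeric(0),
             freq_hz = numeric(0))
}

#' Audit detected slow oscillations against the logical thresholds
#'
#' Independent post-hoc re-check of every returned event against the
#' parameter bounds (durations, amplitudes, PTP).
#'
#' @param events output of [detect_slow_oscillations()].
#' @param params [so_detection_params()].
#' @return logical vector, one entry per event.
#' @export
audit_so_events <- function(events, params = so_detection_params()) {
  with(events,
       neg_dur_s >= params$neg_dur[1] & neg_dur_s <= params$neg_dur[2] &
       pos_dur_s >= params$pos_dur[1] & pos_dur_s <= params$pos_dur[2] &
       -trough_uV >= params$amp_neg[1] & -trough_uV <= params$amp_neg[2] &
       peak_uV >= params$amp_pos[1] & peak_uV <= params$amp_pos[2] &
       ptp_uV >= params$ptp[1] & ptp_uV <= params$ptp[2])
}

# Sliding-window statistics over frame centers via cumulative sums.
sliding_frames <- function(n, win_n, step_n) {
  starts <- seq(1, n - win_n + 1, by = step_n)
  list(starts = starts, centers = starts + win_n %/% 2)
}

#' Detect sleep spindles
#'
#' Three simultaneous criteria on per-channel feature tracks: relative sigma
#' (8--18 Hz) power above `rel_power_threshold` (STFT, 2-s windows, 200-ms
#' step), moving sigma RMS (300-ms window, 100-ms step) above its NREM
#' mean + 1.5 SD, and the moving broadband/sigma Pearson correlation above
#' `corr_threshold`. Candidate runs outside 0.3--3 s are discarded.
#'
#' @param recording an [eeg_recording].
#' @param params [spindle_detection_params()].
#' @param channels channels to process (default all).
#' @return data frame of events: kind, channel, onset_s, offset_s,
#'   duration_s, freq_hz, amp_uV.
#' @export
detect_spindles <- function(recording, params = spindle_detection_params(),
                            channels = recording$channels) {
  fs <- recording$fs
  n <- nrow(recording$signal)
  if (n < params$stft_window_s * fs) stop("recording shorter than STFT window")
  nrem_epoch <- recording$hypnogram %in% c("N2", "N3")
  out <- list()
  for (ch in channels) {
    x <- recording$signal[, ch]
    broad <- fft_bandpass(x, fs, params$broad_band[1], params$broad_band[2],
                          transition = 0.5)
    sigma <- fft_bandpass(x, fs, params$sigma_band[1], params$sigma_band[2],
                          transition = 1)

    # --- relative sigma power from an STFT of the broadband signal
    win_n <- round(params$stft_window_s * fs)
    step_n <- round(params$stft_step_s * fs)
    fr <- sliding_frames(n, win_n, step_n)
    taper <- 0.5 * (1 - cos(2 * pi * (seq_len(win_n) - 1) / (win_n - 1)))
    freqs <- (seq_len(win_n) - 1) * fs / win_n
    band_tot <- freqs >= params$broad_band[1] & freqs <= params$broad_band[2]
    band_sig <- freqs >= params$sigma_band[1] & freqs <= params$sigma_band[2]
    rel <- vapply(fr$starts, function(s) {
      P <- Mod(stats::fft(broad[s:(s + win_n - 1)] * taper))^2
      sum(P[band_sig]) / sum(P[band_tot])
    }, 0)
    rel_track <- stats::approx(fr$centers, rel, xout = seq_len(n),
                               rule = 2)$y

    # --- moving RMS of the sigma-filtered signal (vectorized via cumsums)
    rwin <- round(params$rms_window_s * fs)
    rstep <- round(params$rms_step_s * fs)
    rf <- sliding_frames(n, rwin, rstep)
    cs2 <- cumsum(c(0, sigma^2))
    rms <- sqrt((cs2[rf$starts + rwin] - cs2[rf$starts]) / rwin)
    # NREM baseline statistics over the whole recording
    frame_epoch <- pmin((rf$centers - 1) %/% (30 * fs) + 1, length(nrem_epoch))
    base <- if (any(nrem_epoch[frame_epoch])) rms[nrem_epoch[frame_epoch]] else rms
    rms_thr <- mean(base) + params$rms_sd_factor * stats::sd(base)
    rms_track <- stats::approx(rf$centers, rms, xout = seq_len(n), rule = 2)$y

    # --- moving broadband/sigma correlation on the same frame grid
    cb <- cumsum(c(0, broad)); cs <- cumsum(c(0, sigma))
    cbb <- cumsum(c(0, broad^2)); cbs <- cumsum(c(0, broad * sigma))
    s0 <- rf$starts; s1 <- rf$starts + rwin
    sum_b <- cb[s1] - cb[s0]; sum_s <- cs[s1] - cs[s0]
    sum_bb <- cbb[s1] - cbb[s0]; sum_ss <- cs2[s1] - cs2[s0]
    sum_bs <- cbs[s1] - cbs[s0]
    num <- sum_bs - sum_b * sum_s / rwin
    den <- sqrt(pmax(sum_bb - sum_b^2 / rwin, 0) *
                pmax(sum_ss - sum_s^2 / rwin, 0))
    mcorr <- ifelse(den > 0, num / den, 0)
    corr_track <- stats::approx(rf$centers, mcorr, xout = seq_len(n),
                                rule = 2)$y

    mask <- rel_track > params$rel_power_threshold &
      rms_track > rms_thr & corr_track > params$corr_threshold
    runs <- logical_runs(mask)
    if (nrow(runs) == 0) next
    # refine boundaries with the instantaneous sigma envelope at the
    # equivalent amplitude threshold (RMS of a steady sinusoid = env/sqrt(2)),
    # removing the smearing of the 300-ms RMS window
    env <- Mod(analytic_signal(sigma))
    env_runs <- logical_runs(env > sqrt(2) * rms_thr)
    refined <- lapply(seq_len(nrow(runs)), function(k) {
      seg_idx <- runs$start[k]:runs$end[k]
      pk <- seg_idx[which.max(env[seg_idx])]
      hit <- which(env_runs$start <= pk & env_runs$end >= pk)
      if (!length(hit)) return(NULL)
      data.frame(start = env_runs$start[hit[1]], end = env_runs$end[hit[1]])
    })
    runs <- unique(do.call(rbind, refined))
    if (is.null(runs) || nrow(runs) == 0) next
    dur <- (runs$end - runs$start + 1) / fs
    keep <- dur >= params$duration_s[1] & dur <= params$duration_s[2]
    runs <- runs[keep, , drop = FALSE]
    for (k in seq_len(nrow(runs))) {
      seg <- sigma[runs$start[k]:runs$end[k]]
      zc <- sum(diff(sign(seg)) != 0)
      out[[length(out) + 1]] <- data.frame(
        kind = "spindle", channel = ch,
        onset_s = (runs$start[k] - 1) / fs, offset_s = runs$end[k] / fs,
        duration_s = length(seg) / fs,
        freq_hz = zc / 2 / (length(seg) / fs),
        amp_uV = max(seg) - min(seg))
    }
  }
  if (!length(out)) {
    return(data.frame(kind = character(0), channel = character(0),
                      onset_s = numeric(0), offset_s = numeric(0),
                      duration_s = numeric(0), freq_hz = numeric(0),
                      amp_uV = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$onset_s), ]
}

#' Merge near-simultaneous events across channels
#'
#' Events whose onsets fall within the merge window of each other (transitive
#' closure across channels) are assumed to reflect the same physiological
#' event and are collapsed to one event spanning the earliest onset to the
#' latest offset.
#'
#' @param events event data frame sorted by `onset_s`.
#' @param merge_window_s merge window (s), default 0.5.
#' @return merged event data frame; `channel` lists the contributing channels
#'   and `n_channels` counts them.
#' @export
merge_cross_channel <- function(events, merge_window_s = 0.5) {
  if (nrow(events) < 2) return(events)
  events <- events[order(events$onset_s), ]
  grp <- cumsum(c(1, diff(events$onset_s) > merge_window_s))
  merged <- lapply(split(seq_len(nrow(events)), grp), function(idx) {
    e <- events[idx, ]
    rep_row <- e[which.max(if ("amp_uV" %in% names(e)) e$amp_uV else
      rep(1, nrow(e))), ]
    rep_row$onset_s <- min(e$onset_s)
    rep_row$offset_s <- max(e$offset_s)
    if ("duration_s" %in% names(rep_row)) {
      rep_row$duration_s <- rep_row$offset_s - rep_row$onset_s
    }
    rep_row$channel <- paste(sort(unique(e$channel)), collapse = "+")
    rep_row$n_channels <- length(unique(e$channel))
    rep_row
  })
  res <- do.call(rbind, merged)
  rownames(res) <- NULL
  res
}

#' Per-condition event metrics over stimulation intervals
#'
#' Assigns each event (trough time for SOs, onset for spindles) to the
#' interval covering it and computes, per condition, the event density
#' (events/min), mean amplitude and mean frequency. Condition-level
#' statistics across subjects are obtained by passing a subject x condition
#' metric matrix to [rm_anova()].
#'
#' @param events detected events.
#' @param intervals data frame with `condition` (`up`/`down`/`not`),
#'   `start_s`, `end_s`.
#' @return data frame, one row per condition: condition, minutes, n_events,
#'   density_per_min, mean_amp_uV, mean_freq_hz.
#' @export
event_metrics_by_interval <- function(events, intervals) {
  stopifnot(all(c("condition", "start_s", "end_s") %in% names(intervals)))
  dur_min <- tapply(intervals$end_s - intervals$start_s,
                    intervals$condition, sum) / 60
  if (any(dur_min <= 0)) stop("zero-duration condition")
  anchor <- if (all(c("trough_s") %in% names(events)) &&
                nrow(events) && any(events$kind == "SO")) {
    ifelse(events$kind == "SO", events$trough_s, events$onset_s)
  } else events$onset_s
  conds <- names(dur_min)
  rows <- lapply(conds, function(cc) {
    iv <- intervals[intervals$condition == cc, , drop = FALSE]
    inside <- rep(FALSE, length(anchor))
    for (k in seq_len(nrow(iv))) {
      inside <- inside | (anchor >= iv$start_s[k] & anchor < iv$end_s[k])
    }
    e <- events[inside, , drop = FALSE]
    amp <- if ("amp_uV" %in% names(e) && nrow(e)) mean(e$amp_uV, na.rm = TRUE)
           else if ("ptp_uV" %in% names(e) && nrow(e)) mean(e$ptp_uV)
           else NA_real_
    data.frame(condition = cc, minutes = dur_min[[cc]], n_events = nrow(e),
               density_per_min = nrow(e) / dur_min[[cc]],
               mean_amp_uV = if (nrow(e)) amp else NA_real_,
               mean_freq_hz = if (nrow(e) && "freq_hz" %in% names(e))
                 mean(e$freq_hz) else NA_real_)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Map closed-loop interval spans to analysis conditions
#'
#' Stimulation spans keep their condition; rest and silenced-down spans form
#' the `not` (not-stimulated) condition.
#'
#' @param cue_log a `cue_log`.
#' @return data frame with `condition`, `start_s`, `end_s`.
#' @export
condition_intervals <- function(cue_log) {
  iv <- cue_log$intervals
  cond <- ifelse(iv$type %in% c("up", "down"), iv$type, "not")
  data.frame(condition = cond, start_s = iv$start_s, end_s = iv$end_s)
}
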