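# Post-hoc scoring of delivered cues: true-positive classification against
# sex-specific SO criteria, delivery-phase measurement from the non-causal
# analytic signal, circular statistics, and sham-cue construction on
# not-stimulated SOs.

# Zero-phase 0.1-4.5 Hz reference trace used for all offline phase work.
offline_phase_trace <- function(recording, channel, band = c(0.1, 4.5)) {
  x <- recording$signal[, channel]
  xf <- fft_bandpass(x, recording$fs, band[1], band[2], transition = 0.1)
  list(filtered = xf, phase = instantaneous_phase(xf), fs = recording$fs)
}

# Trough/PTP of the oscillation containing sample ci of filtered trace w.
# Half-waves come from a hysteresis segmentation (+/- eps around zero, so
# noise ripples do not fragment them); each negative half-wave plus its
# adjacent positive half-waves forms an oscillation span. Among the spans
# containing ci, the one with the deepest trough wins (a cue at the peak lies
# both in its SO's span and in the span of the shallow rebound that follows).
# Returns c(trough, ptp) or NULL when ci lies in no span.
local_so_measure <- function(w, ci, eps = 5) {
  sgn <- hysteresis_sign(w, eps)
  runs <- logical_runs(sgn < 0)
  if (nrow(runs) == 0) return(NULL)
  pos_runs <- logical_runs(sgn > 0)
  best <- NULL
  for (k in seq_len(nrow(runs))) {
    r <- runs[k, ]
    after <- which(pos_runs$start == r$end + 1)
    before <- which(pos_runs$end == r$start - 1)
    span_lo <- if (length(before)) pos_runs$start[before] else r$start
    span_hi <- if (length(after)) pos_runs$end[after] else r$end
    if (ci < span_lo || ci > span_hi) next
    trough <- min(w[r$start:r$end])
    if (is.null(best) || trough < best[["trough"]]) {
      peak <- max(0, w[span_lo:span_hi])
      best <- c(trough = trough, ptp = peak - trough)
    }
  }
  best
}

#' Offline classification of cue accuracy
#'
#' For every delivered cue, measures the delivery phase on the non-causal
#' 0.1--4.5 Hz analytic signal and decides (a) whether the cue fell within a
#' true slow oscillation (sex-specific trough and peak-to-peak criteria:
#' -41 uV / 77 uV in females, -39.5 uV / 74 uV in males) and (b) whether the
#' phase fell in the 180-degree window around the condition's target (up:
#' `[0, 180]`; down: `[180, 360)`). A cue is accurate when both hold.
#'
#' @param cues cue data frame (`onset_s`, `condition`) or a `cue_log`.
#' @param recording the full-night [eeg_recording].
#' @param sex `"F"` or `"M"`.
#' @param channel detection channel.
#' @param search_s half-width (s) of the local SO search window.
#' @return list: `records` (per-cue data frame: onset_s, condition, phase_deg,
#'   true_so, accurate, trough_uV, ptp_uV), `accuracy_pct` overall, and
#'   `accuracy_by_condition`.
#' @export
classify_cue_accuracy <- function(cues, recording, sex = "F",
                                  channel = "Fpz", search_s = 2) {
  if (inherits(cues, "cue_log")) cues <- cues$cues
  tr <- offline_phase_trace(recording, channel)
  n <- length(tr$filtered)
  trough_crit <- if (sex == "F") -41 else -39.5
  ptp_crit <- if (sex == "F") 77 else 74
  if (!sex %in% c("F", "M")) stop("unknown sex code: ", sex)

  rec <- lapply(seq_len(nrow(cues)), function(k) {
    i <- round(cues$onset_s[k] * tr$fs) + 1
    if (i < 1 || i > n) stop("cue outside recording bounds at ",
                             cues$onset_s[k], " s")
    lo <- max(1, i - round(search_s * tr$fs))
    hi <- min(n, i + round(search_s * tr$fs))
    m <- local_so_measure(tr$filtered[lo:hi], i - lo + 1)
    phase <- tr$phase[i]
    true_so <- !is.null(m) && m[["trough"]] <= trough_crit &&
      m[["ptp"]] >= ptp_crit
    in_window <- if (cues$condition[k] == "up") {
      phase >= 0 && phase <= 180
    } else phase >= 180 && phase < 360
    data.frame(onset_s = cues$onset_s[k], condition = cues$condition[k],
               phase_deg = phase, true_so = true_so,
               accurate = true_so && in_window,
               trough_uV = if (is.null(m)) NA else m[["trough"]],
               ptp_uV = if (is.null(m)) NA else m[["ptp"]])
  })
  records <- do.call(rbind, rec)
  by_cond <- tapply(records$accurate, records$condition, function(z) 100 * mean(z))
  list(records = records,
       accuracy_pct = 100 * mean(records$accurate),
       accuracy_by_condition = by_cond)
}

#' Circular summary of stimulation phases
#'
#' Mean direction, resultant vector length, and a large-sample 95% confidence
#' interval for the mean direction (circular standard error). With antipodal
#' or near-uniform samples (resultant length ~ 0) the mean direction is
#' undefined and flagged.
#'
#' @param phases_deg phases in degrees.
#' @return list: `mean_deg`, `resultant_length`, `ci_deg` (`c(lo, hi)` or
#'   `NA`), `n`, `defined` (logical).
#' @export
circular_summary <- function(phases_deg) {
  if (!length(phases_deg)) stop("empty phase vector")
  n <- length(phases_deg)
  R <- circ_resultant(phases_deg)
  mu <- circ_mean_deg(phases_deg)
  if (R < 1e-8) {
    return(list(mean_deg = NA_real_, resultant_length = R, ci_deg = c(NA, NA),
                n = n, defined = FALSE))
  }
  # Fisher (1993) large-sample CI via the circular dispersion
  rad <- phases_deg * pi / 180
  mu_rad <- mu * pi / 180
  m2 <- mean(cos(2 * (rad - mu_rad)))
  disp <- (1 - m2) / (2 * R^2)
  se <- sqrt(disp / n)
  half <- if (1.959964 * se >= 1) 180 else asin(1.959964 * se) * 180 / pi
  list(mean_deg = mu, resultant_length = R,
       ci_deg = c((mu - half) %% 360, (mu + half) %% 360),
       n = n, defined = TRUE)
}

#' Assign sham cues to not-stimulated slow oscillations
#'
#' Every not-stimulated SO receives one up-sham and one down-sham time: a
#' phase is drawn (with replacement, seeded) from the corresponding empirical
#' true-positive phase distribution and converted to a time sample on that SO
#' by interpolating the SO's own analytic phase.
#'
#' @param not_stim_sos data frame of SO events with `onset_s`/`offset_s` (as
#'   returned by [detect_slow_oscillations()]).
#' @param up_phases_deg,down_phases_deg empirical true-positive delivery
#'   phases per condition (degrees).
#' @param recording the [eeg_recording] (for the analytic phase).
#' @param channel detection channel.
#' @param seed sampling seed.
#' @return data frame: `so_trough_s`, `up_sham_s`, `down_sham_s`,
#'   `up_phase_deg`, `down_phase_deg` -- one row per not-stimulated SO.
#' @export
assign_sham_cues <- function(not_stim_sos, up_phases_deg, down_phases_deg,
                             recording, channel = "Fpz", seed = NULL) {
  if (!length(up_phases_deg) || !length(down_phases_deg)) {
    stop("need at least one true-positive phase per condition")
  }
  tr <- offline_phase_trace(recording, channel)
  n <- length(tr$phase)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(not_stim_sos)), function(k) {
      i0 <- max(1, round(not_stim_sos$onset_s[k] * tr$fs) + 1)
      i1 <- min(n, round(not_stim_sos$offset_s[k] * tr$fs) + 1)
      ph <- tr$phase[i0:i1]
      up_target <- up_phases_deg[sample.int(length(up_phases_deg), 1)]
      down_target <- down_phases_deg[sample.int(length(down_phases_deg), 1)]
      data.frame(
        so_trough_s = if ("trough_s" %in% names(not_stim_sos))
          not_stim_sos$trough_s[k] else NA_real_,
        up_sham_s = phase_to_time(ph, up_target, i0, tr$fs),
        down_sham_s = phase_to_time(ph, down_target, i0, tr$fs),
        up_phase_deg = up_target, down_phase_deg = down_target)
    })
    do.call(rbind, rows)
  })
}

# First time within the span where the (unwrapped) phase crosses the target,
# linearly interpolated between samples.
phase_to_time <- function(phase_deg, target, i0, fs) {
  d <- circ_diff_deg(phase_deg, target)
  cross <- which(d[-length(d)] < 0 & d[-1] >= 0 &
                   (d[-1] - d[-length(d)]) < 180)
  if (!length(cross)) {
    k <- which.min(abs(d))
    return((i0 + k - 2) / fs)
  }
  k <- cross[1]
  frac <- -d[k] / (d[k + 1] - d[k])
  (i0 + k - 2 + frac) / fs
}
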