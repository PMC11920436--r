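# Synthetic SRTT behavior with planted per-condition overnight gains, an
# exponential learning curve, within-block response-time noise and a known
# error rate, so that the consolidation pipeline can be validated against
# ground truth.

#' Parameters for the behavioral simulator
#'
#' Planted overnight (offline) gains are expressed in percent response-time
#' improvement. Between-subject variability splits into a component shared
#' across conditions (`gain_subject_sd`) and a condition-specific component
#' (`gain_cell_sd`); with both equal the implied repeated-measures
#' correlation is 0.5.
#'
#' @param n_subjects number of simulated participants.
#' @param gains named planted mean gains (%), conditions up/down/not.
#' @param gain_subject_sd SD (%) of the subject-level gain shared across
#'   conditions.
#' @param gain_cell_sd SD (%) of the condition-specific gain component.
#' @param rt_initial_ms,rt_asymptote_ms,learning_rate exponential learning
#'   curve of the block-mean RT over pre-night practice blocks.
#' @param rt_noise_sd_ms within-block trial RT noise SD (ms).
#' @param random_rt_ms block-mean RT of the pseudo-random task.
#' @param error_rate probability of an incorrect key press.
#' @param seed simulation seed.
#' @return parameter list.
#' @export
behavior_sim_params <- function(n_subjects = 28,
                                gains = c(up = 8, down = 2, not = 7),
                                gain_subject_sd = 4.8, gain_cell_sd = 4.8,
                                rt_initial_ms = 420, rt_asymptote_ms = 280,
                                learning_rate = 0.12, rt_noise_sd_ms = 40,
                                random_rt_ms = 430, error_rate = 0.05,
                                seed = NULL) {
  stopifnot(error_rate >= 0, error_rate <= 1, gain_subject_sd >= 0,
            gain_cell_sd >= 0, rt_noise_sd_ms >= 0, n_subjects >= 1)
  as.list(environment())
}

#' Generate a synthetic SRTT trial table
#'
#' Block-mean response times follow an exponential learning curve over the
#' pre-night session; the three pre-test blocks sit at the end-of-training
#' level; the first post-night blocks are scaled down by each subject's
#' planted condition gain, so that the offline-change estimator recovers the
#' planted means. Trial RTs add Gaussian within-block noise (truncated at
#' 50 ms); presses are incorrect with probability `error_rate`.
#'
#' @param schedule a [build_session_schedule()] (`sessions` may restrict it).
#' @param params a [behavior_sim_params()] list.
#' @param sessions sessions to generate (default all in the schedule).
#' @return list: `trials` (per-keypress data frame: subject, session, block,
#'   condition, press, key_expected, key_pressed, rt_ms, correct) and
#'   `truth` (per subject x condition planted gain %).
#' @export
generate_behavior <- function(schedule, params = behavior_sim_params(),
                              sessions = unique(schedule$blocks$session)) {
  stopifnot(inherits(schedule, "session_schedule"))
  blocks <- schedule$blocks[schedule$blocks$session %in% sessions, ]
  conds <- c("up", "down", "not")
  with_seed(params$seed, {
    truth <- list()
    all_trials <- vector("list", params$n_subjects)
    for (s in seq_len(params$n_subjects)) {
      g_subj <- stats::rnorm(1, 0, params$gain_subject_sd)
      g <- params$gains[conds] + g_subj +
        stats::rnorm(3, 0, params$gain_cell_sd)
      names(g) <- conds
      truth[[s]] <- data.frame(subject = s, condition = conds,
                               planted_gain_pct = unname(g))

      # practice index of each sequential block within its condition
      b <- blocks
      b$mean_rt <- NA_real_
      for (cc in conds) {
        sel_tr <- b$session == "pre_training" & b$condition == cc
        idx <- seq_len(sum(sel_tr))
        curve <- params$rt_asymptote_ms +
          (params$rt_initial_ms - params$rt_asymptote_ms) *
          exp(-params$learning_rate * (idx - 1))
        b$mean_rt[sel_tr] <- curve
        end_level <- if (length(curve)) curve[length(curve)] else
          params$rt_asymptote_ms +
          (params$rt_initial_ms - params$rt_asymptote_ms) *
          exp(-params$learning_rate * 20)
        b$mean_rt[b$session == "pre_test" & b$condition == cc] <- end_level
        sel_po <- b$session == "post_training" & b$condition == cc
        post_start <- end_level * (1 - g[cc] / 100)
        npo <- sum(sel_po)
        if (npo) {
          # plateau over the first three blocks (the consolidation read-out),
          # then practice-driven improvement resumes
          idx_po <- pmax(0, seq_len(npo) - 3)
          b$mean_rt[sel_po] <- post_start *
            exp(-0.2 * params$learning_rate * idx_po)
        }
      }
      b$mean_rt[b$condition == "random"] <- params$random_rt_ms

      n_press <- b$n_presses
      rows <- data.frame(
        subject = s,
        session = rep(b$session, n_press),
        block = rep(b$block, n_press),
        condition = rep(b$condition, n_press),
        press = sequence(n_press),
        mean_rt = rep(b$mean_rt, n_press))
      seq_name <- rep(b$sequence, n_press)
      rows$key_expected <- NA_integer_
      for (sq in names(schedule$sequences)) {
        sel <- seq_name == sq
        if (!any(sel)) next
        el <- schedule$sequences[[sq]]
        rows$key_expected[sel] <- el[(rows$press[sel] - 1) %% length(el) + 1]
      }
      rows$rt_ms <- pmax(50, stats::rnorm(nrow(rows), rows$mean_rt,
                                          params$rt_noise_sd_ms))
      rows$correct <- stats::runif(nrow(rows)) >= params$error_rate
      rows$key_pressed <- rows$key_expected
      wrong <- which(!rows$correct & !is.na(rows$key_expected))
      if (length(wrong)) {
        rows$key_pressed[wrong] <- (rows$key_expected[wrong] +
                                      sample(7, length(wrong),
                                             replace = TRUE) - 1) %% 8 + 1
      }
      rows$mean_rt <- NULL
      all_trials[[s]] <- rows
    }
    list(trials = do.call(rbind, all_trials),
         truth = do.call(rbind, truth))
  })
}
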