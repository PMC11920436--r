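# Serial reaction time task (SRTT) schedule construction, trial scoring with
# Tukey outlier filtering, consolidation metrics (offline change %, TMR
# index) and the repeated-measures statistics used throughout the pipeline.

SRTT_SEQUENCES <- list(A = c(4, 7, 2, 8, 3),
                       B = c(1, 6, 3, 5, 2),
                       C = c(7, 3, 8, 4, 6))

#' Build the full SRTT session schedule
#'
#' Pre-night training (63 sequential blocks, 21 per sequence), pre-night test
#' (9 blocks, 3 per sequence), post-night training (63 blocks), plus 4-block
#' pseudo-random sessions before and after the night. Sequential blocks hold
#' 20 key presses (4 repetitions of a 5-element sequence); random blocks hold
#' 60 presses (12 patterns of 5 keys drawn from 8). The sequence practice
#' order and the sequence-to-condition and condition-to-sound assignments are
#' seeded bijections, fixed within subject.
#'
#' @param seed schedule seed.
#' @return a `session_schedule`: list with `blocks` (session, block,
#'   sequence, condition, n_presses), `sequences`, `condition_map`,
#'   `sound_map`, `random_patterns`, `rest_s` (10).
#' @export
build_session_schedule <- function(seed = NULL) {
  with_seed(seed, {
    seq_order <- sample(names(SRTT_SEQUENCES))
    condition_map <- stats::setNames(sample(c("up", "down", "not")),
                                     names(SRTT_SEQUENCES))
    sound_map <- stats::setNames(sample(c("low_tone", "noise", "high_tone")),
                                 c("up", "down", "not"))
    random_patterns <- lapply(seq_len(12), function(i) sample(8, 5))

    seq_session <- function(name, cycles) {
      sq <- rep(seq_order, cycles)
      data.frame(session = name, block = seq_along(sq), sequence = sq,
                 condition = condition_map[sq], n_presses = 20L)
    }
    rand_session <- function(name, n_blocks) {
      data.frame(session = name, block = seq_len(n_blocks),
                 sequence = "random", condition = "random", n_presses = 60L)
    }
    blocks <- rbind(rand_session("random_pre", 4),
                    seq_session("pre_training", 21),
                    seq_session("pre_test", 3),
                    seq_session("post_training", 21),
                    rand_session("random_post", 4))
    rownames(blocks) <- NULL
    structure(list(blocks = blocks, sequences = SRTT_SEQUENCES,
                   condition_map = condition_map, sound_map = sound_map,
                   random_patterns = random_patterns, rest_s = 10),
              class = "session_schedule")
  })
}

#' @export
print.session_schedule <- function(x, ...) {
  tab <- table(x$blocks$session)
  cat("<session_schedule>\n")
  for (s in names(tab)) cat(sprintf("  %-13s %3d blocks\n", s, tab[[s]]))
  cat("  condition map:",
      paste(names(x$condition_map), x$condition_map, sep = "->",
            collapse = ", "), "\n")
  invisible(x)
}

#' Score an SRTT trial table
#'
#' Flags outliers among correct trials with Tukey fences
#' (`Q1 - 1.5 IQR`, `Q3 + 1.5 IQR`, computed per subject x session x
#' condition), then summarizes each block by the median response time over
#' surviving correct trials and the accuracy (% correct).
#'
#' @param trials data frame with columns subject, session, block, condition,
#'   rt_ms, correct.
#' @param k Tukey fence multiplier (default 1.5).
#' @return list: `blocks` (per-block median RT, accuracy, n kept),
#'   `trials` (input plus `outlier` flag), `discarded_pct` (inaccurate +
#'   outlier trials).
#' @export
score_trials <- function(trials, k = 1.5) {
  stopifnot(all(c("subject", "session", "block", "condition", "rt_ms",
                  "correct") %in% names(trials)),
            all(trials$rt_ms > 0))
  trials$outlier <- FALSE
  grp <- interaction(trials$subject, trials$session, trials$condition,
                     drop = TRUE)
  correct_idx <- which(trials$correct)
  for (sel in split(correct_idx, grp[correct_idx])) {
    if (length(sel) < 4) next
    q <- stats::quantile(trials$rt_ms[sel], c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    trials$outlier[sel] <- trials$rt_ms[sel] < q[1] - k * iqr |
      trials$rt_ms[sel] > q[2] + k * iqr
  }
  bgrp <- interaction(trials$subject, trials$session, trials$block,
                      drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(seq_len(nrow(trials)), bgrp), function(idx) {
    keep <- idx[trials$correct[idx] & !trials$outlier[idx]]
    if (!length(keep)) {
      stop("block with zero surviving trials: subject ", trials$subject[idx[1]],
           ", session ", trials$session[idx[1]], ", block ",
           trials$block[idx[1]])
    }
    data.frame(subject = trials$subject[idx[1]],
               session = trials$session[idx[1]],
               block = trials$block[idx[1]],
               condition = trials$condition[idx[1]],
               median_rt = stats::median(trials$rt_ms[keep]),
               accuracy_pct = 100 * mean(trials$correct[idx]),
               n_kept = length(keep))
  })
  blocks <- do.call(rbind, rows)
  rownames(blocks) <- NULL
  list(blocks = blocks, trials = trials,
       discarded_pct = 100 * mean(!trials$correct | trials$outlier))
}

#' Offline change in performance speed
#'
#' `(mean(pre) - mean(post)) / mean(pre) * 100`: a response-time decrease
#' across the night gives a positive value (performance improved).
#'
#' @param pre_rt median RTs of the 3 pre-night test blocks (ms).
#' @param post_rt median RTs of the first 3 post-night blocks (ms).
#' @return offline change in percent.
#' @export
offline_change <- function(pre_rt, post_rt) {
  if (length(pre_rt) < 1 || length(post_rt) < 1) stop("missing blocks")
  100 * (mean(pre_rt) - mean(post_rt)) / mean(pre_rt)
}

#' Per-subject, per-condition offline changes from scored blocks
#'
#' Uses the 3 pre-test block medians and the first 3 post-training blocks of
#' each condition.
#'
#' @param blocks the `blocks` table from [score_trials()].
#' @return data frame: subject, condition, offline_change_pct.
#' @export
consolidation_table <- function(blocks) {
  subs <- unique(blocks$subject)
  conds <- intersect(c("up", "down", "not"), unique(blocks$condition))
  rows <- list()
  for (s in subs) for (cc in conds) {
    pre <- blocks$median_rt[blocks$subject == s & blocks$session == "pre_test" &
                              blocks$condition == cc]
    post_sel <- blocks$subject == s & blocks$session == "post_training" &
      blocks$condition == cc
    post <- blocks$median_rt[post_sel][order(blocks$block[post_sel])][1:3]
    if (length(pre) < 3 || sum(!is.na(post)) < 3) {
      stop("missing pre-test or post-training blocks for subject ", s,
           ", condition ", cc)
    }
    rows[[length(rows) + 1]] <- data.frame(
      subject = s, condition = cc,
      offline_change_pct = offline_change(pre, post))
  }
  do.call(rbind, rows)
}

#' TMR indices from per-condition offline changes
#'
#' `index_up = change_up - change_not`; `index_down = change_down -
#' change_not`.
#'
#' @param changes data frame from [consolidation_table()].
#' @return data frame: subject, tmr_index_up, tmr_index_down.
#' @export
tmr_index <- function(changes) {
  wide <- change_matrix(changes)
  data.frame(subject = rownames(wide),
             tmr_index_up = wide[, "up"] - wide[, "not"],
             tmr_index_down = wide[, "down"] - wide[, "not"],
             row.names = NULL)
}

change_matrix <- function(changes) {
  subs <- unique(changes$subject)
  conds <- intersect(c("up", "down", "not"), unique(changes$condition))
  m <- matrix(NA_real_, length(subs), length(conds),
              dimnames = list(as.character(subs), conds))
  for (i in seq_len(nrow(changes))) {
    m[as.character(changes$subject[i]), changes$condition[i]] <-
      changes$offline_change_pct[i]
  }
  if (anyNA(m)) stop("missing cells in subject x condition table")
  m
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' F statistic via `stats::aov` with an `Error(subject/condition)` stratum;
#' Greenhouse-Geisser epsilon from the double-centered sample covariance
#' matrix, applied to the degrees of freedom for the sphericity-corrected p;
#' partial eta-squared effect size; all pairwise paired t tests with
#' Benjamini-Hochberg FDR correction and paired Cohen's d.
#'
#' @param values numeric subject x condition matrix, or a long data frame
#'   with columns subject, condition and a value column.
#' @param value_col value column name for long input.
#' @return an `rm_anova_result`: F, df1, df2, p, gg_epsilon, p_gg,
#'   eta_sq_partial, posthoc table, n, k.
#' @export
rm_anova <- function(values, value_col = "offline_change_pct") {
  Y <- if (is.matrix(values)) values else {
    change_matrix(stats::setNames(
      values[, c("subject", "condition", value_col)],
      c("subject", "condition", "offline_change_pct")))
  }
  n <- nrow(Y); k <- ncol(Y)
  if (n < 3) stop("need at least 3 subjects")
  if (anyNA(Y)) stop("missing cells")
  long <- data.frame(
    y = as.vector(Y),
    subject = factor(rep(seq_len(n), k)),
    condition = factor(rep(colnames(Y), each = n)))
  fit <- stats::aov(y ~ condition + Error(subject / condition), data = long)
  tab <- summary(fit)[["Error: subject:condition"]][[1]]
  ss_cond <- tab["condition", "Sum Sq"]
  ss_err <- tab["Residuals", "Sum Sq"]
  df1 <- tab["condition", "Df"]
  df2 <- tab["Residuals", "Df"]
  tol <- .Machine$double.eps^0.75 * max(1, sum(Y^2))
  if (ss_cond < tol) {
    Fval <- 0; pval <- 1
  } else if (ss_err < tol) {
    Fval <- Inf; pval <- 0
  } else {
    Fval <- (ss_cond / df1) / (ss_err / df2)
    pval <- stats::pf(Fval, df1, df2, lower.tail = FALSE)
  }
  eps <- gg_epsilon(Y)
  p_gg <- if (is.finite(Fval)) {
    stats::pf(Fval, df1 * eps, df2 * eps, lower.tail = FALSE)
  } else 0
  if (Fval == 0) p_gg <- 1
  eta <- if (ss_cond + ss_err > 0) ss_cond / (ss_cond + ss_err) else 0

  pairs <- utils::combn(colnames(Y), 2)
  ph <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- Y[, pairs[1, j]]; b <- Y[, pairs[2, j]]
    d <- a - b
    if (stats::sd(d) == 0) {
      # degenerate: constant difference (zero variance)
      tv <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      data.frame(contrast = paste(pairs[1, j], "vs", pairs[2, j]),
                 t = tv, df = n - 1, p = if (tv == 0) 1 else 0,
                 cohens_d = NA_real_)
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
      data.frame(contrast = paste(pairs[1, j], "vs", pairs[2, j]),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, cohens_d = mean(d) / stats::sd(d))
    }
  })
  posthoc <- do.call(rbind, ph)
  posthoc$p_fdr <- stats::p.adjust(posthoc$p, method = "BH")

  structure(list(F = Fval, df1 = df1, df2 = df2, p = pval,
                 gg_epsilon = eps, p_gg = p_gg, eta_sq_partial = eta,
                 posthoc = posthoc, n = n, k = k),
            class = "rm_anova_result")
}

# Greenhouse-Geisser epsilon from the double-centered covariance matrix.
gg_epsilon <- function(Y) {
  k <- ncol(Y)
  C <- stats::cov(Y)
  if (all(abs(C) < .Machine$double.eps)) return(1)
  M <- C - outer(rowMeans(C), rep(1, k)) - outer(rep(1, k), colMeans(C)) +
    mean(C)
  num <- sum(diag(M))^2
  den <- (k - 1) * sum(M^2)
  if (den == 0) return(1)
  max(1 / (k - 1), min(1, num / den))
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("One-way rmANOVA: F(%d,%d) = %.3f, p = %.4g (GG-corrected %.4g, epsilon %.3f), partial eta^2 = %.3f\n",
              x$df1, x$df2, x$F, x$p, x$p_gg, x$gg_epsilon,
              x$eta_sq_partial))
  cat("Posthoc paired t tests (FDR-corrected):\n")
  print(x$posthoc, row.names = FALSE, digits = 4)
  invisible(x)
}
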