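#' Performance metrics for one game session
#'
#' Computes the five session metrics from an engine event log (and,
#' optionally, an offline fixation summary): \emph{score} (correct trials;
#' one point per prompted object fixated), \emph{time to complete} (last
#' logged event minus first prompt, seconds), \emph{mean response time}
#' (prompt-to-correct-look, seconds, over correct trials only — timed-out
#' trials are excluded and counted in `n_timeouts`, and trials that received
#' assistance are excluded by default), plus the face-fixation counts and
#' eye/other ratios when a fixation summary is supplied. For a 50-prompt
#' bubble log the five speed-group scores are included.
#'
#' @param log Session event log data frame (see [session_log()]), or a
#'   `gl_sim` object.
#' @param fixations Optional `gl_fix_summary`.
#' @param include_assisted Include assisted correct trials in the response
#'   time mean (default `FALSE`).
#' @return A list of class `gl_metrics`.
#' @export
compute_session_metrics <- function(log, fixations = NULL,
                                    include_assisted = FALSE) {
  if (inherits(log, "gl_sim")) log <- log$log
  if (is.null(log) || nrow(log) == 0L) {
    stop("empty session log", call. = FALSE)
  }
  trials <- log[log$event == "trial_end", , drop = FALSE]
  score <- sum(trials$outcome == "correct")
  prompt_t <- log$t_ms[log$event == "prompt"]
  t0 <- if (length(prompt_t)) prompt_t[1L] else log$t_ms[1L]
  time_to_complete_s <- (log$t_ms[nrow(log)] - t0) / 1000

  # response times from prompt/trial_end row pairs, correct trials only
  rt <- numeric(0)
  n_assisted_correct <- 0L
  for (i in which(trials$outcome == "correct")) {
    idx <- trials$prompt_index[i]
    tp <- log$t_ms[log$event %in% c("prompt", "prompt_repeat") &
                   log$prompt_index == idx]
    if (length(tp) == 0L) next
    assisted <- trials$assists[i] > 0L
    if (assisted) n_assisted_correct <- n_assisted_correct + 1L
    if (assisted && !include_assisted) next
    rt <- c(rt, trials$t_ms[i] - tp[1L])
  }
  n_timeouts <- sum(log$event == "follow_timeout") +
    sum(grepl("^assist:", log$event))

  groups <- NULL
  game <- log$game[1L]
  if (game == "bubble" && nrow(trials) == 50L) {
    groups <- speed_group_scores(data.frame(
      prompt_index = trials$prompt_index,
      outcome = trials$outcome))
  }
  structure(list(game = game, score = score,
                 time_to_complete_s = time_to_complete_s,
                 mean_response_time_s = if (length(rt)) mean(rt) / 1000
                                        else NA_real_,
                 n_response_times = length(rt),
                 n_timeouts = n_timeouts,
                 n_trials = nrow(trials),
                 n_assisted_correct = n_assisted_correct,
                 terminated = any(log$event == "terminate"),
                 speed_group_scores = groups,
                 fixation_total_face = fixations$total_face,
                 fixation_eye = fixations$eye,
                 fixation_other = fixations$other_facial,
                 ratio_eye = fixations$ratio_eye,
                 ratio_other = fixations$ratio_other),
            class = "gl_metrics")
}

#' @export
print.gl_metrics <- function(x, ...) {
  cat("<gl_metrics> ", x$game, " | score ", x$score,
      sprintf(" | time to complete %.1f s", x$time_to_complete_s),
      if (!is.na(x$mean_response_time_s)) {
        sprintf(" | mean response %.2f s (n=%d)", x$mean_response_time_s,
                x$n_response_times)
      } else "",
      " | timeouts ", x$n_timeouts, "\n", sep = "")
  if (!is.null(x$speed_group_scores)) {
    cat("  speed groups: ", paste(x$speed_group_scores, collapse = " "), "\n",
        sep = "")
  }
  if (!is.null(x$fixation_total_face)) {
    cat("  face fixations: ", x$fixation_total_face, " (eye ", x$fixation_eye,
        ", other ", x$fixation_other, ")\n", sep = "")
  }
  invisible(x)
}

#' Speed-group scores for a 50-prompt bubble session
#'
#' The 50 prompts are partitioned into five consecutive blocks of 10; since
#' the prompt speed rises by a constant 2 ups per prompt, each block spans a
#' contiguous 20-ups band of prompt speeds, and its score is the number of
#' correct trials in the block (maximum 10 points per group).
#'
#' @param trials Data frame with `prompt_index` (1..50) and `outcome`.
#' @return Integer vector of length 5; the five values sum to the total
#'   score.
#' @export
speed_group_scores <- function(trials) {
  if (inherits(trials, "gl_sim")) trials <- trials$trials
  if (nrow(trials) != 50L) {
    stop("speed-group scoring requires exactly 50 bubble trials (got ",
         nrow(trials), ")", call. = FALSE)
  }
  grp <- ((as.integer(trials$prompt_index) - 1L) %/% 10L) + 1L
  if (any(grp < 1L | grp > 5L)) stop("prompt_index out of 1..50", call. = FALSE)
  as.integer(tapply(trials$outcome == "correct", factor(grp, levels = 1:5),
                    sum, default = 0L))
}

#' Absolute standardized mean difference (pooled-SD Cohen's d)
#'
#' \deqn{|d| = |m_1 - m_2| / \sqrt{(s_1^2 + s_2^2)/2}}
#' The root-mean-square pooling of the two SDs makes the statistic symmetric
#' in its two groups and scale-invariant.
#'
#' @param mean1,sd1 First group summary.
#' @param mean2,sd2 Second group summary.
#' @return Non-negative effect size.
#' @examples
#' cohens_d(244.04, 74.74, 164.18, 39.93)  # ~1.333
#' @export
cohens_d <- function(mean1, sd1, mean2, sd2) {
  if (sd1 < 0 || sd2 < 0) stop("SDs must be non-negative", call. = FALSE)
  if (mean1 == mean2) return(0)
  pooled <- sqrt((sd1^2 + sd2^2) / 2)
  if (pooled == 0) {
    stop("effect size undefined: both SDs are zero with unequal means",
         call. = FALSE)
  }
  abs(mean1 - mean2) / pooled
}

#' Two-sample t statistic from group summaries (descriptive only)
#'
#' Welch-style statistic computed from means, SDs and sizes. Published
#' p-values from paired designs on raw data cannot be reproduced from
#' summaries; this helper is offered for descriptive comparison only.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries.
#' @return The t statistic.
#' @export
t_stat_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  (mean1 - mean2) / sqrt(sd1^2 / n1 + sd2^2 / n2)
}

#' Summarize per-arm, per-timepoint metric values with effect sizes
#'
#' Takes long-format cohort values and returns the mean/SD summary per cell
#' plus the absolute pre/post effect size per arm and metric. Cells with a
#' single value report `NA` for the SD and the effect size; arms of unequal
#' size are summarized per-cell, never dropped.
#'
#' @param values Data frame with columns `arm`, `timepoint` (`"pre"` /
#'   `"post"`), `metric`, `value`.
#' @return A list of class `gl_cohort_summary` with `cells` (columns
#'   `arm,timepoint,metric,n,mean,sd`) and `effects` (columns
#'   `arm,metric,d`).
#' @export
summarize_cohort <- function(values) {
  req <- c("arm", "timepoint", "metric", "value")
  if (!all(req %in% names(values))) {
    stop("values must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(values$arm, values$timepoint, values$metric, drop = TRUE)
  cells <- do.call(rbind, lapply(split(values, key), function(v) {
    data.frame(arm = v$arm[1L], timepoint = v$timepoint[1L],
               metric = v$metric[1L], n = nrow(v),
               mean = mean(v$value, na.rm = TRUE),
               sd = if (nrow(v) >= 2L) stats::sd(v$value, na.rm = TRUE)
                    else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(cells) <- NULL
  combos <- unique(cells[, c("arm", "metric")])
  effects <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    pre <- cells[cells$arm == combos$arm[i] & cells$metric == combos$metric[i] &
                 cells$timepoint == "pre", ]
    post <- cells[cells$arm == combos$arm[i] & cells$metric == combos$metric[i] &
                  cells$timepoint == "post", ]
    d <- if (nrow(pre) == 1L && nrow(post) == 1L &&
             !is.na(pre$sd) && !is.na(post$sd)) {
      tryCatch(cohens_d(pre$mean, pre$sd, post$mean, post$sd),
               error = function(e) NA_real_)
    } else NA_real_
    data.frame(arm = combos$arm[i], metric = combos$metric[i], d = d,
               stringsAsFactors = FALSE)
  }))
  structure(list(cells = cells, effects = effects),
            class = "gl_cohort_summary")
}

#' @export
print.gl_cohort_summary <- function(x, ...) {
  cat("<gl_cohort_summary>\n")
  print.data.frame(x$cells, row.names = FALSE)
  cat("effect sizes (|d|, pre vs post):\n")
  print.data.frame(x$effects, row.names = FALSE)
  invisible(x)
}
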