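#' Synthetic participant profile
#'
#' Parameterizes a virtual participant's gaze behaviour for closed-loop
#' testing of the games. The participant shares gaze (fixates the avatar's
#' eye region) within a share phase with probability `p_share` after a
#' log-normal latency; once prompted, follows to the correct object with
#' probability
#' \deqn{p_{follow}(v, L) = \mathrm{logit}^{-1}(a - b\,v - c\,(L-1))}
#' where `v` is the prompt speed in ups and `L` the prompt level, after a
#' log-normal response latency; otherwise dwells on distractors (the passive
#' facial features with weight `distractor_facial_w`, wrong game objects with
#' the remainder). The emitted stream has fixation plateaus with Gaussian
#' jitter, linear 30-80 ms saccade transitions, and blink gaps (invalid
#' samples), at a nominal 50-60 Hz binocular-averaged sampling rate.
#'
#' Log-normal latencies are parameterized by median (ms) and log-scale sigma
#' (strictly positive, right-skewed — the standard shape for human reaction
#' times).
#'
#' @param p_share Probability of sharing gaze within a 30 s share window.
#' @param share_latency_median_ms,share_latency_sigma Share latency.
#' @param follow_a,follow_b,follow_c Logistic follow-success coefficients
#'   (intercept, speed slope per ups, level slope per level step).
#' @param response_latency_median_ms,response_latency_sigma Follow latency.
#' @param move_latency_ms Delay before moving an enabled tangram piece.
#' @param jitter_sd Fixation noise SD, px.
#' @param sampling_hz Tracker rate; must lie in [50, 60].
#' @param blink_rate_hz Blink starts per second (0 disables blinks).
#' @param blink_duration_median_ms,blink_duration_sigma Blink length.
#' @param distractor_facial_w Weight of passive facial ROIs among distractor
#'   dwells (the remainder goes to wrong game objects).
#' @return A list of class `gl_profile`.
#' @export
participant_profile <- function(p_share = 0.95,
                                share_latency_median_ms = 1500,
                                share_latency_sigma = 0.5,
                                follow_a = 3.0, follow_b = 0.05,
                                follow_c = 0.3,
                                response_latency_median_ms = 900,
                                response_latency_sigma = 0.4,
                                move_latency_ms = 500,
                                jitter_sd = 12, sampling_hz = 55,
                                blink_rate_hz = 0.15,
                                blink_duration_median_ms = 100,
                                blink_duration_sigma = 0.25,
                                distractor_facial_w = 1.0) {
  if (p_share < 0 || p_share > 1) stop("p_share must be in [0,1]", call. = FALSE)
  if (sampling_hz < 50 || sampling_hz > 60) {
    stop("sampling_hz must be within the tracker's 50-60 Hz range", call. = FALSE)
  }
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  if (distractor_facial_w < 0 || distractor_facial_w > 1) {
    stop("distractor_facial_w must be in [0,1]", call. = FALSE)
  }
  structure(list(p_share = p_share,
                 share_latency_median_ms = share_latency_median_ms,
                 share_latency_sigma = share_latency_sigma,
                 follow_a = follow_a, follow_b = follow_b, follow_c = follow_c,
                 response_latency_median_ms = response_latency_median_ms,
                 response_latency_sigma = response_latency_sigma,
                 move_latency_ms = move_latency_ms,
                 jitter_sd = jitter_sd, sampling_hz = sampling_hz,
                 blink_rate_hz = blink_rate_hz,
                 blink_duration_median_ms = blink_duration_median_ms,
                 blink_duration_sigma = blink_duration_sigma,
                 distractor_facial_w = distractor_facial_w),
            class = "gl_profile")
}

#' @export
print.gl_profile <- function(x, ...) {
  cat("<gl_profile> p_share=", x$p_share,
      " follow: a=", x$follow_a, " b=", x$follow_b, " c=", x$follow_c,
      " | ", x$sampling_hz, " Hz, jitter ", x$jitter_sd, " px\n", sep = "")
  invisible(x)
}

#' An ideal responder: certain share and follow, short latencies, no blinks
#'
#' @param latency_ms Constant share/response latency (default 300 ms).
#' @return A `gl_profile`.
#' @export
ideal_profile <- function(latency_ms = 300) {
  participant_profile(p_share = 1,
                      share_latency_median_ms = latency_ms,
                      share_latency_sigma = 0,
                      follow_a = 50, follow_b = 0, follow_c = 0,
                      response_latency_median_ms = latency_ms,
                      response_latency_sigma = 0,
                      jitter_sd = 3, blink_rate_hz = 0)
}

#' Follow-success probability of a profile at a given prompt
#'
#' @param profile A `gl_profile`.
#' @param speed_ups Prompt speed.
#' @param level Prompt level 1..3.
#' @return Probability in (0, 1).
#' @export
follow_probability <- function(profile, speed_ups, level = 2L) {
  stats::plogis(profile$follow_a - profile$follow_b * speed_ups -
                profile$follow_c * (level - 1))
}

rlnorm_ms <- function(median_ms, sigma) {
  if (sigma <= 0) return(median_ms)
  stats::rlnorm(1L, meanlog = log(median_ms), sdlog = sigma)
}

#' Simulate a full closed-loop game session
#'
#' Generates the participant's gaze stream sample by sample and feeds every
#' sample through the real gaze runtime (dwell accounting, cue / timeout
#' checks) and game engine, so the returned session log is produced by the
#' engine itself, never short-circuited. For speed the per-sample dwell
#' arithmetic is inlined, but it is the same rule set as [update_dwell()] /
#' [check_timeouts()] (an equivalence property is part of the test suite).
#'
#' @param profile A `gl_profile`.
#' @param config A `gl_config`.
#' @param seed Integer seed; all randomness (behaviour, jitter, blinks,
#'   prompt directions) flows from it.
#' @param gaze A `gl_gaze_params`.
#' @param max_ms Hard wall-clock cap on simulated time.
#' @return A list of class `gl_sim` with elements `gaze` (data frame
#'   `t_ms,x_px,y_px,valid`), `log` (engine event log), `trials`, and
#'   `state` (the final `gl_session`).
#' @examples
#' \donttest{
#' sim <- simulate_session(ideal_profile(), game_config("bubble"), seed = 1)
#' sim$state$score  # 50
#' }
#' @export
simulate_session <- function(profile, config, seed, gaze = gaze_params(),
                             max_ms = 3.6e6) {
  stopifnot(inherits(profile, "gl_profile"), inherits(config, "gl_config"))
  set.seed(as.integer(seed))
  state <- new_session(config)
  rois <- state$rois
  rx0 <- rois$x0; rx1 <- rois$x1; ry0 <- rois$y0; ry1 <- rois$y1
  rname <- rois$name; ractive <- rois$active
  facial <- rname[rois$kind == "facial_feature"]
  objects <- rname[rois$kind == "game_object"]
  eye_pos <- roi_center(rois, "avatar_eye")

  theta_fix <- gaze$theta_fix_ms; theta_phase <- gaze$theta_phase_ms
  theta_term <- gaze$theta_term_ms; gap_tol <- gaze$gap_tol_ms
  hz <- profile$sampling_hz
  jit <- profile$jitter_sd

  # dwell-tracking scalars (inlined gl_dwell_state)
  cur_roi <- NA_character_; dwell <- 0; gap <- 0; fired <- FALSE
  phase_clock <- 0; inter_clock <- 0; cue_fired <- FALSE
  last_t <- 0

  # behaviour state
  bs_serial <- -1L
  will <- FALSE; act_t <- Inf; act_target <- eye_pos
  goal <- c(stats::runif(1, 0, 1920), stats::runif(1, 0, 1080))
  pos <- goal
  sac_from <- pos; sac_t0 <- -Inf; sac_dur <- 1
  next_distract_t <- 0
  move_due <- Inf
  blink_until <- -Inf
  next_blink <- if (profile$blink_rate_hz > 0) {
    stats::rexp(1L) * 1000 / profile$blink_rate_hz
  } else Inf

  pick_distractor <- function() {
    # wrong-object dwells must never land on the currently prompted target
    pool <- objects
    if (!is.null(state$trial) && state$phase == "WaitFollow") {
      pool <- setdiff(pool, state$trial$target)
    }
    pool_facial <- stats::runif(1L) < profile$distractor_facial_w ||
      length(pool) == 0L
    nm <- if (pool_facial) facial[sample.int(length(facial), 1L)]
          else pool[sample.int(length(pool), 1L)]
    roi_center(rois, nm)
  }
  set_goal <- function(g, t) {
    sac_from <<- pos; sac_t0 <<- t
    sac_dur <<- stats::runif(1L, 30, 80)
    goal <<- g
  }

  cap <- 300000L
  st_t <- numeric(cap); st_x <- numeric(cap); st_y <- numeric(cap)
  st_v <- logical(cap)
  n <- 0L
  i <- 0L

  while (!state$done) {
    i <- i + 1L
    t <- round(i * 1000 / hz)
    dt <- t - last_t
    last_t <- t
    if (t > max_ms) break
    phase_clock <- phase_clock + dt
    inter_clock <- inter_clock + dt

    # ---- replan behaviour when the engine phase (re)starts ----
    if (state$phase_serial != bs_serial) {
      bs_serial <- state$phase_serial
      move_due <- Inf
      if (state$phase == "WaitShare") {
        will <- stats::runif(1L) < profile$p_share
        act_t <- if (will) {
          t + rlnorm_ms(profile$share_latency_median_ms,
                        profile$share_latency_sigma)
        } else Inf
        act_target <- eye_pos
      } else if (state$phase == "WaitFollow") {
        p <- follow_probability(profile, state$trial$speed, state$trial$level)
        will <- stats::runif(1L) < p
        act_t <- if (will) {
          t + rlnorm_ms(profile$response_latency_median_ms,
                        profile$response_latency_sigma)
        } else Inf
        act_target <- roi_center(rois, state$trial$target)
      } else if (state$phase == "MovePiece") {
        move_due <- t + profile$move_latency_ms
        act_t <- t  # keep gaze on the piece while moving it
        act_target <- roi_center(rois, state$movable)
      }
      next_distract_t <- if (is.finite(act_t)) Inf else t
    }

    # ---- gaze kinematics ----
    if (is.finite(act_t) && t >= act_t) {
      set_goal(act_target, t)
      act_t <- -Inf  # goal locked on target; hold there
      next_distract_t <- Inf
    } else if (t >= next_distract_t) {
      set_goal(pick_distractor(), t)
      next_distract_t <- t + stats::runif(1L, 800, 2500)
    }
    if (t < sac_t0 + sac_dur) {
      f <- (t - sac_t0) / sac_dur
      pos <- sac_from + f * (goal - sac_from)
    } else {
      pos <- goal
    }

    # ---- blinks ----
    if (t >= next_blink && t > blink_until) {
      blink_until <- t + rlnorm_ms(profile$blink_duration_median_ms,
                                   profile$blink_duration_sigma)
      next_blink <- blink_until +
        stats::rexp(1L) * 1000 / profile$blink_rate_hz
    }
    valid <- t > blink_until
    if (valid && jit > 0) {
      j <- stats::rnorm(2L, 0, jit)
      x <- pos[1L] + j[1L]; y <- pos[2L] + j[2L]
    } else if (valid) {
      x <- pos[1L]; y <- pos[2L]
    } else {
      x <- NA_real_; y <- NA_real_
    }

    n <- n + 1L
    if (n > cap) {
      cap <- cap * 2L
      length(st_t) <- cap; length(st_x) <- cap
      length(st_y) <- cap; length(st_v) <- cap
    }
    st_t[n] <- t; st_x[n] <- x; st_y[n] <- y; st_v[n] <- valid

    # ---- dwell update (same rules as update_dwell) ----
    trigger <- NA_character_
    if (!valid) {
      gap <- gap + dt
      if (gap > gap_tol) {
        cur_roi <- NA_character_; dwell <- 0; fired <- FALSE
      }
    } else {
      gap <- 0
      h <- which(x >= rx0 & x < rx1 & y >= ry0 & y < ry1)
      hit <- if (length(h) == 0L) NA_character_ else rname[h[1L]]
      if (is.na(hit)) {
        cur_roi <- NA_character_; dwell <- 0; fired <- FALSE
      } else if (identical(hit, cur_roi)) {
        dwell <- dwell + dt
        if (!fired && dwell >= theta_fix) {
          fired <- TRUE
          if (ractive[h[1L]]) trigger <- hit
        }
      } else {
        cur_roi <- hit; dwell <- 0; fired <- FALSE
      }
    }

    # ---- event delivery (same rules as check_timeouts) ----
    if (!is.na(trigger)) {
      inter_clock <- 0
      state <- step_session(state, gaze_event(t, "FixationTrigger", trigger))
    }
    if (!state$done) {
      if (inter_clock >= theta_term) {
        state <- step_session(state, gaze_event(t, "Terminate"))
      } else if (state$phase == "WaitShare" && !cue_fired &&
                 phase_clock >= theta_phase) {
        state <- step_session(state, gaze_event(t, "CueAudio"))
        if (state$game == "tangram") {
          state <- step_session(state, gaze_event(t, "CueVisual", "avatar_eye"))
        }
        cue_fired <- TRUE
        # the cue draws the participant's attention: re-decide whether to
        # share in the remainder of the phase
        if (!will) bs_serial <- -1L
      } else if (state$phase == "WaitFollow" && phase_clock >= theta_phase) {
        state <- step_session(state, gaze_event(t, "FollowTimeout"))
      }
    }
    if (!state$done && state$phase == "MovePiece" && t >= move_due) {
      state <- step_session(state, gaze_event(t, "MouseMove", state$movable))
    }
    if (state$phase_serial != bs_serial) {  # phase changed: reset phase clocks
      phase_clock <- 0
      cue_fired <- FALSE
    }
  }

  if (n == 0L) stop("profile produced no samples", call. = FALSE)
  gaze_df <- data.frame(t_ms = st_t[seq_len(n)], x_px = st_x[seq_len(n)],
                        y_px = st_y[seq_len(n)], valid = st_v[seq_len(n)])
  structure(list(gaze = gaze_df, log = session_log(state),
                 trials = session_trials(state), state = state),
            class = "gl_sim")
}

#' @export
print.gl_sim <- function(x, ...) {
  st <- x$state
  cat("<gl_sim> ", st$game, " session | score ", st$score, "/",
      if (st$game == "bubble") st$config$n_prompts else st$config$n_pieces,
      " | ", nrow(x$gaze), " gaze samples | ",
      length(st$trials), " trials",
      if (st$complete) " | complete" else " | terminated", "\n", sep = "")
  invisible(x)
}

# family mean parameters for cohort simulation
family_means <- function(family) {
  switch(family,
    ideal = list(p_share = 1, a = 50, b = 0, c = 0, share_med = 300,
                 resp_med = 300, jitter = 3, blink = 0),
    td_like = list(p_share = 0.98, a = 4.5, b = 0.04, c = 0.2,
                   share_med = 1000, resp_med = 700, jitter = 10,
                   blink = 0.15),
    asd_like_pre = list(p_share = 0.90, a = 3.0, b = 0.05, c = 0.35,
                        share_med = 2500, resp_med = 1800, jitter = 16,
                        blink = 0.15),
    asd_like_post = list(p_share = 0.96, a = 4.2, b = 0.038, c = 0.25,
                         share_med = 1400, resp_med = 1000, jitter = 13,
                         blink = 0.15),
    stop("unknown profile family: ", family, call. = FALSE)
  )
}

#' Mean profile of a named participant family
#'
#' Families: `"ideal"`, `"td_like"` (high follow intercept, shallow speed
#' slope), `"asd_like_pre"` (lower intercept, steeper speed slope, longer
#' latencies), `"asd_like_post"` (intermediate, emulating post-intervention
#' improvement). Family parameters are this package's own calibration for
#' end-to-end experiments, not measured quantities.
#'
#' @param family Family name.
#' @return A `gl_profile` at the family means.
#' @export
profile_family <- function(family = c("td_like", "asd_like_pre",
                                      "asd_like_post", "ideal")) {
  family <- match.arg(family)
  m <- family_means(family)
  participant_profile(p_share = m$p_share,
                      share_latency_median_ms = m$share_med,
                      follow_a = m$a, follow_b = m$b, follow_c = m$c,
                      response_latency_median_ms = m$resp_med,
                      jitter_sd = m$jitter, blink_rate_hz = m$blink)
}

#' Draw a cohort of participant profiles around family means
#'
#' Individual profiles scatter around the family means: the follow intercept
#' and slopes vary normally (slopes truncated at 0), the share probability
#' varies on the logit scale, and latency medians vary log-normally.
#' `dispersion = 0` returns `n` copies of the family means.
#'
#' @param n Number of participants (>= 1).
#' @param family Family name, see [profile_family()].
#' @param seed Optional seed.
#' @param dispersion Scale factor on the between-participant scatter.
#' @return A list of `n` `gl_profile` objects.
#' @export
make_cohort <- function(n, family = "td_like", seed = NULL, dispersion = 1) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- family_means(family)
  lapply(seq_len(n), function(i) {
    a <- m$a + dispersion * stats::rnorm(1L, 0, 0.5)
    b <- max(0, m$b + dispersion * stats::rnorm(1L, 0, 0.01))
    c_ <- max(0, m$c + dispersion * stats::rnorm(1L, 0, 0.08))
    ps <- if (m$p_share >= 1) 1 else stats::plogis(
      stats::qlogis(m$p_share) + dispersion * stats::rnorm(1L, 0, 0.4))
    participant_profile(p_share = ps,
                        share_latency_median_ms =
                          m$share_med * exp(dispersion * stats::rnorm(1L, 0, 0.2)),
                        follow_a = a, follow_b = b, follow_c = c_,
                        response_latency_median_ms =
                          m$resp_med * exp(dispersion * stats::rnorm(1L, 0, 0.2)),
                        jitter_sd = m$jitter, blink_rate_hz = m$blink)
  })
}
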