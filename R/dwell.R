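#' Gaze-runtime thresholds
#'
#' The four timing constants of the real-time gaze controller:
#' \describe{
#'   \item{theta_fix_ms}{dwell time on one ROI that registers a fixation
#'     trigger (default 200 ms, a standard minimum human fixation duration;
#'     the comparison is `>=`).}
#'   \item{theta_phase_ms}{waiting time in a share or follow phase before a
#'     cue / timeout fires (default 30 s).}
#'   \item{theta_term_ms}{time without any registered interaction before the
#'     session terminates (default 120 s).}
#'   \item{gap_tol_ms}{maximum blink / track-loss gap that does not reset a
#'     running dwell (default 75 ms; consumer trackers drop samples during
#'     blinks, and a blink should not cancel an otherwise steady gaze).}
#' }
#'
#' @param theta_fix_ms,theta_phase_ms,theta_term_ms,gap_tol_ms Milliseconds.
#' @return A list of class `gl_gaze_params`.
#' @export
gaze_params <- function(theta_fix_ms = 200, theta_phase_ms = 30000,
                        theta_term_ms = 120000, gap_tol_ms = 75) {
  p <- list(theta_fix_ms = as.numeric(theta_fix_ms),
            theta_phase_ms = as.numeric(theta_phase_ms),
            theta_term_ms = as.numeric(theta_term_ms),
            gap_tol_ms = as.numeric(gap_tol_ms))
  for (nm in names(p)) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      stop(sprintf("gaze parameter '%s' must be a positive number", nm),
           call. = FALSE)
    }
  }
  class(p) <- "gl_gaze_params"
  p
}

#' Construct a gaze event
#'
#' @param t Time in milliseconds from session start.
#' @param kind One of `"FixationTrigger"`, `"CueAudio"`, `"CueVisual"`,
#'   `"FollowTimeout"`, `"Terminate"`, `"MouseMove"`.
#' @param roi Optional ROI name; mandatory for `FixationTrigger`.
#' @export
gaze_event <- function(t, kind, roi = NA_character_) {
  kinds <- c("FixationTrigger", "CueAudio", "CueVisual", "FollowTimeout",
             "Terminate", "MouseMove")
  if (!kind %in% kinds) stop("unknown event kind: ", kind, call. = FALSE)
  if (kind == "FixationTrigger" && is.na(roi)) {
    stop("FixationTrigger must carry an ROI name", call. = FALSE)
  }
  structure(list(t = as.numeric(t), kind = kind, roi = roi),
            class = "gl_event")
}

#' Fresh dwell-tracking state
#'
#' Tracks the ROI currently gazed at, the accumulated in-ROI dwell, the time
#' since the current game phase began and the time since the last registered
#' interaction (any fixation trigger on an active ROI). `fired` marks that the
#' current dwell episode already emitted its trigger; `cue_fired` that the
#' once-per-phase 30 s cue has been given.
#'
#' @param t0 Session-start timestamp in ms (default 0).
#' @return A list of class `gl_dwell_state`.
#' @export
dwell_state <- function(t0 = 0) {
  structure(list(current_roi = NA_character_, dwell_ms = 0, gap_ms = 0,
                 last_t = as.numeric(t0), phase_clock_ms = 0,
                 interaction_clock_ms = 0, fired = FALSE, cue_fired = FALSE),
            class = "gl_dwell_state")
}

#' Advance the dwell state by one gaze sample
#'
#' Dwell accumulates by timestamp differences, not sample counts, so streams
#' at different sampling rates behave alike. A sample entering a new ROI
#' starts a fresh episode at zero dwell; continuing samples add the elapsed
#' interval; leaving all ROIs (or switching ROI) resets. Invalid samples
#' (blinks) contribute no dwell, and a run of them longer than
#' `gap_tol_ms` resets the episode. When the accumulated dwell first reaches
#' `theta_fix_ms` on an *active* ROI, one `FixationTrigger` is emitted for the
#' episode; passive (facial-feature) ROIs accumulate dwell but never trigger.
#'
#' The two phase clocks advance with every sample; the caller resets
#' `phase_clock_ms` when the game phase changes and `interaction_clock_ms`
#' when a trigger registers.
#'
#' @param state A `gl_dwell_state`.
#' @param sample List with `t` (ms), `x`, `y` (px), `valid` (logical).
#' @param rois A `gl_roi_set`.
#' @param params A `gl_gaze_params`.
#' @return `list(state = <updated state>, events = <list of gl_event>)`.
#' @export
update_dwell <- function(state, sample, rois, params = gaze_params()) {
  t <- as.numeric(sample$t)
  dt <- t - state$last_t
  if (dt < 0) {
    stop(sprintf("out-of-order gaze sample at t=%.3f ms (previous t=%.3f ms)",
                 t, state$last_t), call. = FALSE)
  }
  state$last_t <- t
  state$phase_clock_ms <- state$phase_clock_ms + dt
  state$interaction_clock_ms <- state$interaction_clock_ms + dt
  events <- list()

  if (!isTRUE(as.logical(sample$valid))) {
    state$gap_ms <- state$gap_ms + dt
    if (state$gap_ms > params$gap_tol_ms) {
      state$current_roi <- NA_character_
      state$dwell_ms <- 0
      state$fired <- FALSE
    }
    return(list(state = state, events = events))
  }

  state$gap_ms <- 0
  hit <- hit_test(sample, rois)
  if (is.na(hit)) {
    state$current_roi <- NA_character_
    state$dwell_ms <- 0
    state$fired <- FALSE
  } else if (identical(hit, state$current_roi)) {
    state$dwell_ms <- state$dwell_ms + dt
    if (!state$fired && state$dwell_ms >= params$theta_fix_ms) {
      state$fired <- TRUE
      if (rois$active[match(hit, rois$name)]) {
        events[[1L]] <- gaze_event(t, "FixationTrigger", hit)
      }
    }
  } else {
    state$current_roi <- hit
    state$dwell_ms <- 0
    state$fired <- FALSE
  }
  list(state = state, events = events)
}

#' Emit cue / timeout / termination events for the current phase
#'
#' In the gaze-share phase, 30 s without a registered share produces a
#' once-per-phase audio cue (a bell) in both games plus a visual cue
#' highlighting the avatar's eye region in the tangram game. In the
#' gaze-follow phase, 30 s produces a `FollowTimeout` (the engine maps it to
#' the next prompt in the bubble game, or an assist request in the tangram
#' game). Independently, 120 s without any interaction terminates the
#' session. `Terminate` preempts everything else.
#'
#' The function is pure; the caller marks `cue_fired` on the dwell state after
#' delivering the cue so it fires once per phase.
#'
#' @param state A `gl_dwell_state` (phase and interaction clocks are read).
#' @param phase `"WaitShare"` or `"WaitFollow"`.
#' @param game `"bubble"` or `"tangram"`.
#' @param now Current time, ms.
#' @param params A `gl_gaze_params`.
#' @return List of `gl_event` (possibly empty).
#' @export
check_timeouts <- function(state, phase, game, now, params = gaze_params()) {
  if (!phase %in% c("WaitShare", "WaitFollow")) {
    stop("unknown phase: ", phase, call. = FALSE)
  }
  if (!game %in% c("bubble", "tangram")) {
    stop("unknown game: ", game, call. = FALSE)
  }
  if (state$interaction_clock_ms >= params$theta_term_ms) {
    return(list(gaze_event(now, "Terminate")))
  }
  events <- list()
  if (phase == "WaitShare" && !state$cue_fired &&
      state$phase_clock_ms >= params$theta_phase_ms) {
    events <- c(events, list(gaze_event(now, "CueAudio")))
    if (game == "tangram") {
      events <- c(events, list(gaze_event(now, "CueVisual", "avatar_eye")))
    }
  }
  if (phase == "WaitFollow" && state$phase_clock_ms >= params$theta_phase_ms) {
    events <- c(events, list(gaze_event(now, "FollowTimeout")))
  }
  events
}
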