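#' Game configuration
#'
#' Fixed rules of the two games. The bubble-popping game is the assessment
#' game: 50 prompts over 8 bubbles, prompt level pinned at 2, speed rising
#' 2 ups per prompt, no adaptation and no assistance. The tangram-puzzle game
#' is the practice game: 7 pieces, level from the game-number schedule
#' (games 1-3 level 1, 4-6 level 2, 7-9 level 3) with the adaptation
#' controller active, and least-to-most assistance on failed follows.
#'
#' @param game `"bubble"` or `"tangram"`.
#' @param n_prompts Bubble prompts per session (default 50).
#' @param n_bubbles Number of bubbles (default 8).
#' @param bubble_respawn_ms Delay before a popped bubble regenerates
#'   (default 5000 ms).
#' @param n_pieces Tangram pieces (default 7).
#' @param game_number Tangram game number 1..9 for the level schedule.
#' @param adaptation_enabled,assistance_enabled Tangram only; forced off for
#'   the bubble game.
#' @param v0_ups,delta_ups,floor_ups Speed schedule parameters (ups).
#' @param streak Streak length for the adaptation rules.
#' @param assist_slowdown Speed factor for repeated (assisted) prompts.
#' @param no_immediate_repeat Forbid prompting the same target twice in a row.
#' @param scene A `gl_roi_set`; defaults to [default_scene()] for the game.
#' @return A list of class `gl_config`.
#' @export
game_config <- function(game = c("bubble", "tangram"),
                        n_prompts = 50L, n_bubbles = 8L,
                        bubble_respawn_ms = 5000,
                        n_pieces = 7L, game_number = 1L,
                        adaptation_enabled = (game == "tangram"),
                        assistance_enabled = (game == "tangram"),
                        v0_ups = 2, delta_ups = 2, floor_ups = 2,
                        streak = 3L, assist_slowdown = 0.5,
                        no_immediate_repeat = FALSE,
                        scene = NULL) {
  game <- match.arg(game)
  if (game == "bubble" && (isTRUE(adaptation_enabled) || isTRUE(assistance_enabled))) {
    stop("the bubble game runs without adaptation or assistance", call. = FALSE)
  }
  if (game == "tangram" && (game_number < 1L || game_number > 9L)) {
    stop("game_number must be 1..9", call. = FALSE)
  }
  if (is.null(scene)) scene <- default_scene(game)
  structure(list(game = game, n_prompts = as.integer(n_prompts),
                 n_bubbles = as.integer(n_bubbles),
                 bubble_respawn_ms = as.numeric(bubble_respawn_ms),
                 n_pieces = as.integer(n_pieces),
                 game_number = as.integer(game_number),
                 adaptation_enabled = isTRUE(adaptation_enabled),
                 assistance_enabled = isTRUE(assistance_enabled),
                 v0_ups = as.numeric(v0_ups), delta_ups = as.numeric(delta_ups),
                 floor_ups = as.numeric(floor_ups), streak = as.integer(streak),
                 assist_slowdown = as.numeric(assist_slowdown),
                 no_immediate_repeat = isTRUE(no_immediate_repeat),
                 scene = scene),
            class = "gl_config")
}

#' Prompt level for a tangram game number
#'
#' Games 1-3 use level 1 (head + full eye movement), 4-6 level 2 (full eye
#' movement), 7-9 level 3 (minimal eye movement).
#'
#' @param game_number Integer 1..9.
#' @return Level 1..3.
#' @export
level_schedule <- function(game_number) {
  g <- as.integer(game_number)
  if (any(g < 1L) || any(g > 9L)) stop("game_number must be 1..9", call. = FALSE)
  ((g - 1L) %/% 3L) + 1L
}

#' Start a fresh game session
#'
#' @param config A `gl_config`.
#' @return A list of class `gl_session` holding the FSM state, current phase
#'   (`WaitShare`, `WaitFollow`, `MovePiece`), trial records, score, pending
#'   bubble respawns, controller states and the event log.
#' @export
new_session <- function(config) {
  stopifnot(inherits(config, "gl_config"))
  adapt <- NULL
  if (config$game == "tangram") {
    adapt <- adaptation_state(level = level_schedule(config$game_number),
                              speed_ups = config$v0_ups,
                              floor_ups = config$floor_ups,
                              streak = config$streak,
                              delta_ups = config$delta_ups)
  }
  structure(list(config = config, game = config$game, rois = config$scene,
                 phase = "WaitShare", phase_serial = 1L, fsm = "Initialize",
                 prompt_index = 0L, trial = NULL, trials = list(),
                 score = 0L, pending_cues = 0L,
                 popped_until = stats::setNames(numeric(0), character(0)),
                 placed = character(0), movable = NA_character_,
                 adapt = adapt, assist = assist_state(config$assist_slowdown),
                 last_target = NA_character_,
                 done = FALSE, complete = FALSE, t_end = NA_real_,
                 log = list()),
            class = "gl_session")
}

# append one event-log row
log_row <- function(state, t, event, roi = NA_character_,
                    outcome = NA_character_) {
  tr <- state$trial
  state$log[[length(state$log) + 1L]] <- list(
    t_ms = t, game = state$game, fsm_state = state$fsm, event = event,
    roi = roi,
    prompt_index = if (is.null(tr)) state$prompt_index else tr$index,
    direction = if (is.null(tr)) NA_integer_ else tr$direction,
    level = if (is.null(tr)) NA_integer_ else tr$level,
    speed_ups = if (is.null(tr)) NA_real_ else tr$speed,
    score = state$score, assists = state$assist$attempts, outcome = outcome)
  state
}

#' Session event log as a data frame
#'
#' Columns: `t_ms, game, fsm_state, event, roi, prompt_index, direction,
#' level, speed_ups, score, assists, outcome` — one row per engine event.
#' The log alone suffices to recompute every session metric.
#'
#' @param state A `gl_session`.
#' @return A data frame.
#' @export
session_log <- function(state) {
  if (length(state$log) == 0L) {
    return(data.frame(t_ms = numeric(0), game = character(0),
                      fsm_state = character(0), event = character(0),
                      roi = character(0), prompt_index = integer(0),
                      direction = integer(0), level = integer(0),
                      speed_ups = numeric(0), score = integer(0),
                      assists = integer(0), outcome = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(state$log, function(r) {
    data.frame(r, stringsAsFactors = FALSE)
  }))
}

#' Trial records as a data frame
#'
#' One row per prompt-response cycle with the prompt parameters, outcome,
#' timestamps, derived response time, and assistance / cue counts.
#'
#' @param state A `gl_session`.
#' @return A data frame.
#' @export
session_trials <- function(state) {
  if (length(state$trials) == 0L) {
    return(data.frame(prompt_index = integer(0), target = character(0),
                      direction = integer(0), level = integer(0),
                      speed_ups = numeric(0), outcome = character(0),
                      t_prompt_ms = numeric(0), t_response_ms = numeric(0),
                      response_time_ms = numeric(0), assists_used = integer(0),
                      cues_fired = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(state$trials, function(r) {
    data.frame(r, stringsAsFactors = FALSE)
  }))
}

#' Select the next avatar gaze prompt
#'
#' The gaze direction is drawn uniformly from the currently valid targets:
#' bubbles not waiting to respawn, or tangram pieces not yet placed. Each
#' target maps to one of the eight avatar gaze directions. The level comes
#' from the adaptation controller (tangram, when enabled), the game-number
#' schedule (tangram otherwise), or is pinned at 2 (bubble); the speed from
#' the bubble ramp or the adaptation controller. Randomness uses R's global
#' RNG: seed with `set.seed()` for reproducible direction sequences.
#'
#' @param state A `gl_session`.
#' @param now Current engine time, ms.
#' @return A prompt list (`index`, `direction`, `level`, `speed`, `target`),
#'   or `NULL` if no valid target remains (game complete).
#' @export
select_prompt <- function(state, now) {
  cfg <- state$config
  if (cfg$game == "bubble") {
    all_t <- paste0("bubble_", seq_len(cfg$n_bubbles))
    gone <- names(state$popped_until)[state$popped_until > now]
    avail <- setdiff(all_t, gone)
  } else {
    all_t <- paste0("piece_", seq_len(cfg$n_pieces))
    avail <- setdiff(all_t, state$placed)
  }
  if (cfg$no_immediate_repeat && length(avail) > 1L) {
    avail <- setdiff(avail, state$last_target)
  }
  if (length(avail) == 0L) return(NULL)
  target <- avail[sample.int(length(avail), 1L)]
  direction <- as.integer(sub("^[a-z]+_", "", target))
  index <- state$prompt_index + 1L
  if (cfg$game == "bubble") {
    level <- 2L
    speed <- bubble_speed(index, cfg$v0_ups, cfg$delta_ups, cfg$n_prompts)
  } else if (cfg$adaptation_enabled) {
    level <- state$adapt$level
    speed <- state$adapt$speed_ups
  } else {
    level <- level_schedule(cfg$game_number)
    speed <- cfg$v0_ups
  }
  list(index = index, direction = direction, level = as.integer(level),
       speed = speed, target = target)
}

# start a new trial at a registered gaze share
begin_trial <- function(state, t) {
  prompt <- select_prompt(state, t)
  if (is.null(prompt)) {  # no valid target: game over
    state$done <- TRUE
    state$complete <- TRUE
    state$fsm <- "Initialize"
    state <- log_row(state, t, "session_end")
    return(state)
  }
  state$prompt_index <- prompt$index
  state$last_target <- prompt$target
  state$trial <- list(index = prompt$index, target = prompt$target,
                      direction = prompt$direction, level = prompt$level,
                      speed = prompt$speed, t_prompt = t,
                      cues = state$pending_cues, assists = 0L)
  state$pending_cues <- 0L
  state$assist <- assist_state(state$config$assist_slowdown)
  state$phase <- "WaitFollow"
  state$phase_serial <- state$phase_serial + 1L
  state$fsm <- if (state$game == "bubble") "Avatar Prompt" else "Play Avatar"
  log_row(state, t, "prompt", prompt$target)
}

# close the current trial and append its record
finish_trial <- function(state, t, outcome) {
  tr <- state$trial
  correct <- identical(outcome, "correct")
  state$trials[[length(state$trials) + 1L]] <- list(
    prompt_index = tr$index, target = tr$target, direction = tr$direction,
    level = tr$level, speed_ups = tr$speed, outcome = outcome,
    t_prompt_ms = tr$t_prompt,
    t_response_ms = if (correct) t else NA_real_,
    response_time_ms = if (correct) t - tr$t_prompt else NA_real_,
    assists_used = tr$assists, cues_fired = tr$cues)
  if (correct) state$score <- state$score + 1L
  state <- log_row(state, t, "trial_end", tr$target, outcome)
  state["trial"] <- list(NULL)  # keep the element so $trial stays exact NULL
  state
}

# move to the next trial's share phase, or finish the session
advance_or_finish <- function(state, t, n_total) {
  finished <- if (state$game == "bubble") state$prompt_index >= n_total
              else length(state$placed) >= n_total
  if (finished) {
    state$done <- TRUE
    state$complete <- TRUE
    state$fsm <- "Initialize"
    state$t_end <- t
    state <- log_row(state, t, "session_end")
  } else {
    state$phase <- "WaitShare"
    state$phase_serial <- state$phase_serial + 1L
    state$fsm <- "Initialize"
  }
  state
}

check_event_roi <- function(state, ev) {
  if (ev$kind == "FixationTrigger" && !ev$roi %in% state$rois$name) {
    stop("event references unknown ROI: ", ev$roi, call. = FALSE)
  }
}

#' Advance the bubble-popping game by one event
#'
#' FSM (states Initialize, Avatar Prompt, Bubble Pop; final state
#' Initialize): a registered gaze share in the share phase issues the next
#' prompt; a fixation trigger on the prompted bubble pops it (one point,
#' respawn scheduled 5 s later) and the next trial requires a fresh share; a
#' follow timeout scores nothing and likewise moves on; after the 50th prompt
#' resolves the session completes. Fixations on non-target bubbles change
#' nothing.
#'
#' @param state A `gl_session` configured for the bubble game.
#' @param event A `gl_event`.
#' @return Updated `gl_session`.
#' @export
step_bubble <- function(state, event) {
  stopifnot(state$game == "bubble")
  if (state$done) return(state)
  check_event_roi(state, event)
  t <- event$t
  switch(event$kind,
    FixationTrigger = {
      if (state$phase == "WaitShare" && event$roi == "avatar_eye") {
        state <- log_row(state, t, "share", event$roi)
        state <- begin_trial(state, t)
      } else if (state$phase == "WaitFollow" &&
                 identical(event$roi, state$trial$target)) {
        state$popped_until[event$roi] <- t + state$config$bubble_respawn_ms
        state$fsm <- "Bubble Pop"
        state <- log_row(state, t, "pop", event$roi)
        state <- finish_trial(state, t, "correct")
        state <- advance_or_finish(state, t, state$config$n_prompts)
      } else {
        state <- log_row(state, t, "fixation", event$roi)
      }
      state
    },
    CueAudio = ,
    CueVisual = {
      state$pending_cues <- state$pending_cues + 1L
      log_row(state, t, if (event$kind == "CueAudio") "cue_audio" else "cue_visual")
    },
    FollowTimeout = {
      if (state$phase == "WaitFollow") {
        state <- log_row(state, t, "follow_timeout", state$trial$target)
        state <- finish_trial(state, t, "timeout")
        state <- advance_or_finish(state, t, state$config$n_prompts)
      }
      state
    },
    Terminate = {
      if (!is.null(state$trial)) state <- finish_trial(state, t, "terminated")
      state$done <- TRUE
      state$fsm <- "Initialize"
      state$t_end <- t
      log_row(state, t, "terminate")
    },
    stop("the bubble game accepts no '", event$kind, "' input", call. = FALSE)
  )
}

#' Advance the tangram-puzzle game by one event
#'
#' FSM (states Initialize, Play Avatar, Show Puzzle Color, Enable Puzzle
#' Movement; final state Initialize): a gaze share issues (or, after an
#' eye-contact assist, repeats) the prompt; a fixation trigger on the
#' prompted grey piece restores its colour and enables its movement; a mouse
#' move of the enabled piece to the target completes the trial (movement
#' inputs for any other piece, or while movement is disabled, are rejected
#' unchanged). Follow timeouts escalate the least-to-most ladder: attempt 1
#' returns to the share phase with the eye region highlighted, attempts 2-3
#' repeat the prompt at reduced speed, and past 3 the engine auto-places the
#' piece (outcome `auto_assisted`, no score). The adaptation controller sees
#' `"correct"` per completed piece and `"wrong"` per failed follow attempt.
#' The session completes when all 7 pieces are placed.
#'
#' @param state A `gl_session` configured for the tangram game.
#' @param event A `gl_event` (`MouseMove` carries the piece being moved).
#' @return Updated `gl_session`.
#' @export
step_tangram <- function(state, event) {
  stopifnot(state$game == "tangram")
  if (state$done) return(state)
  check_event_roi(state, event)
  t <- event$t
  switch(event$kind,
    FixationTrigger = {
      if (state$phase == "WaitShare" && event$roi == "avatar_eye") {
        state <- log_row(state, t, "share", event$roi)
        if (is.null(state$trial)) {
          state <- begin_trial(state, t)
        } else {  # resuming after an eye-contact assist: repeat the prompt
          state$phase <- "WaitFollow"
          state$phase_serial <- state$phase_serial + 1L
          state$fsm <- "Play Avatar"
          state <- log_row(state, t, "prompt_repeat", state$trial$target)
        }
      } else if (state$phase == "WaitFollow" &&
                 identical(event$roi, state$trial$target)) {
        state$fsm <- "Show Puzzle Color"
        state <- log_row(state, t, "show_color", event$roi)
        state$movable <- event$roi
        state$fsm <- "Enable Puzzle Movement"
        state$phase <- "MovePiece"
        state$phase_serial <- state$phase_serial + 1L
        state$trial$t_follow <- t
        state <- log_row(state, t, "enable_move", event$roi)
      } else {
        state <- log_row(state, t, "fixation", event$roi)
      }
      state
    },
    CueAudio = ,
    CueVisual = {
      state$pending_cues <- state$pending_cues + 1L
      if (!is.null(state$trial)) {
        state$trial$cues <- state$trial$cues + 1L
        state$pending_cues <- 0L
      }
      log_row(state, t, if (event$kind == "CueAudio") "cue_audio" else "cue_visual")
    },
    MouseMove = {
      if (state$phase == "MovePiece" && identical(event$roi, state$movable)) {
        state$placed <- c(state$placed, event$roi)
        state$movable <- NA_character_
        state <- log_row(state, t, "piece_placed", event$roi)
        state <- finish_trial(state, t, "correct")
        if (state$config$adaptation_enabled) {
          state$adapt <- update_adaptation(state$adapt, "correct")
        }
        state <- advance_or_finish(state, t, state$config$n_pieces)
      }
      state  # movement while disabled: rejected, state unchanged
    },
    FollowTimeout = {
      if (state$phase != "WaitFollow") return(state)
      if (!state$config$assistance_enabled) {
        state <- log_row(state, t, "follow_timeout", state$trial$target)
        state <- finish_trial(state, t, "timeout")
        return(advance_or_finish(state, t, state$config$n_pieces))
      }
      if (state$config$adaptation_enabled) {
        state$adapt <- update_adaptation(state$adapt, "wrong")
      }
      res <- next_assist(state$assist, "follow",
                         state$config$assistance_enabled)
      state$assist <- res$state
      state$trial$assists <- state$assist$attempts
      state <- log_row(state, t, paste0("assist:", paste(res$action, collapse = "+")),
                       state$trial$target)
      if ("auto_move" %in% res$action) {
        state$placed <- c(state$placed, state$trial$target)
        state$movable <- NA_character_
        state <- log_row(state, t, "piece_placed_auto", state$trial$target)
        state <- finish_trial(state, t, "auto_assisted")
        state <- advance_or_finish(state, t, state$config$n_pieces)
      } else if ("highlight_eye" %in% res$action) {
        state$phase <- "WaitShare"
        state$phase_serial <- state$phase_serial + 1L
        state$fsm <- "Initialize"
      } else {  # repeat the gaze prompt at a lower speed
        state$trial$speed <- max(state$config$floor_ups,
                                 state$trial$speed * state$config$assist_slowdown)
        state$phase_serial <- state$phase_serial + 1L
        state$fsm <- "Play Avatar"
        state <- log_row(state, t, "prompt_repeat", state$trial$target)
      }
      state
    },
    Terminate = {
      if (!is.null(state$trial)) state <- finish_trial(state, t, "terminated")
      state$done <- TRUE
      state$fsm <- "Initialize"
      state$t_end <- t
      log_row(state, t, "terminate")
    },
    stop("the tangram game accepts no '", event$kind, "' input", call. = FALSE)
  )
}

#' Advance a session by one event (dispatching on the configured game)
#'
#' @param state A `gl_session`.
#' @param event A `gl_event`.
#' @return Updated `gl_session`.
#' @export
step_session <- function(state, event) {
  if (state$game == "bubble") step_bubble(state, event)
  else step_tangram(state, event)
}

#' @export
print.gl_session <- function(x, ...) {
  cat("<gl_session> ", x$game, " game | fsm: ", x$fsm, " | phase: ", x$phase,
      "\n  prompts issued: ", x$prompt_index, " | score: ", x$score,
      " | trials resolved: ", length(x$trials),
      if (x$done) " | DONE" else "", "\n", sep = "")
  invisible(x)
}
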