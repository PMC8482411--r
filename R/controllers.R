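#' Adaptive-difficulty controller state (tangram game)
#'
#' The rule-based game adaptation controller tracks the avatar's gaze-prompt
#' level (1 = head + full eye movement, 2 = full eye movement, 3 = minimal
#' 40%-range eye movement), the prompt speed in ups (units per second), and
#' the running correct / wrong streaks. The wrong-streak rule is two-staged:
#' the first run of three consecutive wrong attempts lowers the speed, a
#' second run lowers the level; `wrong_stage` remembers which stage applies
#' next.
#'
#' @param level Initial prompt level, 1..3.
#' @param speed_ups Initial prompt speed (default 2 ups).
#' @param floor_ups Minimum speed (default 2 ups, the starting speed).
#' @param streak Streak length triggering a change (default 3).
#' @param delta_ups Speed step per change (default 2 ups).
#' @return A list of class `gl_adapt`.
#' @export
adaptation_state <- function(level = 1L, speed_ups = 2, floor_ups = 2,
                             streak = 3L, delta_ups = 2) {
  level <- as.integer(level)
  if (level < 1L || level > 3L) stop("level must be 1..3", call. = FALSE)
  if (speed_ups < floor_ups) stop("speed_ups below floor", call. = FALSE)
  structure(list(level = level, speed_ups = as.numeric(speed_ups),
                 floor_ups = as.numeric(floor_ups), streak = as.integer(streak),
                 delta_ups = as.numeric(delta_ups),
                 streak_correct = 0L, streak_wrong = 0L,
                 wrong_stage = "none"),
            class = "gl_adapt")
}

#' Apply one trial outcome to the adaptation controller
#'
#' Rules, in the order they fire:
#' \itemize{
#'   \item correct selection: speed increases by `delta_ups` (constant-rate
#'     ramp), the wrong streak and the wrong stage clear;
#'   \item three consecutive correct: prompt level increases (capped at 3)
#'     and the streak restarts;
#'   \item wrong selection: speed unchanged, the correct streak clears;
#'   \item three consecutive wrong, first stage: speed decreases by
#'     `delta_ups` (floored), streak restarts, stage arms;
#'   \item three more consecutive wrong: level decreases (floored at 1),
#'     stage disarms, streak restarts.
#' }
#' A speed decrease therefore always precedes a level decrease within one
#' wrong run.
#'
#' @param state A `gl_adapt`.
#' @param outcome `"correct"` or `"wrong"`.
#' @return Updated `gl_adapt`.
#' @examples
#' s <- adaptation_state(level = 1, speed_ups = 4)
#' update_adaptation(s, "correct")$speed_ups  # 6
#' @export
update_adaptation <- function(state, outcome) {
  if (!outcome %in% c("correct", "wrong")) {
    stop("outcome must be 'correct' or 'wrong'", call. = FALSE)
  }
  if (outcome == "correct") {
    state$speed_ups <- state$speed_ups + state$delta_ups
    state$streak_wrong <- 0L
    state$wrong_stage <- "none"
    state$streak_correct <- state$streak_correct + 1L
    if (state$streak_correct >= state$streak) {
      state$level <- min(3L, state$level + 1L)
      state$streak_correct <- 0L
    }
  } else {
    state$streak_correct <- 0L
    state$streak_wrong <- state$streak_wrong + 1L
    if (state$streak_wrong >= state$streak) {
      if (state$wrong_stage == "none") {
        state$speed_ups <- max(state$floor_ups, state$speed_ups - state$delta_ups)
        state$wrong_stage <- "speed_reduced"
      } else {
        state$level <- max(1L, state$level - 1L)
        state$wrong_stage <- "none"
      }
      state$streak_wrong <- 0L
    }
  }
  state
}

#' Bubble-game prompt speed schedule
#'
#' In the bubble game the prompt speed rises at a constant rate on every
#' prompt regardless of performance: `v0 + delta * (prompt_index - 1)`,
#' default 2 + 2(k-1) ups, i.e. 2 ups on the first prompt up to 100 ups on
#' the fiftieth.
#'
#' @param prompt_index 1-based prompt number, 1..`n_prompts`.
#' @param v0 Starting speed (ups).
#' @param delta Per-prompt increment (ups).
#' @param n_prompts Session length (default 50).
#' @return Speed in ups.
#' @export
bubble_speed <- function(prompt_index, v0 = 2, delta = 2, n_prompts = 50L) {
  k <- as.integer(prompt_index)
  if (any(is.na(k)) || any(k < 1L) || any(k > n_prompts)) {
    stop("prompt_index out of range 1..", n_prompts, call. = FALSE)
  }
  v0 + delta * (k - 1)
}

#' Least-to-most assistance state (tangram game)
#'
#' @param slowdown Factor applied to the prompt speed when the avatar repeats
#'   a gaze prompt "at a lower speed" (default 0.5, floored at the speed
#'   floor).
#' @return A list of class `gl_assist`.
#' @export
assist_state <- function(slowdown = 0.5) {
  structure(list(attempts = 0L, slowdown = as.numeric(slowdown),
                 actions_issued = list()),
            class = "gl_assist")
}

# the LTM ladder: action set for a given attempt count
assist_actions_for <- function(attempts) {
  if (attempts <= 0L) c("highlight_eye")
  else if (attempts == 1L) c("highlight_eye", "sound_cue")
  else if (attempts == 2L) c("repeat_slow")
  else if (attempts == 3L) c("repeat_slow", "highlight_object", "rotate_object")
  else c("auto_move")
}

#' Escalate the least-to-most prompting ladder by one failed attempt
#'
#' Called when a share or follow timeout occurs in the tangram game. The
#' attempt counter increments and the action set for the new count is
#' returned, in the fixed ladder order: 1 = highlight the avatar's eye region
#' plus a sound cue (re-establish eye contact); 2 = the avatar repeats the
#' gaze prompt at a lower speed; 3 = repeat at lower speed plus highlighting
#' and rotating the target object in place; beyond 3 = the avatar moves the
#' object to the target itself (full assistance).
#'
#' @param state A `gl_assist`.
#' @param phase `"share"` or `"follow"` (recorded with the action).
#' @param enabled Must be `TRUE`; the bubble game never assists.
#' @return `list(state = <updated>, action = <character vector of actions>)`.
#' @examples
#' a <- assist_state()
#' next_assist(a, "follow")$action  # highlight_eye + sound_cue
#' @export
next_assist <- function(state, phase = c("follow", "share"), enabled = TRUE) {
  phase <- match.arg(phase)
  if (!isTRUE(enabled)) {
    stop("assistance requested but assistance_enabled is FALSE", call. = FALSE)
  }
  state$attempts <- state$attempts + 1L
  action <- assist_actions_for(state$attempts)
  state$actions_issued <- c(state$actions_issued,
                            list(list(attempt = state$attempts, phase = phase,
                                      action = action)))
  list(state = state, action = action)
}
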