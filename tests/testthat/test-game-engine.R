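# drive the engines directly with scripted events (no simulator)

share_then_target <- function(state, t_share, dt_follow = 500) {
  state <- step_session(state, gaze_event(t_share, "FixationTrigger",
                                          "avatar_eye"))
  target <- state$trial$target
  step_session(state, gaze_event(t_share + dt_follow, "FixationTrigger",
                                 target))
}

test_that("a correct bubble follow scores one point and pops the bubble", {
  set.seed(1)
  st <- new_session(game_config("bubble"))
  st <- step_bubble(st, gaze_event(1000, "FixationTrigger", "avatar_eye"))
  expect_equal(st$phase, "WaitFollow")
  expect_equal(st$fsm, "Avatar Prompt")
  expect_equal(st$trial$level, 2L)
  target <- st$trial$target
  # fixating a different bubble does nothing
  other <- setdiff(paste0("bubble_", 1:8), target)[1]
  st <- step_bubble(st, gaze_event(1200, "FixationTrigger", other))
  expect_equal(st$score, 0L)
  expect_equal(st$phase, "WaitFollow")
  st <- step_bubble(st, gaze_event(1500, "FixationTrigger", target))
  expect_equal(st$score, 1L)
  expect_equal(unname(st$popped_until[target]), 1500 + 5000)
  expect_equal(st$phase, "WaitShare")  # fresh share needed for prompt 2
  tr <- session_trials(st)
  expect_equal(tr$outcome, "correct")
  expect_equal(tr$response_time_ms, 500)
})

test_that("a popped bubble is out of the target pool for exactly 5 s", {
  set.seed(2)
  st <- new_session(game_config("bubble"))
  st <- share_then_target(st, 1000)
  popped <- session_trials(st)$target
  for (rep in 1:40) {
    p <- select_prompt(st, now = 3000)   # 1.5 s after the pop
    expect_false(p$target == popped)
  }
  seen <- replicate(100, select_prompt(st, now = 1500 + 5000)$target)
  expect_true(popped %in% seen)          # back at exactly +5000 ms
})

test_that("a follow timeout scores nothing and the session runs to 50 prompts", {
  set.seed(3)
  st <- new_session(game_config("bubble"))
  t <- 0
  for (k in 1:50) {
    t <- t + 1000
    st <- step_bubble(st, gaze_event(t, "FixationTrigger", "avatar_eye"))
    expect_equal(st$trial$speed, 2 + 2 * (k - 1))  # constant-rate ramp
    if (k %% 2 == 0) {
      st <- step_bubble(st, gaze_event(t + 30000, "FollowTimeout"))
      t <- t + 30000
    } else {
      target <- st$trial$target
      st <- step_bubble(st, gaze_event(t + 400, "FixationTrigger", target))
      t <- t + 400
    }
  }
  expect_true(st$done && st$complete)
  expect_equal(st$fsm, "Initialize")     # final FSM state
  expect_equal(st$score, 25L)
  tr <- session_trials(st)
  expect_equal(nrow(tr), 50L)
  expect_equal(sum(tr$outcome == "timeout"), 25L)
  expect_true(all(tr$level == 2L))
  expect_true(all(is.na(tr$response_time_ms[tr$outcome == "timeout"])))
})

test_that("prompt direction sequences are reproducible under a fixed seed", {
  run <- function(seed) {
    set.seed(seed)
    st <- new_session(game_config("bubble"))
    t <- 0
    dirs <- integer(0)
    for (k in 1:20) {
      t <- t + 1000
      st <- step_bubble(st, gaze_event(t, "FixationTrigger", "avatar_eye"))
      dirs <- c(dirs, st$trial$direction)
      st <- step_bubble(st, gaze_event(t + 100, "FollowTimeout"))
    }
    dirs
  }
  expect_identical(run(1234), run(1234))
  expect_false(identical(run(1234), run(4321)))
})

test_that("tangram: correct follow colours the piece, then movement completes it", {
  set.seed(4)
  st <- new_session(game_config("tangram"))
  st <- step_tangram(st, gaze_event(1000, "FixationTrigger", "avatar_eye"))
  target <- st$trial$target
  expect_equal(st$trial$level, 1L)       # game number 1 -> level 1
  expect_equal(st$trial$speed, 2)
  # moving before movement is enabled is rejected, state unchanged
  before <- st
  st <- step_tangram(st, gaze_event(1100, "MouseMove", target))
  expect_identical(st$placed, before$placed)
  st <- step_tangram(st, gaze_event(1500, "FixationTrigger", target))
  expect_equal(st$fsm, "Enable Puzzle Movement")
  expect_equal(st$movable, target)
  st <- step_tangram(st, gaze_event(2200, "MouseMove", target))
  expect_equal(st$placed, target)
  expect_equal(st$score, 1L)
  expect_equal(st$adapt$speed_ups, 4)    # +2 ups after a correct selection
})

test_that("tangram: 7 placements complete the game and pieces never repeat", {
  set.seed(5)
  st <- new_session(game_config("tangram"))
  t <- 0
  targets <- character(0)
  while (!st$done) {
    t <- t + 1000
    st <- step_tangram(st, gaze_event(t, "FixationTrigger", "avatar_eye"))
    targets <- c(targets, st$trial$target)
    st <- step_tangram(st, gaze_event(t + 300, "FixationTrigger",
                                      st$trial$target))
    st <- step_tangram(st, gaze_event(t + 800, "MouseMove", st$movable))
    t <- t + 800
  }
  expect_equal(length(targets), 7L)
  expect_false(anyDuplicated(targets) > 0)
  expect_equal(st$score, 7L)
  expect_true(st$complete)
  expect_equal(st$fsm, "Initialize")
})

test_that("tangram assist ladder escalates per failed follow and auto-places", {
  set.seed(6)
  st <- new_session(game_config("tangram"))
  st <- step_tangram(st, gaze_event(1000, "FixationTrigger", "avatar_eye"))
  target <- st$trial$target
  v0 <- st$trial$speed
  # attempt 1: highlight eye + sound, back to the share phase
  st <- step_tangram(st, gaze_event(31000, "FollowTimeout"))
  expect_equal(st$phase, "WaitShare")
  expect_equal(st$assist$attempts, 1L)
  st <- step_tangram(st, gaze_event(32000, "FixationTrigger", "avatar_eye"))
  expect_equal(st$phase, "WaitFollow")
  expect_equal(st$trial$target, target)  # same prompt repeated
  # attempt 2: repeat at lower speed, stays in the follow phase
  st <- step_tangram(st, gaze_event(62000, "FollowTimeout"))
  expect_equal(st$phase, "WaitFollow")
  expect_equal(st$trial$speed, max(2, v0 / 2))
  # attempt 3: repeat + highlight + rotate
  st <- step_tangram(st, gaze_event(92000, "FollowTimeout"))
  expect_equal(st$assist$attempts, 3L)
  # attempt 4: auto-placement, no score credit
  st <- step_tangram(st, gaze_event(122000, "FollowTimeout"))
  expect_equal(st$placed, target)
  expect_equal(st$score, 0L)
  tr <- session_trials(st)
  expect_equal(tr$outcome, "auto_assisted")
  expect_equal(tr$assists_used, 4L)
  ladder <- grep("^assist:", vapply(st$log, `[[`, "", "event"), value = TRUE)
  expect_equal(ladder,
               c("assist:highlight_eye+sound_cue",
                 "assist:repeat_slow",
                 "assist:repeat_slow+highlight_object+rotate_object",
                 "assist:auto_move"))
})

test_that("invalid inputs are hard errors; random event fuzz stays in the state set", {
  set.seed(7)
  st <- new_session(game_config("bubble"))
  expect_error(step_bubble(st, gaze_event(10, "FixationTrigger", "nowhere")),
               "unknown ROI")
  expect_error(step_bubble(st, gaze_event(10, "MouseMove", "bubble_1")),
               "no 'MouseMove' input")
  bubble_states <- c("Initialize", "Avatar Prompt", "Bubble Pop")
  tangram_states <- c("Initialize", "Play Avatar", "Show Puzzle Color",
                      "Enable Puzzle Movement")
  for (game in c("bubble", "tangram")) {
    st <- new_session(game_config(game))
    rois <- st$rois$name
    t <- 0
    closed <- TRUE
    conserved <- TRUE
    for (i in 1:400) {
      if (st$done) break
      t <- t + sample(50:2000, 1)
      kind <- sample(c("FixationTrigger", "FollowTimeout", "CueAudio",
                       if (game == "tangram") "MouseMove"), 1)
      ev <- if (kind %in% c("FixationTrigger", "MouseMove")) {
        gaze_event(t, kind, sample(rois, 1))
      } else gaze_event(t, kind)
      if (kind == "FollowTimeout" && st$phase != "WaitFollow") next
      st <- step_session(st, ev)
      closed <- closed && st$fsm %in% (if (game == "bubble") bubble_states
                                       else tangram_states)
      conserved <- conserved &&
        st$score == sum(session_trials(st)$outcome == "correct")
    }
    expect_true(closed, info = paste(game, "FSM escaped its state set"))
    expect_true(conserved, info = paste(game, "score conservation"))
  }
})
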