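scene <- default_scene("bubble")
eye <- c(960, 300)

test_that("hit-testing uses half-open rectangles in declaration order", {
  expect_equal(hit_test(list(t = 0, x = eye[1], y = eye[2], valid = TRUE),
                        scene), "avatar_eye")
  expect_true(is.na(hit_test(list(t = 0, x = 5, y = 5, valid = TRUE), scene)))
  # right/bottom edges excluded, left/top edges included
  r <- roi_set(roi("avatar_eye", "avatar_eye", 0, 0, 100, 100))
  expect_true(is.na(hit_test(list(t = 0, x = 100, y = 50, valid = TRUE), r)))
  expect_true(is.na(hit_test(list(t = 0, x = 50, y = 100, valid = TRUE), r)))
  expect_equal(hit_test(list(t = 0, x = 0, y = 0, valid = TRUE), r),
               "avatar_eye")
  # invalid samples never hit
  expect_true(is.na(hit_test(list(t = 0, x = eye[1], y = eye[2],
                                  valid = FALSE), scene)))
  # overlapping rectangles resolve to the first declared, eye first
  ov <- roi_set(roi("box", "game_object", 0, 0, 100, 100),
                roi("avatar_eye", "avatar_eye", 50, 50, 150, 150))
  expect_equal(hit_test(list(t = 0, x = 75, y = 75, valid = TRUE), ov),
               "avatar_eye")
})

test_that("ROI construction rejects degenerate or ill-formed scenes", {
  expect_error(roi("bad", "game_object", 10, 10, 10, 50), "degenerate")
  expect_error(roi("f", "facial_feature", 0, 0, 1, 1, active = TRUE),
               "passive")
  expect_error(roi_set(roi("a", "game_object", 0, 0, 1, 1)), "avatar_eye")
})

test_that("a 200 ms dwell fires exactly one trigger per episode", {
  st <- make_stream(list(list(ms = 240, x = eye[1], y = eye[2])), hz = 50)
  res <- feed_stream(st, scene)
  expect_length(res$events, 1L)
  ev <- res$events[[1]]
  expect_equal(ev$kind, "FixationTrigger")
  expect_equal(ev$roi, "avatar_eye")
  expect_equal(ev$t, 200)  # first sample at which accumulated dwell >= 200
})

test_that("leaving the ROI before 200 ms resets the dwell", {
  st <- make_stream(list(list(ms = 160, x = eye[1], y = eye[2]),
                         list(ms = 200, x = 5, y = 5),
                         list(ms = 160, x = eye[1], y = eye[2])), hz = 50)
  res <- feed_stream(st, scene)
  expect_length(res$events, 0L)
})

test_that("blink gaps within tolerance bridge a dwell; longer gaps reset", {
  # 180 ms in, 60 ms blink, 100 ms in: fires during the second run
  st <- make_stream(list(list(ms = 180, x = eye[1], y = eye[2]),
                         list(ms = 60, valid = FALSE),
                         list(ms = 100, x = eye[1], y = eye[2])), hz = 50)
  res <- feed_stream(st, scene)
  expect_length(res$events, 1L)
  expect_gt(res$events[[1]]$t, 240)  # inside the second run
  # same stream but a 120 ms gap (> 75 ms tolerance): episode resets
  st2 <- make_stream(list(list(ms = 180, x = eye[1], y = eye[2]),
                          list(ms = 120, valid = FALSE),
                          list(ms = 100, x = eye[1], y = eye[2])), hz = 50)
  expect_length(feed_stream(st2, scene)$events, 0L)
})

test_that("out-of-order samples are a hard error naming the sample", {
  s <- dwell_state()
  s <- update_dwell(s, list(t = 100, x = 1, y = 1, valid = TRUE), scene)$state
  expect_error(update_dwell(s, list(t = 60, x = 1, y = 1, valid = TRUE),
                            scene),
               "out-of-order.*60")
})

test_that("phase cues and timeouts follow the 30 s / 120 s rules", {
  s <- dwell_state()
  s$phase_clock_ms <- 30000
  ev_t <- check_timeouts(s, "WaitShare", "tangram", now = 30000)
  expect_equal(vapply(ev_t, `[[`, "", "kind"), c("CueAudio", "CueVisual"))
  ev_b <- check_timeouts(s, "WaitShare", "bubble", now = 30000)
  expect_equal(vapply(ev_b, `[[`, "", "kind"), "CueAudio")
  # the cue fires once per phase
  s$cue_fired <- TRUE
  expect_length(check_timeouts(s, "WaitShare", "bubble", now = 31000), 0L)
  # follow timeout
  s2 <- dwell_state()
  s2$phase_clock_ms <- 30000
  expect_equal(check_timeouts(s2, "WaitFollow", "bubble",
                              now = 60000)[[1]]$kind, "FollowTimeout")
  # termination preempts everything
  s3 <- dwell_state()
  s3$phase_clock_ms <- 31000
  s3$interaction_clock_ms <- 120000
  ev <- check_timeouts(s3, "WaitShare", "tangram", now = 120000)
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$kind, "Terminate")
  expect_error(check_timeouts(s3, "Elsewhere", "bubble", 0), "phase")
})

test_that("dwell timing is robust to resampling the same gaze path", {
  path <- list(list(ms = 400, x = eye[1], y = eye[2]),
               list(ms = 100, x = 5, y = 5),
               list(ms = 300, x = 960, y = 780))  # bubble_3 region
  for (pair in list(c(50, 100), c(55, 110))) {
    e1 <- feed_stream(make_stream(path, hz = pair[1]), scene)$events
    e2 <- feed_stream(make_stream(path, hz = pair[2]), scene)$events
    expect_equal(length(e1), length(e2))
    for (k in seq_along(e1)) {
      expect_equal(e1[[k]]$roi, e2[[k]]$roi)
      expect_lte(abs(e1[[k]]$t - e2[[k]]$t), 1000 / pair[1] + 1)
    }
  }
})

test_that("replay of an identical stream is deterministic", {
  set.seed(11)
  st <- random_burst_stream(n_bursts = 6)
  e1 <- feed_stream(st, scene)$events
  e2 <- feed_stream(st, scene)$events
  expect_identical(e1, e2)
})

test_that("streamed dwell events match the from-scratch reference", {
  set.seed(7)
  for (rep in 1:40) {
    st <- random_burst_stream(n_bursts = sample(2:6, 1),
                              jitter = runif(1, 2, 14),
                              p_invalid = runif(1, 0, 0.08))
    got <- feed_stream(st, scene)$events
    want <- oracle_dwell_events(st, scene)
    expect_equal(length(got), length(want),
                 info = sprintf("stream %d: event count", rep))
    for (k in seq_along(want)) {
      expect_equal(got[[k]]$t, want[[k]]$t)
      expect_equal(got[[k]]$roi, want[[k]]$roi)
    }
  }
})
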