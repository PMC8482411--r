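# Constructed gaze streams for runtime and fixation tests.
#
# make_stream() builds a sample table from piecewise segments; each segment
# holds a position (or invalid samples) for a duration. Samples are spaced
# 1000/hz ms apart, timestamps rounded to integer ms as the logger would.

make_stream <- function(segments, hz = 50, t0 = 0) {
  dt <- 1000 / hz
  rows <- list()
  k <- 0L
  t_cursor <- t0
  for (seg in segments) {
    n <- round(seg$ms / dt)
    for (i in seq_len(n)) {
      k <- k + 1L
      valid <- if (is.null(seg$valid)) TRUE else seg$valid
      rows[[k]] <- data.frame(
        t_ms = round(t_cursor + (i - 1) * dt),
        x_px = if (valid) seg$x else NA_real_,
        y_px = if (valid) seg$y else NA_real_,
        valid = valid)
    }
    t_cursor <- t_cursor + n * dt
  }
  do.call(rbind, rows)
}

# feed a stream through the exported functional dwell API
feed_stream <- function(stream, rois, params = gaze_params(),
                        state = dwell_state(t0 = stream$t_ms[1] - 20)) {
  events <- list()
  for (i in seq_len(nrow(stream))) {
    res <- update_dwell(state,
                        list(t = stream$t_ms[i], x = stream$x_px[i],
                             y = stream$y_px[i], valid = stream$valid[i]),
                        rois, params)
    state <- res$state
    events <- c(events, res$events)
  }
  list(events = events, state = state)
}

# random jittered multi-burst stream for oracle comparisons
random_burst_stream <- function(n_bursts = 4, hz = 50, jitter = 6,
                                p_invalid = 0.03,
                                width = 1920, height = 1080) {
  segs <- list()
  for (b in seq_len(n_bursts)) {
    cx <- runif(1, 100, width - 100)
    cy <- runif(1, 100, height - 100)
    segs[[length(segs) + 1L]] <- list(ms = runif(1, 120, 600), x = cx, y = cy)
    if (runif(1) < 0.5) {
      segs[[length(segs) + 1L]] <- list(ms = runif(1, 20, 60), valid = FALSE)
    }
  }
  st <- make_stream(segs, hz = hz)
  j <- st$valid
  st$x_px[j] <- st$x_px[j] + rnorm(sum(j), 0, jitter)
  st$y_px[j] <- st$y_px[j] + rnorm(sum(j), 0, jitter)
  drop <- runif(nrow(st)) < p_invalid
  st$valid[drop] <- FALSE
  st$x_px[drop] <- NA_real_
  st$y_px[drop] <- NA_real_
  st
}
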