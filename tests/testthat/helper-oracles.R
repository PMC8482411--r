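# Independent brute-force references. Each recomputes its quantity from
# scratch rather than incrementally, so agreement with the package is a
# meaningful cross-check, not a tautology.

# --- dwell-event reference -------------------------------------------------
# For every sample, walks backwards to find the start of the current dwell
# episode (crossing invalid runs no longer than the gap tolerance) and
# recomputes the accumulated in-ROI time of the whole episode from scratch
# (O(n^2) overall). Emits one trigger per episode at the first sample whose
# recomputed dwell reaches the threshold, active ROIs only.
oracle_dwell_events <- function(stream, rois, params = gaze_params()) {
  n <- nrow(stream)
  t <- stream$t_ms
  valid <- as.logical(stream$valid)
  roi_of <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (valid[i]) {
      roi_of[i] <- hit_test(list(t = t[i], x = stream$x_px[i],
                                 y = stream$y_px[i], valid = TRUE), rois)
    }
  }
  active <- stats::setNames(rois$active, rois$name)

  episode_start <- function(i) {
    r <- roi_of[i]
    j <- i
    repeat {
      k <- j - 1L
      if (k < 1L) return(j)
      if (valid[k] && identical(roi_of[k], r)) { j <- k; next }
      if (!valid[k]) {
        m <- k
        while (m > 1L && !valid[m - 1L]) m <- m - 1L
        if (m > 1L && valid[m - 1L] && identical(roi_of[m - 1L], r) &&
            (t[k] - t[m - 1L]) <= params$gap_tol_ms) {
          j <- m - 1L
          next
        }
      }
      return(j)
    }
  }
  dwell_at <- function(i, j) {
    if (i == j) return(0)
    r <- roi_of[i]
    d <- 0
    for (l in seq(j + 1L, i)) {
      if (l > j && valid[l] && identical(roi_of[l], r)) {
        d <- d + (t[l] - t[l - 1L])
      }
    }
    d
  }

  events <- list()
  for (i in seq_len(n)) {
    if (!valid[i] || is.na(roi_of[i])) next
    j <- episode_start(i)
    if (dwell_at(i, j) < params$theta_fix_ms) next
    fired_before <- FALSE
    if (i > j) {
      for (l in seq(j, i - 1L)) {
        if (valid[l] && identical(roi_of[l], roi_of[i]) &&
            episode_start(l) == j &&
            dwell_at(l, j) >= params$theta_fix_ms) {
          fired_before <- TRUE
          break
        }
      }
    }
    if (!fired_before && isTRUE(active[[roi_of[i]]])) {
      events[[length(events) + 1L]] <- list(t = t[i], roi = roi_of[i])
    }
  }
  events
}

# --- fixation-detection reference -----------------------------------------
# Sequential dispersion clustering with the cluster mean recomputed from all
# members at every step, explicit outlier pass, and duration filter.
oracle_fixations <- function(stream, params = fixation_params()) {
  if (!is.null(stream$valid)) stream <- stream[as.logical(stream$valid), ]
  ok <- is.finite(stream$x_px) & is.finite(stream$y_px)
  x <- stream$x_px[ok]; y <- stream$y_px[ok]; t <- stream$t_ms[ok]
  t1_px <- tan(params$t1_deg * pi / 180) * params$distance_cm *
    params$screen_w_px / params$screen_w_cm
  n <- length(x)
  clusters <- list()
  finalize <- function(idx) {
    cx <- mean(x[idx]); cy <- mean(y[idx])
    d <- sqrt((x[idx] - cx)^2 + (y[idx] - cy)^2)
    if (length(idx) > 1L) {
      t2 <- if (params$t2_mode == "fixed") params$t2_px
            else params$t2_sd_mult * stats::sd(d)
      if (is.finite(t2) && t2 > 0) {
        keep <- d <= t2
        if (any(keep) && any(!keep)) idx <- idx[keep]
      }
    }
    if (max(t[idx]) - min(t[idx]) < params$min_duration_ms) return(NULL)
    list(x = mean(x[idx]), y = mean(y[idx]),
         onset = min(t[idx]), offset = max(t[idx]), n = length(idx))
  }
  cur <- integer(0)
  for (i in seq_len(n)) {
    if (length(cur) == 0L) {
      cur <- i
    } else if (sqrt((x[i] - mean(x[cur]))^2 + (y[i] - mean(y[cur]))^2) <= t1_px) {
      cur <- c(cur, i)
    } else {
      cl <- finalize(cur)
      if (!is.null(cl)) clusters[[length(clusters) + 1L]] <- cl
      cur <- i
    }
  }
  if (length(cur)) {
    cl <- finalize(cur)
    if (!is.null(cl)) clusters[[length(clusters) + 1L]] <- cl
  }
  clusters
}

# --- adaptation-rule reference --------------------------------------------
# Literal transcription of the difficulty rules with its own counters:
# correct -> +2 ups and count correct run (3 in a row -> level up);
# wrong -> count wrong run (first triple -> -2 ups, second -> level down).
oracle_adaptation_replay <- function(outcomes, level0 = 1, speed0 = 2,
                                     floor = 2) {
  level <- level0; speed <- speed0
  run_c <- 0; run_w <- 0; speed_was_reduced <- FALSE
  trace <- vector("list", length(outcomes))
  for (i in seq_along(outcomes)) {
    if (outcomes[i] == "correct") {
      speed <- speed + 2
      run_w <- 0
      speed_was_reduced <- FALSE
      run_c <- run_c + 1
      if (run_c == 3) {
        if (level < 3) level <- level + 1
        run_c <- 0
      }
    } else {
      run_c <- 0
      run_w <- run_w + 1
      if (run_w == 3) {
        if (!speed_was_reduced) {
          speed <- max(floor, speed - 2)
          speed_was_reduced <- TRUE
        } else {
          if (level > 1) level <- level - 1
          speed_was_reduced <- FALSE
        }
        run_w <- 0
      }
    }
    trace[[i]] <- list(level = level, speed = speed)
  }
  trace
}
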