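#' Parameters for two-threshold dispersion fixation detection
#'
#' The offline detector uses two spatial parameters and one temporal
#' parameter: `t1` opens and grows a fixation cluster (a sample joins while
#' it stays within `t1` of the running centroid), `t2` cleans a closed
#' cluster by removing member samples farther than `t2` from the centroid,
#' and clusters shorter than `min_duration_ms` are discarded. `t1` is given
#' in degrees of visual angle and converted to pixels from the screen
#' geometry; `t2` is by default derived per cluster from the spread of its
#' members (`t2_sd_mult` times the SD of member-to-centroid distances).
#'
#' @param t1_deg First spatial threshold, degrees of visual angle
#'   (default 1).
#' @param t2_mode `"auto_sd"` (default) or `"fixed"`.
#' @param t2_px Fixed second threshold in pixels (required when
#'   `t2_mode = "fixed"`).
#' @param t2_sd_mult Multiplier on the member-distance SD in `auto_sd` mode
#'   (default 3, the conventional outlier cut).
#' @param min_duration_ms Minimum fixation duration (default 200 ms).
#' @param distance_cm Viewing distance (default 60 cm).
#' @param screen_w_cm,screen_w_px Physical and pixel screen width used for
#'   the degree-to-pixel conversion (defaults: a 24-inch 16:9 panel at
#'   1920 px).
#' @return A list of class `gl_fix_params`.
#' @export
fixation_params <- function(t1_deg = 1, t2_mode = c("auto_sd", "fixed"),
                            t2_px = NULL, t2_sd_mult = 3,
                            min_duration_ms = 200,
                            distance_cm = 60, screen_w_cm = 53.1,
                            screen_w_px = 1920) {
  t2_mode <- match.arg(t2_mode)
  if (t1_deg <= 0) stop("t1_deg must be > 0", call. = FALSE)
  if (min_duration_ms <= 0) stop("min_duration_ms must be > 0", call. = FALSE)
  if (distance_cm <= 0 || screen_w_cm <= 0 || screen_w_px <= 0) {
    stop("screen geometry fields must be positive", call. = FALSE)
  }
  if (t2_mode == "fixed" && (is.null(t2_px) || t2_px <= 0)) {
    stop("t2_mode = 'fixed' requires a positive t2_px", call. = FALSE)
  }
  structure(list(t1_deg = t1_deg, t2_mode = t2_mode, t2_px = t2_px,
                 t2_sd_mult = t2_sd_mult, min_duration_ms = min_duration_ms,
                 distance_cm = distance_cm, screen_w_cm = screen_w_cm,
                 screen_w_px = screen_w_px),
            class = "gl_fix_params")
}

#' Convert degrees of visual angle to screen pixels
#'
#' `px = tan(theta) * distance_cm * (px per cm)`; at the default geometry
#' 1 degree is roughly 38 px.
#'
#' @param deg Angle in degrees.
#' @param params A `gl_fix_params` carrying the geometry.
#' @return Length in pixels.
#' @export
deg_to_px <- function(deg, params = fixation_params()) {
  tan(deg * pi / 180) * params$distance_cm *
    (params$screen_w_px / params$screen_w_cm)
}

# close one raw cluster: outlier removal + recompute, or NULL if too short
close_cluster <- function(tx, ty, tt, params, t1_px) {
  cx <- mean(tx); cy <- mean(ty)
  d <- sqrt((tx - cx)^2 + (ty - cy)^2)
  t2 <- if (params$t2_mode == "fixed") params$t2_px
        else params$t2_sd_mult * stats::sd(d)
  removed <- 0L
  if (length(tx) > 1L && is.finite(t2) && t2 > 0) {
    keep <- d <= t2
    removed <- sum(!keep)
    if (removed > 0L && any(keep)) {
      tx <- tx[keep]; ty <- ty[keep]; tt <- tt[keep]
      cx <- mean(tx); cy <- mean(ty)
    }
  }
  dur <- max(tt) - min(tt)
  if (dur < params$min_duration_ms) return(NULL)
  list(x = cx, y = cy, onset_ms = min(tt), offset_ms = max(tt),
       duration_ms = dur, n_samples = length(tt),
       n_removed_outliers = removed)
}

#' Detect fixations in a gaze stream by sequential dispersion clustering
#'
#' Valid samples are scanned in time order. A sample joins the running
#' cluster while its distance to the running centroid (incremental mean of
#' members so far) is at most `t1`; otherwise the cluster closes — members
#' farther than `t2` from the closed cluster's centroid are removed and the
#' centroid recomputed — and a new cluster starts at the current sample.
#' Removed outliers are discarded entirely. Closed clusters shorter than the
#' minimum duration are dropped.
#'
#' @param samples Data frame with columns `t_ms`, `x_px`, `y_px` and
#'   optionally `valid` (invalid rows are excluded).
#' @param params A `gl_fix_params`.
#' @return A data frame of class `gl_fixations` with columns `onset_ms`,
#'   `offset_ms`, `duration_ms`, `x_px`, `y_px`, `n_samples`,
#'   `n_removed_outliers`.
#' @export
detect_fixations <- function(samples, params = fixation_params()) {
  if (!is.null(samples$valid)) samples <- samples[as.logical(samples$valid), ]
  x <- samples$x_px; y <- samples$y_px; t <- samples$t_ms
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]; t <- t[keep]
  if (is.unsorted(t)) stop("gaze samples must be time-ordered", call. = FALSE)
  t1_px <- deg_to_px(params$t1_deg, params)
  out <- list()
  n <- length(x)
  if (n > 0L) {
    cs_x <- x[1L]; cs_y <- y[1L]; cn <- 1L; c0 <- 1L
    for (i in seq_len(n)[-1L]) {
      cx <- cs_x / cn; cy <- cs_y / cn
      if (sqrt((x[i] - cx)^2 + (y[i] - cy)^2) <= t1_px) {
        cs_x <- cs_x + x[i]; cs_y <- cs_y + y[i]; cn <- cn + 1L
      } else {
        cl <- close_cluster(x[c0:(i - 1L)], y[c0:(i - 1L)], t[c0:(i - 1L)],
                            params, t1_px)
        if (!is.null(cl)) out[[length(out) + 1L]] <- cl
        cs_x <- x[i]; cs_y <- y[i]; cn <- 1L; c0 <- i
      }
    }
    cl <- close_cluster(x[c0:n], y[c0:n], t[c0:n], params, t1_px)
    if (!is.null(cl)) out[[length(out) + 1L]] <- cl
  }
  if (length(out) == 0L) {
    res <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      duration_ms = numeric(0), x_px = numeric(0),
                      y_px = numeric(0), n_samples = integer(0),
                      n_removed_outliers = integer(0))
  } else {
    res <- do.call(rbind, lapply(out, function(cl) {
      data.frame(onset_ms = cl$onset_ms, offset_ms = cl$offset_ms,
                 duration_ms = cl$duration_ms, x_px = cl$x, y_px = cl$y,
                 n_samples = cl$n_samples,
                 n_removed_outliers = cl$n_removed_outliers)
    }))
  }
  class(res) <- c("gl_fixations", "data.frame")
  res
}

#' Assign fixations to ROIs and summarize the eye / other-face split
#'
#' Each fixation is assigned by hit-testing its centroid against the ROI
#' set; fixations landing on no ROI count as off-face. Returns per-ROI
#' counts plus the grouping used for joint-attention analysis: fixations on
#' the avatar's eye region versus the other facial features, with normalized
#' ratios `eye / (eye + other)` and `other / (eye + other)` (reported as
#' `NA` when no face fixation exists).
#'
#' @param clusters A `gl_fixations` data frame (or any frame with `x_px`,
#'   `y_px`).
#' @param rois A `gl_roi_set` containing the avatar-eye and facial ROIs.
#' @return A list of class `gl_fix_summary`: `clusters` (with an added `roi`
#'   column), `per_roi` counts, `total_face`, `eye`, `other_facial`,
#'   `off_face`, `ratio_eye`, `ratio_other`.
#' @export
assign_fixations <- function(clusters, rois) {
  n <- nrow(clusters)
  assigned <- character(n)
  for (i in seq_len(n)) {
    assigned[i] <- hit_test(list(t = 0, x = clusters$x_px[i],
                                 y = clusters$y_px[i], valid = TRUE), rois)
  }
  clusters$roi <- assigned
  kind <- rois$kind[match(assigned, rois$name)]
  eye <- sum(!is.na(kind) & kind == "avatar_eye")
  other <- sum(!is.na(kind) & kind == "facial_feature")
  face <- eye + other
  per_roi <- table(factor(assigned, levels = rois$name))
  structure(list(clusters = clusters,
                 per_roi = as.data.frame(per_roi,
                                         responseName = "n_fixations",
                                         stringsAsFactors = FALSE),
                 total_face = face, eye = eye, other_facial = other,
                 off_face = n - face,
                 ratio_eye = if (face > 0) eye / face else NA_real_,
                 ratio_other = if (face > 0) other / face else NA_real_),
            class = "gl_fix_summary")
}

#' @export
print.gl_fix_summary <- function(x, ...) {
  cat("<gl_fix_summary> ", nrow(x$clusters), " fixations | face: ",
      x$total_face, " (eye ", x$eye, ", other ", x$other_facial, ")",
      if (!is.na(x$ratio_eye)) {
        sprintf(" | ratios %.2f / %.2f", x$ratio_eye, x$ratio_other)
      } else "", "\n", sep = "")
  invisible(x)
}
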