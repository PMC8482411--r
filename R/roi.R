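#' Define a rectangular region of interest
#'
#' An ROI is a named, axis-aligned screen rectangle. Active ROIs (the avatar's
#' eye region and the game objects) can trigger game events when fixated;
#' passive ROIs (the five facial features: forehead, ears, nose, mouth) are
#' only logged and analysed offline.
#'
#' Rectangles use the half-open convention \eqn{[x0, x1) \times [y0, y1)} in
#' screen pixels with the origin at the top-left corner and y increasing
#' downwards, so adjacent rectangles tile the screen without double hits.
#'
#' @param name Identifier, unique within a scene.
#' @param kind One of `"avatar_eye"`, `"game_object"`, `"facial_feature"`.
#' @param x0,y0,x1,y1 Rectangle corners in pixels; `x0 < x1`, `y0 < y1`.
#' @param active Logical; facial features must be passive.
#' @return A one-row data frame of class `gl_roi`.
#' @examples
#' roi("avatar_eye", "avatar_eye", 840, 250, 1080, 350)
#' @export
roi <- function(name, kind = c("game_object", "avatar_eye", "facial_feature"),
                x0, y0, x1, y1, active = kind != "facial_feature") {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("'name' must be a non-empty string", call. = FALSE)
  }
  x0 <- as.numeric(x0); y0 <- as.numeric(y0)
  x1 <- as.numeric(x1); y1 <- as.numeric(y1)
  if (!(x0 < x1) || !(y0 < y1)) {
    stop(sprintf("degenerate rectangle for ROI '%s': need x0 < x1 and y0 < y1", name),
         call. = FALSE)
  }
  if (kind == "facial_feature" && isTRUE(active)) {
    stop(sprintf("facial_feature ROI '%s' must be passive", name), call. = FALSE)
  }
  out <- data.frame(name = name, kind = kind, x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                    active = isTRUE(active), stringsAsFactors = FALSE)
  class(out) <- c("gl_roi", "data.frame")
  out
}

#' Assemble an ordered ROI set for a scene
#'
#' Declaration order matters: overlapping rectangles resolve to the first
#' declared hit, and the avatar-eye region is always moved to the front so a
#' gaze landing on an overlap with a facial feature registers as eye contact.
#'
#' @param ... `gl_roi` rows (or data frames of them).
#' @return A data frame of class `gl_roi_set`, one row per ROI.
#' @export
roi_set <- function(...) {
  parts <- list(...)
  if (length(parts) == 0L) stop("roi_set() needs at least one ROI", call. = FALSE)
  out <- do.call(rbind, lapply(parts, as.data.frame))
  if (anyDuplicated(out$name)) {
    stop("duplicate ROI names: ", paste(unique(out$name[duplicated(out$name)]),
                                        collapse = ", "), call. = FALSE)
  }
  n_eye <- sum(out$kind == "avatar_eye")
  if (n_eye != 1L) {
    stop("a scene must contain exactly one avatar_eye ROI (found ", n_eye, ")",
         call. = FALSE)
  }
  out <- rbind(out[out$kind == "avatar_eye", , drop = FALSE],
               out[out$kind != "avatar_eye", , drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("gl_roi_set", "data.frame")
  out
}

#' @export
print.gl_roi_set <- function(x, ...) {
  cat("<gl_roi_set> ", nrow(x), " ROIs (", sum(x$active), " active)\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Default scene geometry for the two games
#'
#' Builds the standard 1920x1080 scene: the avatar's face in the upper half
#' (one active eye-region rectangle plus the five passive facial features:
#' forehead, right ear, left ear, nose, mouth) and either eight bubbles laid
#' out on an arc (bubble game) or seven grey tangram pieces in a row plus an
#' implicit target area (tangram game). Object `k` corresponds to avatar gaze
#' direction `k`.
#'
#' @param game `"bubble"` or `"tangram"`.
#' @param width,height Screen size in pixels.
#' @return A `gl_roi_set`.
#' @export
default_scene <- function(game = c("bubble", "tangram"),
                          width = 1920, height = 1080) {
  game <- match.arg(game)
  cx <- width / 2
  face <- list(
    roi("avatar_eye", "avatar_eye", cx - 120, 250, cx + 120, 350),
    roi("forehead",  "facial_feature", cx - 120, 150, cx + 120, 230),
    roi("right_ear", "facial_feature", cx + 150, 260, cx + 220, 380),
    roi("left_ear",  "facial_feature", cx - 220, 260, cx - 150, 380),
    roi("nose",      "facial_feature", cx - 50,  360, cx + 50,  440),
    roi("mouth",     "facial_feature", cx - 80,  450, cx + 80,  520)
  )
  if (game == "bubble") {
    # eight bubbles on a wide, flat arc below the avatar's face so no bubble
    # rectangle overlaps a facial ROI
    n <- 8L
    ang <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    bx <- cx + 620 * cos(ang)
    by <- 780 + 120 * sin(ang)
    objs <- lapply(seq_len(n), function(k) {
      roi(paste0("bubble_", k), "game_object",
          bx[k] - 70, by[k] - 70, bx[k] + 70, by[k] + 70)
    })
  } else {
    n <- 7L
    px <- seq(260, width - 260, length.out = n)
    objs <- lapply(seq_len(n), function(k) {
      roi(paste0("piece_", k), "game_object",
          px[k] - 80, 840, px[k] + 80, 1000)
    })
  }
  do.call(roi_set, c(face, objs))
}

#' Hit-test a gaze sample against an ordered ROI set
#'
#' Returns the name of the first declared ROI whose half-open rectangle
#' contains the point, or `NA_character_` if no rectangle contains it or the
#' sample is invalid (blink / track loss). Never throws for bad samples.
#'
#' @param sample A list or one-row data frame with `t`, `x`, `y`, `valid`.
#' @param rois A `gl_roi_set`.
#' @return ROI name or `NA_character_`.
#' @examples
#' sc <- default_scene("bubble")
#' hit_test(list(t = 0, x = 960, y = 300, valid = TRUE), sc)
#' @export
hit_test <- function(sample, rois) {
  if (nrow(rois) == 0L) stop("empty ROI set", call. = FALSE)
  if (!isTRUE(as.logical(sample$valid))) return(NA_character_)
  x <- sample$x; y <- sample$y
  if (is.na(x) || is.na(y)) return(NA_character_)
  hit <- which(x >= rois$x0 & x < rois$x1 & y >= rois$y0 & y < rois$y1)
  if (length(hit) == 0L) NA_character_ else rois$name[hit[1L]]
}

# centroid of an ROI (internal helper for the simulator)
roi_center <- function(rois, name) {
  i <- match(name, rois$name)
  if (is.na(i)) stop("unknown ROI: ", name, call. = FALSE)
  c((rois$x0[i] + rois$x1[i]) / 2, (rois$y0[i] + rois$y1[i]) / 2)
}
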