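#' Assemble a validated session configuration
#'
#' Bundles everything one run needs: the game rules, the gaze-runtime
#' thresholds, the offline fixation parameters, the participant profile for
#' simulation, the RNG seed and the output directory. All defaults match the
#' standard study conditions (200 ms dwell, 30 s phase timeout, 120 s
#' termination, 5 s respawn, 2 ups starting speed and increment, 1 degree
#' first dispersion threshold).
#'
#' @param game `"bubble"` or `"tangram"`.
#' @param game_opts Named list passed to [game_config()].
#' @param gaze_opts Named list passed to [gaze_params()].
#' @param fixation_opts Named list passed to [fixation_params()].
#' @param profile_opts Named list passed to [participant_profile()], or a
#'   ready `gl_profile`.
#' @param scene Optional ROI table overriding [default_scene()].
#' @param seed Integer seed (mandatory before simulation).
#' @param out_dir Output directory for CLI runs.
#' @return A list of class `gl_session_config`.
#' @export
session_config <- function(game = "bubble", game_opts = list(),
                           gaze_opts = list(), fixation_opts = list(),
                           profile_opts = list(), scene = NULL,
                           seed = NULL, out_dir = ".") {
  if (!is.null(scene)) {
    if (is.data.frame(scene)) {
      class(scene) <- c("gl_roi_set", "data.frame")
    } else {
      scene <- do.call(roi_set, lapply(scene, function(r) {
        do.call(roi, r)
      }))
    }
  }
  cfg <- do.call(game_config, c(list(game = game, scene = scene), game_opts))
  gz <- do.call(gaze_params, gaze_opts)
  fx <- do.call(fixation_params, fixation_opts)
  pr <- if (inherits(profile_opts, "gl_profile")) profile_opts
        else do.call(participant_profile, profile_opts)
  structure(list(schema = 1L, config = cfg, gaze = gz, fixation = fx,
                 profile = pr, seed = if (is.null(seed)) NULL
                                     else as.integer(seed),
                 out_dir = out_dir),
            class = "gl_session_config")
}

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop("unknown ", where, " key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Load and validate a session configuration file
#'
#' Reads a single YAML (or JSON) document, rejects unknown keys at every
#' level, applies the standard defaults for anything omitted, and validates
#' every threshold through the same constructors used programmatically, so
#' an invalid value (say a negative dwell threshold) errors with the
#' offending key named.
#'
#' @param path Path to the config file.
#' @return A `gl_session_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  check_keys(raw, c("schema", "game", "gaze", "fixation", "profile", "scene",
                    "seed", "out_dir"), "top-level")
  if (!is.null(raw$schema) && raw$schema != 1L) {
    stop("unsupported config schema version: ", raw$schema, call. = FALSE)
  }
  game_keys <- setdiff(names(formals(game_config)), c("game", "scene"))
  gaze_keys <- names(formals(gaze_params))
  fix_keys <- names(formals(fixation_params))
  prof_keys <- names(formals(participant_profile))
  g <- raw$game
  if (is.null(g) || is.null(g$game)) {
    stop("config must name the game under game: game:", call. = FALSE)
  }
  game_name <- g$game
  g$game <- NULL
  check_keys(g, game_keys, "game")
  check_keys(raw$gaze, gaze_keys, "gaze")
  check_keys(raw$fixation, fix_keys, "fixation")
  check_keys(raw$profile, prof_keys, "profile")
  session_config(game = game_name, game_opts = g,
                 gaze_opts = if (is.null(raw$gaze)) list() else raw$gaze,
                 fixation_opts = if (is.null(raw$fixation)) list()
                                 else raw$fixation,
                 profile_opts = if (is.null(raw$profile)) list()
                                else raw$profile,
                 scene = raw$scene, seed = raw$seed,
                 out_dir = if (is.null(raw$out_dir)) "." else raw$out_dir)
}

#' Write a session configuration back to YAML
#'
#' Inverse of [load_config()]: a written file re-reads to an identical
#' configuration.
#'
#' @param cfg A `gl_session_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "gl_session_config"))
  gc_ <- cfg$config
  game_fields <- setdiff(names(gc_), c("game", "scene"))
  scene <- gc_$scene
  out <- list(
    schema = 1L,
    game = c(list(game = gc_$game),
             lapply(stats::setNames(game_fields, game_fields),
                    function(f) gc_[[f]])),
    gaze = unclass(cfg$gaze),
    fixation = Filter(Negate(is.null), unclass(cfg$fixation)),
    profile = unclass(cfg$profile),
    scene = lapply(seq_len(nrow(scene)), function(i) {
      list(name = scene$name[i], kind = scene$kind[i], x0 = scene$x0[i],
           y0 = scene$y0[i], x1 = scene$x1[i], y1 = scene$y1[i],
           active = scene$active[i])
    }),
    seed = cfg$seed, out_dir = cfg$out_dir)
  out <- Filter(Negate(is.null), out)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Read / write a gaze stream CSV (`t_ms,x_px,y_px,valid`)
#'
#' The on-disk dialect stores `valid` as 0/1; invalid rows carry empty
#' coordinates.
#'
#' @param path File path.
#' @return `read_gaze_csv`: data frame with numeric `t_ms`, `x_px`, `y_px`
#'   and logical `valid`.
#' @export
read_gaze_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_ms", "x_px", "y_px", "valid")
  if (!all(need %in% names(df))) {
    stop("gaze CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  df$valid <- as.logical(as.integer(df$valid))
  df
}

#' @rdname read_gaze_csv
#' @param gaze Gaze data frame.
#' @export
write_gaze_csv <- function(gaze, path) {
  out <- data.frame(t_ms = gaze$t_ms,
                    x_px = round(gaze$x_px, 3),
                    y_px = round(gaze$y_px, 3),
                    valid = as.integer(gaze$valid))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a session event log CSV
#'
#' @param path File path.
#' @return `read_session_log`: the log data frame.
#' @export
read_session_log <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(roi = "character", outcome = "character"))
}

#' @rdname read_session_log
#' @param log Log data frame (see [session_log()]).
#' @export
write_session_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write detected fixations to CSV
#' (`onset_ms,offset_ms,duration_ms,x_px,y_px,n_samples,roi`)
#'
#' @param fixations A `gl_fixations` frame or the `clusters` element of a
#'   `gl_fix_summary`.
#' @param path Output path.
#' @export
write_fixations_csv <- function(fixations, path) {
  if (inherits(fixations, "gl_fix_summary")) fixations <- fixations$clusters
  if (is.null(fixations$roi)) fixations$roi <- NA_character_
  cols <- c("onset_ms", "offset_ms", "duration_ms", "x_px", "y_px",
            "n_samples", "roi")
  utils::write.csv(fixations[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a metrics report as JSON
#'
#' @param metrics A `gl_metrics`.
#' @param path Output path.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(Filter(Negate(is.null), unclass(metrics)), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
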