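#' Write trials to CSV
#'
#' Serializes a trial table as two plain-text files: a long trajectory CSV
#' (`trial_id, frame, p_x, p_y, o_x, o_y, alive`) and a sidecar metadata CSV
#' holding, per trial, the generating parameters and labels
#' (`trial_id, d, w_d, w_s, w_p, a, s, v, goal, profile, censored_length`).
#'
#' @param trials A trial tibble.
#' @param path Path of the trajectory CSV; the sidecar defaults to the same
#'   path with a `_meta.csv` suffix.
#' @param meta_path Optional explicit sidecar path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trials, path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- default_meta_path(path)
  long <- purrr::map2_dfr(trials$trial_id, trials$frames, function(id, f) {
    tibble::tibble(trial_id = id, frame = seq_len(nrow(f)),
                   p_x = f[, 1], p_y = f[, 2], o_x = f[, 3], o_y = f[, 4],
                   alive = as.integer(f[, 5]))
  })
  readr::write_csv(long, path)
  meta <- tibble::tibble(
    trial_id = trials$trial_id,
    d = trials$d, w_d = trials$w_d, w_s = trials$w_s, w_p = trials$w_p,
    a = trials$a, s = trials$s, v = trials$v,
    goal = trials$goal %||% NA_character_,
    profile = trials$profile,
    censored_length = trials$censored_length %||% trials$n_frames
  )
  if ("participant" %in% names(trials)) meta$participant <- trials$participant
  readr::write_csv(meta, meta_path)
  invisible(path)
}

default_meta_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_meta.csv")
}

#' Read trials from CSV
#'
#' Inverse of [write_trajectories()]: reconstructs the trial tibble from the
#' trajectory CSV and its sidecar. Frames are sorted; duplicate
#' `(trial_id, frame)` pairs and non-monotone alive flags (an agent cannot
#' come back to life) are parse errors naming the offending trial.
#'
#' @param path Trajectory CSV path.
#' @param meta_path Sidecar path (defaults as in [write_trajectories()]).
#' @return A trial tibble.
#' @export
read_trajectories <- function(path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- default_meta_path(path)
  cols <- c("trial_id", "frame", "p_x", "p_y", "o_x", "o_y", "alive")
  long <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(cols %in% names(long)))
    stop("trajectory file must have columns: ", paste(cols, collapse = ", "))
  meta <- readr::read_csv(meta_path, show_col_types = FALSE)
  if (nrow(long) == 0) {
    out <- tibble::as_tibble(meta)
    out$frames <- list()
    out$n_frames <- integer(0)
    return(out)
  }
  long <- dplyr::arrange(long, .data$trial_id, .data$frame)
  split_frames <- split(long, long$trial_id)
  frames <- lapply(split_frames, function(g) {
    id <- g$trial_id[1]
    if (anyDuplicated(g$frame))
      stop("duplicate (trial, frame) rows in trial ", id)
    al <- g$alive
    if (any(diff(al) > 0))
      stop("non-monotone alive flag in trial ", id,
           " (an agent cannot come back to life)")
    m <- cbind(p_x = g$p_x, p_y = g$p_y, o_x = g$o_x, o_y = g$o_y,
               alive = as.numeric(al))
    m
  })
  ids <- as.numeric(names(frames))
  out <- tibble::as_tibble(meta[match(ids, meta$trial_id), , drop = FALSE])
  out$frames <- unname(frames)
  out$n_frames <- vapply(out$frames, nrow, integer(1))
  if (is.null(out$censored_length[1]) || anyNA(out$censored_length))
    out$censored_length <- out$n_frames
  out
}

#' Read or write a run configuration (YAML)
#'
#' A run configuration bundles the screen geometry, simulator constants,
#' prior settings, training hyperparameters and the root seed so that any
#' run can be reproduced from the persisted file.
#'
#' @param path YAML file path.
#' @return `read_run_config()`: a list of class `glop_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_run_config(raw)
}

#' @rdname read_run_config
#' @param config A `glop_run_config` (or plain list of overrides).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Default run configuration
#'
#' @param ... Named overrides of top-level fields: `seed`, `n_trials`,
#'   `epochs`, `n_test`, plus the sub-lists `geometry`, `config`, `prior`.
#' @return A list of class `glop_run_config`.
#' @export
default_run_config <- function(...) {
  base <- list(
    seed = 1L,
    n_trials = 10000L,
    n_test = 4000L,
    epochs = 15L,
    target_length = 138L,
    lr = 1e-3,
    batch = 8L,
    geometry = list(width = 1920, height = 1080),
    config = unclass_deep(unclass(glop_config())),
    prior = unclass_deep(unclass(glop_prior()))
  )
  as_run_config(utils::modifyList(base, list(...)))
}

as_run_config <- function(x) {
  stopifnot(is.list(x))
  structure(x, class = "glop_run_config")
}

run_config_objects <- function(rc) {
  list(
    geom = screen_geometry(rc$geometry$width, rc$geometry$height),
    config = do.call(glop_config,
                     rc$config[setdiff(names(rc$config), character(0))]),
    prior = do.call(glop_prior, rc$prior)
  )
}
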