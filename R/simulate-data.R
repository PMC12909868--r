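#' Simulate a batch of dyadic trials
#'
#' Takes a parameter table (one row per trial, with a `profile` column) and
#' attaches simulated trajectories as a list-column of frame matrices with
#' columns `p_x, p_y, o_x, o_y, alive`. Starting positions, the Defensive
#' profile's hidden target and the Wandering profile's initial heading are
#' drawn per trial.
#'
#' @param params A data frame with the seven parameter columns of
#'   [glop_params()] plus `profile`; extra columns are carried through.
#' @param geom A [screen_geometry()].
#' @param config A [glop_config()].
#' @param horizon Frames to simulate per trial: a scalar or a vector of
#'   length `nrow(params)` (defaults to `config$n_frames`).
#' @return `params` as a tibble with added columns `trial_id`, `n_frames`
#'   and `frames` (list of numeric matrices).
#' @export
simulate_trials <- function(params, geom = screen_geometry(),
                            config = glop_config(),
                            horizon = config$n_frames) {
  validate_glop_params(params)
  stopifnot("profile" %in% names(params))
  n <- nrow(params)
  codes <- match(params$profile, opponent_profiles())
  if (anyNA(codes)) stop("unknown opponent profile in `profile` column")
  horizon <- as.integer(rep_len(horizon, n))
  stopifnot(all(horizon >= 2))
  m <- config$start_margin
  px <- stats::runif(n, m, geom$width - m)
  py <- stats::runif(n, m, geom$height - m)
  ox <- stats::runif(n, m, geom$width - m)
  oy <- stats::runif(n, m, geom$height - m)
  hx <- stats::runif(n, 0, geom$width)
  hy <- stats::runif(n, 0, geom$height)
  hd <- stats::runif(n, -pi, pi)
  pm <- as.matrix(params[, param_names()])
  g <- unclass(geom)
  cf <- unclass(config)
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    frames[[i]] <- cpp_simulate_trial(pm[i, ], codes[i], c(px[i], py[i]),
                                      c(ox[i], oy[i]), c(hx[i], hy[i]),
                                      hd[i], horizon[i], g, cf)
    colnames(frames[[i]]) <- c("p_x", "p_y", "o_x", "o_y", "alive")
  }
  out <- tibble::as_tibble(params)
  out$trial_id <- seq_len(n)
  out$n_frames <- horizon
  out$frames <- frames
  dplyr::relocate(out, "trial_id")
}

#' Generate a prior-predictive training set
#'
#' The data factory for amortized estimation: draws `n_total` parameter sets
#' from the prior, assigns the five opponent profiles in equal numbers
#' (`n_total` must be divisible by 5), simulates each trial, removes trials
#' that collide on the first time step, and (by default) censors each trial
#' with an independent uniform draw on `{2, ..., max_steps}` frames. For
#' efficiency each trial is simulated directly to its censor length; the
#' post-collision tail, where both agents are frozen, is what the alive flag
#' encodes.
#'
#' @param n_total Number of trials before filtering (divisible by 5).
#' @param prior A [glop_prior()].
#' @param geom,config Geometry and configuration.
#' @param censor Censor trial lengths? If `FALSE` every trial runs the full
#'   `config$n_frames`.
#' @param max_steps Censoring ceiling in frames.
#' @return A trial tibble as from [simulate_trials()], with an added
#'   `censored_length` column and `goal = NA` (prior draws carry no goal).
#' @export
generate_training_set <- function(n_total, prior = glop_prior(),
                                  geom = screen_geometry(),
                                  config = glop_config(), censor = TRUE,
                                  max_steps = config$n_frames) {
  stopifnot(n_total >= 5, n_total %% 5 == 0)
  params <- sample_params(n_total, prior)
  params$profile <- rep(opponent_profiles(), each = n_total / 5)
  params$goal <- NA_character_
  len <- if (censor) draw_censor_lengths(n_total, max_steps)
         else rep.int(as.integer(config$n_frames), n_total)
  len <- pmin(len, as.integer(config$n_frames))
  trials <- simulate_trials(params, geom, config, horizon = len)
  trials$censored_length <- trials$n_frames
  filter_first_step_collisions(trials)
}

draw_censor_lengths <- function(n, max_steps) {
  stopifnot(max_steps >= 2)
  as.integer(sample(2:max_steps, n, replace = TRUE))
}

#' Remove trials that collide on the first time step
#'
#' @param trials A trial tibble with a `frames` list-column.
#' @return The tibble restricted to trials whose alive flag is set at
#'   frame 1.
#' @export
filter_first_step_collisions <- function(trials) {
  keep <- vapply(trials$frames, function(f) f[1, "alive"] == 1, logical(1))
  trials[keep, , drop = FALSE]
}

#' Censor trial lengths
#'
#' Draws an independent censor length uniformly on `{2, ..., max_steps}` for
#' each trial and sets `censored_length = min(draw, trial length)`: trials
#' shorter than their draw are left unchanged. Downstream encoders only read
#' the first `censored_length` frames, which is what makes the estimation
#' networks applicable to partial, real-time data.
#'
#' @param trials A trial tibble with `frames` and `n_frames`.
#' @param max_steps Censoring ceiling in frames (>= 2).
#' @return `trials` with an updated `censored_length` column.
#' @export
censor_trials <- function(trials, max_steps = 600) {
  draw <- draw_censor_lengths(nrow(trials), max_steps)
  trials$censored_length <- pmin(draw, trials$n_frames)
  trials
}

#' Generate a goal-labeled trial set
#'
#' Synthetic stand-in for the empirical goal-labeled data: simulated
#' "participants" each receive one parameter draw per goal from the
#' goal-conditional [label_param_map()] (Attack prefers small `d`, Inspect
#' intermediate, Avoid large) and play `reps_per_cell` trials against each of
#' the five opponent profiles under each goal. Grouping trials into
#' participant blocks preserves the leakage structure that participant-level
#' train/validation/test splits guard against.
#'
#' @param n_participants Number of simulated participants (blocks).
#' @param map A [label_param_map()].
#' @param reps_per_cell Trials per goal-by-profile cell per participant.
#' @param geom,config Geometry and configuration.
#' @return A trial tibble with `participant`, `goal`, `profile`, parameter
#'   columns, `frames` and `censored_length` (full length).
#' @examples
#' set.seed(1)
#' tr <- generate_goal_labeled_set(1, reps_per_cell = 1,
#'                                 config = glop_config(n_frames = 30))
#' nrow(tr) # 15 cells
#' @export
generate_goal_labeled_set <- function(n_participants, map = label_param_map(),
                                      reps_per_cell = 1,
                                      geom = screen_geometry(),
                                      config = glop_config()) {
  stopifnot(n_participants >= 1, reps_per_cell >= 1)
  goals <- goal_labels()
  blocks <- list()
  for (pid in seq_len(n_participants)) {
    for (goal in goals) {
      par <- sample_goal_params(1, map, goal)
      cell <- par[rep(1, 5 * reps_per_cell), ]
      cell$profile <- rep(opponent_profiles(), each = reps_per_cell)
      cell$goal <- goal
      cell$participant <- pid
      blocks[[length(blocks) + 1]] <- cell
    }
  }
  params <- dplyr::bind_rows(blocks)
  trials <- simulate_trials(params, geom, config)
  trials$censored_length <- trials$n_frames
  trials
}

#' Replicate trials at multiple censored lengths
#'
#' Expands each trial into one row per requested prefix length (lengths
#' exceeding the trial are dropped), mimicking the replicate-and-censor
#' scheme used to train classifiers that must operate on partial trials.
#'
#' @param trials A trial tibble.
#' @param lengths Integer vector of censor lengths (each >= 2).
#' @return The expanded tibble with `censored_length` set per row.
#' @export
replicate_censored <- function(trials, lengths) {
  stopifnot(all(lengths >= 2))
  out <- tidyr::crossing(trials, censor_to = as.integer(lengths))
  out <- out[out$censor_to <= out$n_frames, , drop = FALSE]
  out$censored_length <- out$censor_to
  out$censor_to <- NULL
  out
}

#' Participant-level split
#'
#' Assigns whole participant blocks to disjoint training, validation and
#' test sets so that no participant's trials leak across sets.
#'
#' @param trials A trial tibble with a `participant` column.
#' @param n_test,n_val Number of participants held out for test/validation.
#' @return `trials` with an added `split` factor column.
#' @export
split_participants <- function(trials, n_test = 1, n_val = 1) {
  ids <- unique(trials$participant)
  stopifnot(length(ids) > n_test + n_val)
  ord <- sample(ids)
  test <- ord[seq_len(n_test)]
  val <- ord[n_test + seq_len(n_val)]
  trials$split <- factor(
    ifelse(trials$participant %in% test, "test",
           ifelse(trials$participant %in% val, "validation", "train")),
    levels = c("train", "validation", "test")
  )
  trials
}
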