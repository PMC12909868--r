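#' Unit vector from participant to opponent
#'
#' @param p,o Length-2 numeric positions in pixels.
#' @return Unit vector pointing from `p` to `o`; errors when the agents are
#'   co-located (degenerate geometry; [glop_step()] substitutes a zero
#'   vector in that case because a collision will already have frozen play).
#' @examples
#' unit_vector_to_opponent(c(0, 0), c(300, 400)) # (0.6, 0.8)
#' @export
unit_vector_to_opponent <- function(p, o) {
  diff <- as.numeric(o) - as.numeric(p)
  nrm <- sqrt(sum(diff^2))
  if (nrm == 0) stop("degenerate geometry: agents are co-located")
  diff / nrm
}

#' Preferred distance vector
#'
#' The local approach-avoidance component: points toward the opponent when
#' the current separation exceeds the preferred distance `d * dist_max`, and
#' away from the opponent when the agents are too close. Magnitude equals the
#' discrepancy in pixels, so larger violations of the preferred distance
#' drive faster motion.
#'
#' @param p,o Length-2 positions in pixels.
#' @param d Preferred distance as a fraction of the screen diagonal.
#' @param geom A [screen_geometry()].
#' @return Length-2 vector in px/frame.
#' @examples
#' preferred_distance_vector(c(0, 0), c(300, 400), d = 0, screen_geometry())
#' @export
preferred_distance_vector <- function(p, o, d, geom = screen_geometry()) {
  t_hat <- unit_vector_to_opponent(p, o)
  dist <- sqrt(sum((as.numeric(o) - as.numeric(p))^2))
  (dist - d * geom$dist_max) * t_hat
}

#' Spatial preference grid
#'
#' Evaluates the attractiveness of every cell of a regular grid over the
#' screen given the opponent position and the preferred distance: cells whose
#' distance to the opponent equals `d * dist_max` score 1, and the score
#' decays linearly in the absolute deviation, reaching 0 at the maximal
#' possible deviation. Cell (i, j) is centered at
#' `((i - 0.5) * width / res, (j - 0.5) * height / res)`.
#'
#' @param o Opponent position (length-2, pixels).
#' @param d Preferred distance fraction.
#' @param geom A [screen_geometry()].
#' @param resolution Cells per axis (>= 2).
#' @return A list of class `preference_grid` with `cell_x`, `cell_y`
#'   (coordinate vectors), `D` (resolution x resolution matrix of preference
#'   strengths in `[0, 1]`, rows indexing x) and the inputs.
#' @export
spatial_preference_matrix <- function(o, d, geom = screen_geometry(),
                                      resolution = 50) {
  stopifnot(resolution >= 2)
  cx <- (seq_len(resolution) - 0.5) * geom$width / resolution
  cy <- (seq_len(resolution) - 0.5) * geom$height / resolution
  dist <- sqrt(outer(cx - o[1], cy - o[2], function(a, b) a^2 + b^2))
  D <- (geom$dist_max - abs(dist - d * geom$dist_max)) / geom$dist_max
  structure(list(cell_x = cx, cell_y = cy, D = D, o = as.numeric(o), d = d,
                 geom = geom, resolution = as.integer(resolution)),
            class = "preference_grid")
}

#' Spatial preference vector
#'
#' The global component of motivation: the resultant of vectors from the
#' participant toward each grid cell, weighted by the cell's preference
#' strength raised to the spatial sensitivity `s`, and normalized by the
#' number of cells. Large `s` concentrates the pull onto the few best cells;
#' small `s` spreads it over all acceptable locations.
#' `sign = "printed"` reverses the summand to point from cells toward the
#' participant.
#'
#' @param p Participant position (length-2, pixels).
#' @param grid A [spatial_preference_matrix()] result.
#' @param s Spatial sensitivity exponent (> 0).
#' @param sign `"attract"` (default) or `"printed"`.
#' @return Length-2 vector in px/frame.
#' @export
spatial_vector <- function(p, grid, s, sign = c("attract", "printed")) {
  sign <- match.arg(sign)
  stopifnot(inherits(grid, "preference_grid"), s > 0)
  w <- grid$D^s
  n <- length(w)
  vx <- sum(w * (grid$cell_x - p[1])) / n   # rows of D index x cells
  vy <- sum(t(w) * (grid$cell_y - p[2])) / n
  out <- c(vx, vy)
  if (sign == "printed") out <- -out
  out
}

#' Pace matching vector
#'
#' The direction and speed the participant wants to copy from the opponent:
#' the opponent's most recent per-frame displacement. Combined with the
#' preferred-distance component this produces interception-like motion.
#'
#' @param opponent_prev_traj Opponent displacement over the previous frame
#'   (length-2, px/frame).
#' @return The same vector.
#' @export
pace_vector <- function(opponent_prev_traj) {
  as.numeric(opponent_prev_traj)
}

#' Motivational vector
#'
#' Convex combination of the three motivation components with the simplex
#' weights: `v_motiv = w_d * v_dist + w_s * v_spatial + w_p * v_pace` with
#' `w_p = 1 - w_d - w_s`.
#'
#' @param v_dist,v_spatial,v_pace Length-2 component vectors (px/frame).
#' @param params A [glop_params()] row (only the weights are used).
#' @return Length-2 vector in px/frame.
#' @export
motivational_vector <- function(v_dist, v_spatial, v_pace, params) {
  validate_glop_params(params)
  params$w_d * v_dist + params$w_s * v_spatial + params$w_p * v_pace
}

#' Movement variability draw
#'
#' Isotropic Gaussian motor noise whose per-axis standard deviation scales
#' with the speed of intended movement: `sd = v * ||v_motiv||`. Faster
#' intended movement is harder to execute precisely.
#'
#' @param v_motiv Motivational vector (length-2, px/frame).
#' @param v Movement variability scale (>= 0).
#' @return Length-2 noise vector; deterministic under `set.seed()`.
#' @export
movement_noise <- function(v_motiv, v) {
  stopifnot(v >= 0)
  sd <- v * sqrt(sum(v_motiv^2))
  stats::rnorm(2, mean = 0, sd = sd)
}

#' Trajectory vector
#'
#' The executed step: autocorrelation-weighted blend of the previous step
#' with the noisy motivational vector,
#' `v_traj = a * prev_traj + (1 - a) * (v_motiv + v_variability)`.
#'
#' @param prev_traj Previous executed step (length-2, px/frame).
#' @param v_motiv Motivational vector.
#' @param v_variability Motor-noise draw.
#' @param a Autocorrelation weight in `[0, 1]`.
#' @return Length-2 vector in px/frame (before the speed cap).
#' @export
trajectory_vector <- function(prev_traj, v_motiv, v_variability, a) {
  stopifnot(a >= 0, a <= 1)
  a * prev_traj + (1 - a) * (v_motiv + v_variability)
}

#' Agent state
#'
#' @param position Length-2 position in pixels.
#' @param prev_traj Previous per-frame displacement (defaults to rest).
#' @return A list of class `agent_state`.
#' @export
agent_state <- function(position, prev_traj = c(0, 0)) {
  structure(list(position = as.numeric(position),
                 prev_traj = as.numeric(prev_traj)),
            class = "agent_state")
}

#' One GLOP participant step
#'
#' Advances the participant by one frame: computes the preferred-distance,
#' spatial-preference and pace-matching components, converts the two
#' positional-discrepancy components to an intended velocity through
#' `config$motiv_gain`, mixes them with the simplex weights, adds
#' speed-scaled Gaussian variability, blends with the previous step through
#' the autocorrelation weight, caps the speed at `config$max_speed` and
#' clamps the position to the screen. Co-located
#' agents contribute a zero preferred-distance component (collision will
#' already have frozen play in a simulated trial).
#'
#' @param state Participant [agent_state()].
#' @param opponent Opponent [agent_state()]; its `prev_traj` feeds the pace
#'   component.
#' @param params A [glop_params()] row.
#' @param geom A [screen_geometry()].
#' @param config A [glop_config()].
#' @param noise Draw movement variability? Set `FALSE` for the mean path.
#' @return Updated participant [agent_state()].
#' @export
glop_step <- function(state, opponent, params, geom = screen_geometry(),
                      config = glop_config(), noise = TRUE) {
  validate_glop_params(params)
  res <- cpp_glop_step(state$position, state$prev_traj, opponent$position,
                       opponent$prev_traj, as_param_vector(params),
                       unclass(geom), unclass(config), noise)
  agent_state(res$position, res$prev_traj)
}

#' Simulate one dyadic trial
#'
#' Runs the GLOP participant against a scripted opponent profile for
#' `n_frames` frames at the configured frame rate. Frame 1 is the starting
#' state; a collision (center distance below `config$collision_radius`)
#' clears the alive flag and freezes both agents for the remainder.
#'
#' @param params A [glop_params()] row.
#' @param profile Opponent profile name (see [opponent_profiles()]).
#' @param geom,config Geometry and configuration.
#' @param n_frames Number of frames (defaults to `config$n_frames`).
#' @param p_start,o_start Starting positions; drawn uniformly inside the
#'   screen margins when `NULL`.
#' @param hidden_target Defensive profile's hidden anchor; drawn uniformly
#'   when `NULL`.
#' @return A tibble with columns `frame, p_x, p_y, o_x, o_y, alive`.
#' @examples
#' set.seed(1)
#' p <- glop_params(d = 0.1, w_d = 1, w_s = 0, a = 0, s = 1, v = 0)
#' tr <- simulate_trial(p, "Aggressive", n_frames = 60)
#' @export
simulate_trial <- function(params, profile, geom = screen_geometry(),
                           config = glop_config(), n_frames = config$n_frames,
                           p_start = NULL, o_start = NULL,
                           hidden_target = NULL) {
  validate_glop_params(params)
  profile_code <- match(profile, opponent_profiles())
  if (is.na(profile_code)) stop("unknown opponent profile: ", profile)
  m <- config$start_margin
  if (is.null(p_start))
    p_start <- c(stats::runif(1, m, geom$width - m),
                 stats::runif(1, m, geom$height - m))
  if (is.null(o_start))
    o_start <- c(stats::runif(1, m, geom$width - m),
                 stats::runif(1, m, geom$height - m))
  if (is.null(hidden_target))
    hidden_target <- c(stats::runif(1, 0, geom$width),
                       stats::runif(1, 0, geom$height))
  heading <- stats::runif(1, -pi, pi)
  mat <- cpp_simulate_trial(as_param_vector(params), profile_code, p_start,
                            o_start, hidden_target, heading,
                            as.integer(n_frames), unclass(geom),
                            unclass(config))
  tibble::tibble(frame = seq_len(nrow(mat)), p_x = mat[, 1], p_y = mat[, 2],
                 o_x = mat[, 3], o_y = mat[, 4], alive = mat[, 5])
}
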