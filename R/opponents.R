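#' Scripted opponent profiles
#'
#' The five computer-opponent movement profiles: *Aggressive* moves straight
#' at the participant, *Shy* straight away, *Curious* holds a standoff
#' distance (a distance-keeping rule equivalent to a GLOP agent with
#' `w_d = 1`), *Defensive* holds the midpoint between the participant and a
#' hidden screen location, and *Wandering* follows a persistent random
#' heading with wall avoidance. All profiles move at `config$opponent_speed`
#' px/frame with Gaussian heading noise and are clamped to the screen.
#'
#' @return Character vector of the five profile names, in code order 1-5.
#' @export
opponent_profiles <- function() {
  c("Aggressive", "Shy", "Curious", "Defensive", "Wandering")
}

#' Opponent state
#'
#' @param position Length-2 position in pixels.
#' @param prev_traj Previous per-frame displacement.
#' @param heading Current heading in radians (Wandering profile).
#' @param hidden_target Hidden anchor position (Defensive profile).
#' @return A list of class `opponent_state`.
#' @export
opponent_state <- function(position, prev_traj = c(0, 0), heading = 0,
                           hidden_target = c(0, 0)) {
  structure(list(position = as.numeric(position),
                 prev_traj = as.numeric(prev_traj),
                 heading = as.numeric(heading),
                 hidden_target = as.numeric(hidden_target)),
            class = "opponent_state")
}

#' One scripted opponent step
#'
#' @param profile Profile name (see [opponent_profiles()]).
#' @param state An [opponent_state()].
#' @param participant The participant's [agent_state()].
#' @param geom A [screen_geometry()].
#' @param config A [glop_config()].
#' @return Updated [opponent_state()].
#' @export
opponent_step <- function(profile, state, participant,
                          geom = screen_geometry(), config = glop_config()) {
  code <- match(profile, opponent_profiles())
  if (is.na(code)) stop("unknown opponent profile: ", profile)
  res <- cpp_opponent_step(code, state$position, state$prev_traj,
                           state$heading, participant$position,
                           state$hidden_target, unclass(geom),
                           unclass(config))
  opponent_state(res$position, res$prev_traj, res$heading,
                 state$hidden_target)
}
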