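#' Screen geometry for the continuous control task
#'
#' The task takes place on a pixel grid; the maximum attainable distance
#' between two agents, `dist_max`, is the screen diagonal and is the unit in
#' which the preferred-distance parameter `d` is expressed.
#'
#' @param width,height Screen size in pixels. Defaults mirror the task
#'   display (1920 x 1080).
#' @return A list of class `screen_geometry` with fields `width`, `height`
#'   and `dist_max`.
#' @examples
#' geom <- screen_geometry()
#' geom$dist_max # sqrt(1920^2 + 1080^2)
#' @export
screen_geometry <- function(width = 1920, height = 1080) {
  stopifnot(is.numeric(width), is.numeric(height), width > 0, height > 0)
  structure(
    list(width = as.numeric(width), height = as.numeric(height),
         dist_max = sqrt(width^2 + height^2)),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %g x %g px (dist_max = %.1f px)\n",
              x$width, x$height, x$dist_max))
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles the tunable constants of the dyadic simulator: the preference-grid
#' resolution, the participant's speed cap (emulating joystick saturation),
#' the collision radius at which agents freeze, frame rate and trial length,
#' and the scripted-opponent kinematics. `spatial_sign = "attract"` makes the
#' preference-gradient summand point from the participant toward each grid
#' cell (movement toward good locations); `"printed"` flips the sign.
#'
#' @param grid_resolution Cells per axis of the spatial preference grid.
#' @param max_speed Participant speed cap in px/frame.
#' @param motiv_gain Control gain converting the positional discrepancy
#'   components (preferred-distance and spatial-preference vectors, in px)
#'   into intended joystick velocity (px/frame) before they are mixed with
#'   the pace component. The default 1/60 aims to close a discrepancy in
#'   about one second at 60 Hz.
#' @param collision_radius Center distance in px below which agents collide.
#' @param spatial_sign `"attract"` or `"printed"` (see Details).
#' @param fps Sampling rate in frames per second.
#' @param n_frames Trial length in frames (default 600 = 10 s at 60 Hz).
#' @param opponent_speed Scripted opponent speed in px/frame.
#' @param heading_noise_sd SD of the Gaussian heading rotation (radians)
#'   applied to opponent steps.
#' @param curious_distance Standoff distance in px for the Curious profile.
#' @param wander_persistence Per-frame heading persistence of the Wandering
#'   profile, in `[0, 1)`.
#' @param wander_margin Distance from a wall (px) at which the Wandering
#'   profile starts steering back toward the screen center.
#' @param start_margin Margin in px inside which starting positions are not
#'   placed when drawn at random.
#' @return A list of class `glop_config`.
#' @examples
#' cfg <- glop_config(n_frames = 120)
#' @export
glop_config <- function(grid_resolution = 50,
                        max_speed = 10,
                        motiv_gain = 1 / 60,
                        collision_radius = 40,
                        spatial_sign = c("attract", "printed"),
                        fps = 60,
                        n_frames = 600,
                        opponent_speed = 6,
                        heading_noise_sd = 0.2,
                        curious_distance = 200,
                        wander_persistence = 0.95,
                        wander_margin = 60,
                        start_margin = 50) {
  spatial_sign <- match.arg(spatial_sign)
  stopifnot(grid_resolution >= 2, max_speed > 0, motiv_gain > 0,
            collision_radius >= 0,
            fps > 0, n_frames >= 2, opponent_speed > 0,
            heading_noise_sd >= 0, curious_distance >= 0,
            wander_persistence >= 0, wander_persistence < 1)
  structure(
    list(grid_resolution = as.integer(grid_resolution),
         max_speed = as.numeric(max_speed),
         motiv_gain = as.numeric(motiv_gain),
         collision_radius = as.numeric(collision_radius),
         spatial_sign = spatial_sign,
         fps = as.numeric(fps),
         n_frames = as.integer(n_frames),
         opponent_speed = as.numeric(opponent_speed),
         heading_noise_sd = as.numeric(heading_noise_sd),
         curious_distance = as.numeric(curious_distance),
         wander_persistence = as.numeric(wander_persistence),
         wander_margin = as.numeric(wander_margin),
         start_margin = as.numeric(start_margin)),
    class = "glop_config"
  )
}

#' @export
print.glop_config <- function(x, ...) {
  cat("<glop_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
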