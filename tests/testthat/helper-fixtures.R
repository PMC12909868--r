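# Shared small fixtures for unit tests.  Heavy (acceptance-scale) fixtures
# live in helper-acceptance.R.

# short-trial configuration for fast unit tests
tiny_config <- function(...) glop_config(n_frames = 60, ...)

# a hand-made frame matrix builder
make_frames <- function(p, o, alive = NULL) {
  p <- matrix(p, ncol = 2, byrow = TRUE)
  o <- matrix(o, ncol = 2, byrow = TRUE)
  if (is.null(alive)) alive <- rep(1, nrow(p))
  m <- cbind(p_x = p[, 1], p_y = p[, 2], o_x = o[, 1], o_y = o[, 2],
             alive = alive)
  m
}

# wrap a frame matrix as a one-row trial tibble
make_trial <- function(frames, profile = "Aggressive", goal = NA_character_,
                       params = glop_params(d = 0.2, w_d = 0.5, w_s = 0.3,
                                            a = 0.5, s = 1, v = 0.1)) {
  out <- tibble::as_tibble(params)
  out$profile <- profile
  out$goal <- goal
  out$trial_id <- 1L
  out$n_frames <- nrow(frames)
  out$censored_length <- nrow(frames)
  out$frames <- list(frames)
  out
}

# naive double-loop oracle for the spatial preference vector
spatial_vector_oracle <- function(p, grid, s, sign = "attract") {
  acc <- c(0, 0)
  res <- grid$resolution
  for (i in seq_len(res)) {
    for (j in seq_len(res)) {
      cell <- c(grid$cell_x[i], grid$cell_y[j])
      acc <- acc + grid$D[i, j]^s * (cell - p)
    }
  }
  out <- acc / (res * res)
  if (sign == "printed") out <- -out
  out
}

# separable goal-labeled population: goals occupy disjoint preferred-distance
# ranges AND lean on distance motivation, so the assigned goal is strongly
# expressed in behavior
separable_label_map <- function() {
  label_param_map(attack = c(1, 99), inspect = c(20, 60), avoid = c(120, 6),
                  w_shape = c(12, 1, 1))
}
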