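geom <- screen_geometry()

test_that("unit vector to opponent is normalized and oriented", {
  expect_equal(unit_vector_to_opponent(c(0, 0), c(300, 400)), c(0.6, 0.8))
  expect_equal(unit_vector_to_opponent(c(5, 5), c(5, 9)), c(0, 1))
  expect_error(unit_vector_to_opponent(c(3, 3), c(3, 3)), "co-located")
})

test_that("preferred distance vector follows the discrepancy rule", {
  # d = 0: full attraction toward the opponent
  expect_equal(preferred_distance_vector(c(0, 0), c(300, 400), 0, geom),
               c(300, 400))
  # current distance equals preferred distance: no pull
  expect_equal(
    preferred_distance_vector(c(0, 0), c(300, 400), 500 / geom$dist_max, geom),
    c(0, 0))
  # d = 1: strong repulsion, (500 - dist_max) * (0.6, 0.8)
  expect_equal(preferred_distance_vector(c(0, 0), c(300, 400), 1, geom),
               (500 - geom$dist_max) * c(0.6, 0.8))
})

test_that("spatial preference matrix is bounded and peaks at the ring", {
  for (k in 1:25) {
    set.seed(k)
    o <- c(runif(1, 0, geom$width), runif(1, 0, geom$height))
    d <- runif(1)
    grid <- spatial_preference_matrix(o, d, geom, 20)
    expect_true(all(grid$D >= 0 & grid$D <= 1))
    # cells at (near) the preferred ring score (near) 1
    dist <- sqrt(outer(grid$cell_x - o[1], grid$cell_y - o[2],
                       function(a, b) a^2 + b^2))
    expect_equal(grid$D, (geom$dist_max - abs(dist - d * geom$dist_max)) /
                   geom$dist_max)
  }
  # d = 0 and a cell exactly dist_max away scores 0
  g0 <- screen_geometry(2, 2)
  grid <- spatial_preference_matrix(c(0.5, 0.5), 0, g0, 2)
  expect_equal(grid$D[2, 2], 1 - sqrt(2) / g0$dist_max)
})

test_that("spatial vector matches the double-loop oracle", {
  for (res in c(2, 3, 5)) {
    for (k in 1:10) {
      set.seed(100 + res * 10 + k)
      o <- c(runif(1, 0, geom$width), runif(1, 0, geom$height))
      p <- c(runif(1, 0, geom$width), runif(1, 0, geom$height))
      d <- runif(1)
      s <- rgamma(1, 2, 2) + 0.05
      grid <- spatial_preference_matrix(o, d, geom, res)
      got <- spatial_vector(p, grid, s)
      want <- spatial_vector_oracle(p, grid, s)
      expect_equal(got, want, tolerance = 1e-10)
      expect_equal(spatial_vector(p, grid, s, sign = "printed"), -want,
                   tolerance = 1e-10)
    }
  }
})

test_that("large spatial sensitivity concentrates pull on the best cell", {
  set.seed(5)
  o <- c(700, 400)
  p <- c(200, 900)
  # preference strengths cluster near 1 on this screen, so driving the
  # resultant onto the single best cell needs a very large exponent
  grid <- spatial_preference_matrix(o, 0.3, geom, 9)
  v <- spatial_vector(p, grid, 5000)
  best <- which(grid$D == max(grid$D), arr.ind = TRUE)[1, ]
  dir_best <- c(grid$cell_x[best[1]], grid$cell_y[best[2]]) - p
  cosine <- sum(v * dir_best) / sqrt(sum(v^2) * sum(dir_best^2))
  expect_gt(cosine, 0.999)
})

test_that("symmetric constant preference cancels", {
  # uniform D over a grid symmetric about the participant
  g0 <- screen_geometry(100, 100)
  grid <- spatial_preference_matrix(c(50, 50), 0.5, g0, 4)
  grid$D[] <- 0.7
  expect_equal(spatial_vector(c(50, 50), grid, 2), c(0, 0))
})

test_that("pace vector copies the opponent's displacement", {
  expect_equal(pace_vector(c(0, 0)), c(0, 0))
  expect_equal(pace_vector(c(2, -3)), c(2, -3))
})

test_that("motivational vector is the exact simplex blend", {
  p <- glop_params(d = 0.5, w_d = 0.5, w_s = 0.3, a = 0.5, s = 1, v = 0)
  expect_equal(
    motivational_vector(c(10, 0), c(0, 10), c(-10, 0), p), c(3, 3))
  p1 <- glop_params(d = 0.5, w_d = 1, w_s = 0, a = 0.5, s = 1, v = 0)
  expect_equal(motivational_vector(c(4, -2), c(9, 9), c(9, 9), p1), c(4, -2))
  expect_equal(motivational_vector(c(0, 0), c(0, 0), c(0, 0), p), c(0, 0))
  # w_p = 1 makes the motivational vector the opponent's velocity
  pp <- glop_params(d = 0.5, w_d = 0, w_s = 0, a = 0.5, s = 1, v = 0)
  expect_equal(motivational_vector(c(4, 4), c(5, 5), c(2, -3), pp), c(2, -3))
  bad <- tibble::tibble(d = .5, w_d = .6, w_s = .6, w_p = .6, a = .5,
                        s = 1, v = 0)
  expect_error(motivational_vector(c(1, 0), c(0, 1), c(0, 0), bad),
               "sum to 1")
})

test_that("motivational vector norm never exceeds the largest component", {
  set.seed(9)
  for (k in 1:200) {
    w <- rgamma(3, 2, 2)
    w <- w / sum(w)
    comps <- matrix(rnorm(6, sd = 20), 2)
    vm <- comps %*% w
    expect_lte(sqrt(sum(vm^2)),
               max(sqrt(colSums(comps^2))) + 1e-12)
  }
})

test_that("movement noise scales with motivational speed", {
  set.seed(3)
  expect_equal(movement_noise(c(3, 4), 0), c(0, 0))
  expect_equal(movement_noise(c(0, 0), 0.7), c(0, 0))
  draws <- replicate(1e5, movement_noise(c(6, 8), 0.5))
  expect_equal(sd(draws[1, ]), 5, tolerance = 0.02)
  expect_equal(sd(draws[2, ]), 5, tolerance = 0.02)
  expect_equal(mean(draws), 0, tolerance = 0.05)
})

test_that("trajectory vector blends autocorrelation and motivation", {
  expect_equal(trajectory_vector(c(7, -1), c(3, 3), c(1, 1), 1), c(7, -1))
  expect_equal(trajectory_vector(c(7, -1), c(3, 3), c(0, 0), 0), c(3, 3))
  expect_equal(trajectory_vector(c(4, 0), c(0, 4), c(0, 0), 0.5), c(2, 2))
})

test_that("glop_step reproduces the composed vector-field equations", {
  cfg <- glop_config()
  p <- glop_params(d = 0.25, w_d = 0.3, w_s = 0.5, a = 0.4, s = 3.2, v = 0)
  st <- agent_state(c(400, 300), c(2, 1))
  op <- agent_state(c(1200, 700), c(-3, 2))
  new <- glop_step(st, op, p, geom, cfg, noise = FALSE)
  v_dist <- preferred_distance_vector(c(400, 300), c(1200, 700), 0.25, geom)
  grid <- spatial_preference_matrix(c(1200, 700), 0.25, geom,
                                    cfg$grid_resolution)
  v_sp <- spatial_vector(c(400, 300), grid, 3.2)
  # discrepancy components are converted to joystick velocity by the
  # control gain before the simplex mixing; pace is already a velocity
  v_m <- motivational_vector(cfg$motiv_gain * v_dist, cfg$motiv_gain * v_sp,
                             pace_vector(c(-3, 2)), p)
  v_t <- trajectory_vector(c(2, 1), v_m, c(0, 0), 0.4)
  if (sqrt(sum(v_t^2)) > cfg$max_speed)
    v_t <- v_t * cfg$max_speed / sqrt(sum(v_t^2))
  expect_equal(new$position, c(400, 300) + v_t, tolerance = 1e-7)
  expect_equal(new$prev_traj, v_t, tolerance = 1e-7)
})

test_that("pure distance pursuit closes on a stationary opponent", {
  cfg <- glop_config()
  p <- glop_params(d = 1e-9, w_d = 1, w_s = 0, a = 0, s = 1, v = 0)
  st <- agent_state(c(100, 100))
  op <- agent_state(c(900, 700))
  d0 <- sqrt(sum((op$position - st$position)^2))
  for (k in 1:3) {
    set.seed(k)
    st <- glop_step(st, op, p, geom, cfg)
    d1 <- sqrt(sum((op$position - st$position)^2))
    expect_equal(d0 - d1, cfg$max_speed, tolerance = 1e-9) # capped approach
    d0 <- d1
  }
})

test_that("full autocorrelation yields straight-line motion", {
  cfg <- glop_config()
  p <- glop_params(d = 0.5, w_d = 0.5, w_s = 0.2, a = 1, s = 1, v = 2)
  st <- agent_state(c(500, 500), c(3, 1))
  op <- agent_state(c(1000, 800), c(1, 1))
  set.seed(1)
  s1 <- glop_step(st, op, p, geom, cfg)
  s2 <- glop_step(s1, op, p, geom, cfg)
  expect_equal(s1$position, c(503, 501))
  expect_equal(s2$position, c(506, 502))
})

test_that("simulated trials are bitwise reproducible under a seed", {
  p <- glop_params(d = 0.15, w_d = 0.4, w_s = 0.4, a = 0.7, s = 2, v = 0.3)
  set.seed(77)
  t1 <- simulate_trial(p, "Wandering", config = tiny_config())
  set.seed(77)
  t2 <- simulate_trial(p, "Wandering", config = tiny_config())
  expect_identical(t1, t2)
})

test_that("collision freezes both agents and clears the alive flag", {
  p <- glop_params(d = 1e-9, w_d = 1, w_s = 0, a = 0, s = 1, v = 0)
  set.seed(2)
  tr <- simulate_trial(p, "Aggressive", config = glop_config(n_frames = 300),
                       p_start = c(500, 500), o_start = c(900, 700))
  expect_true(any(tr$alive == 0))
  expect_true(all(diff(tr$alive) <= 0))
  dead <- which(tr$alive == 0)
  expect_equal(length(unique(tr$p_x[dead])), 1)
  expect_equal(length(unique(tr$o_x[dead])), 1)
  d_end <- sqrt((tr$p_x - tr$o_x)^2 + (tr$p_y - tr$o_y)^2)[dead[1]]
  expect_lt(d_end, glop_config()$collision_radius)
})
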