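test_that("approach index hits its endpoints and is bounded", {
  expect_equal(approach_index(c(3, 4), c(0.6, 0.8)), 1)
  expect_equal(approach_index(c(-3, -4), c(0.6, 0.8)), -1)
  expect_equal(approach_index(c(1, 0), c(0, 1)), 0)
  expect_error(approach_index(c(0, 0), c(1, 0)), "zero-motion")
  set.seed(1)
  for (k in 1:200) {
    step <- rnorm(2)
    t_hat <- rnorm(2)
    t_hat <- t_hat / sqrt(sum(t_hat^2))
    ai <- approach_index(step, t_hat)
    expect_gte(ai, -1 - 1e-12)
    expect_lte(ai, 1 + 1e-12)
  }
})

test_that("summary stats match a hand computation on a toy trial", {
  # participant walks straight east toward an opponent due east
  f <- make_frames(c(0, 0, 1, 0, 2, 0), c(10, 0, 10, 0, 10, 0))
  ss <- summary_stats(f, "Shy")
  expect_equal(ss$profile_code, 2L)
  expect_equal(ss$angle_mean, 0)
  expect_equal(ss$angle_var, 0)
  expect_equal(ss$approach_mean, 1)
  expect_equal(ss$approach_var, 0)

  # 3-frame hand-built trial with motion both toward and orthogonal
  f2 <- make_frames(c(0, 0, 3, 4, 3, 104), c(6, 8, 6, 8, 3, 108))
  # frame angles: atan2(8,6); atan2(4,3); atan2(4,0)
  th <- c(atan2(8, 6), atan2(4, 3), pi / 2)
  cb <- mean(cos(th)); sb <- mean(sin(th))
  # approach: step1 (3,4) vs t_hat (.6,.8) -> 1; step2 (0,100) vs (.6,.8) -> .8
  ai <- c(1, 0.8)
  ss2 <- summary_stats(f2, 1)
  expect_equal(ss2$angle_mean, atan2(sb, cb))
  expect_equal(ss2$angle_var, 1 - sqrt(cb^2 + sb^2))
  expect_equal(ss2$approach_mean, mean(ai))
  expect_equal(ss2$approach_var, var(ai))
})

test_that("degenerate all-stationary trials are flagged", {
  f <- make_frames(matrix(1, 5, 2), matrix(c(500, 400), 5, 2, byrow = TRUE))
  expect_error(summary_stats(f, 1), "degenerate")
  ss <- summary_stats(f, 1, strict = FALSE)
  expect_equal(ss$approach_mean, 0)
})

test_that("estimation input is always 5 x 138 with the summary column first", {
  set.seed(2)
  p <- glop_params(d = 0.2, w_d = 0.5, w_s = 0.3, a = 0.6, s = 1, v = 0.2)
  tr <- simulate_trial(p, "Curious", config = glop_config(n_frames = 600))
  f <- as.matrix(tr[, c("p_x", "p_y", "o_x", "o_y", "alive")])
  for (L in c(2, 3, 50, 137, 400, 600)) {
    inp <- build_estimation_input(f, "Curious", censored_length = L)
    expect_equal(dim(inp), c(5, 138))
    expect_equal(unname(inp[1, 1]), 3) # profile code leads the summary column
    expect_true(all(inp[1, -1] %in% c(0, 1)))
  }
})

test_that("a 137-frame trial passes through the encoder unchanged", {
  set.seed(3)
  p <- glop_params(d = 0.3, w_d = 0.6, w_s = 0.2, a = 0.5, s = 1, v = 0.1)
  tr <- simulate_trial(p, "Shy", config = glop_config(n_frames = 137))
  f <- as.matrix(tr[, c("p_x", "p_y", "o_x", "o_y", "alive")])
  inp <- build_estimation_input(f, "Shy")
  expect_equal(inp[2, -1], unname(f[, "p_x"]))
  expect_equal(inp[5, -1], unname(f[, "o_y"]))
})

test_that("2x downsampling follows the linear midpoint rule", {
  # 274 frames resampled to 137 columns: column k sits at frame 1 + 2.0147(k-1)
  x <- seq_len(274)
  f <- cbind(p_x = x, p_y = 274 - x, o_x = x * 2, o_y = rep(5, 274),
             alive = rep(1, 274))
  inp <- build_estimation_input(f, 1)
  at <- seq(1, 274, length.out = 137)
  expect_equal(inp[2, -1], (1 - (at - floor(at))) * x[floor(at)] +
                 (at - floor(at)) * x[ceiling(at)])
  expect_equal(inp[5, -1], rep(5, 137)) # constant row stays constant
})

test_that("parameter transforms are bijective on prior draws", {
  expect_equal(transform_params(
    glop_params(d = 0.5, w_d = 0.3, w_s = 0.3, a = 0.5, s = 1, v = 1)
  )$logit_d, 0)
  expect_equal(transform_params(
    glop_params(d = 0.5, w_d = 0.3, w_s = 0.3, a = 0.5, s = 1, v = 1)
  )$log_s, 0)
  set.seed(4)
  p <- sample_params(1e4)
  back <- inverse_transform_params(transform_params(p))
  for (nm in c("d", "w_d", "w_s", "w_p", "a", "s", "v")) {
    expect_lt(max(abs(back[[nm]] - p[[nm]])), 1e-9)
  }
})

test_that("boundary parameters are clipped with a warning", {
  p <- tibble::tibble(d = 1e-9, w_d = 0.5, w_s = 0.25, w_p = 0.25, a = 0.5,
                      s = 1, v = 1)
  expect_warning(tp <- transform_params(p), "clipped")
  expect_equal(tp$logit_d, logb(1e-6 / (1 - 1e-6)))
})

test_that("the z-score normalizer matches hand values and is stable", {
  x <- matrix(c(1, 3, 5, 5), ncol = 2)
  expect_warning(nz <- fit_normalizer(x), "zero-variance")
  xn <- apply_normalizer(x, nz)
  expect_equal(xn[, 1], c(-1, 1)) # population SD
  expect_equal(xn[, 2], c(0, 0))  # constant feature normalizes to zero
  # normalized training features have mean 0, population SD 1
  set.seed(5)
  big <- matrix(rnorm(500, mean = 7, sd = 3), ncol = 5)
  nb <- fit_normalizer(big)
  bn <- apply_normalizer(big, nb)
  expect_equal(colMeans(bn), rep(0, 5), tolerance = 1e-12)
  expect_equal(sqrt(colMeans(bn^2)), rep(1, 5), tolerance = 1e-12)
  # refitting on identical data reproduces the stored statistics
  nz2 <- suppressWarnings(fit_normalizer(x))
  expect_identical(nz$mean, nz2$mean)
  expect_identical(nz$sd, nz2$sd)
})
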