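test_that("recovery is 1 for perfect estimates and ~0 for permuted ones", {
  set.seed(1)
  truth <- sample_params(400)
  lengths <- sample(2:600, 400, TRUE)
  rec <- recovery_analysis(truth, truth, lengths)
  expect_true(all(abs(rec$r[!is.na(rec$r)] - 1) < 1e-12))
  perm <- truth[sample(nrow(truth)), ]
  rec2 <- recovery_analysis(truth, perm, lengths)
  overall <- rec2[rec2$bin == "overall", ]
  expect_true(all(abs(overall$r) < 3 / sqrt(400)))
})

test_that("degenerate recovery bins are undefined, not zero", {
  truth <- sample_params(10)
  est <- truth
  est$d <- 0.5 # zero-variance estimates
  rec <- recovery_analysis(truth, est, rep(30, 10))
  expect_true(is.na(rec$r[rec$parameter == "d" & rec$bin == "overall"]))
  # a bin with < 3 trials is undefined
  rec2 <- recovery_analysis(truth, truth, c(rep(30, 8), 300, 550))
  expect_true(is.na(rec2$r[rec2$parameter == "a" & rec2$lower == 8]))
})

test_that("resynchronized prediction of a noiseless trial is exact", {
  set.seed(2)
  p <- glop_params(d = 0.25, w_d = 0.5, w_s = 0.3, a = 0.6, s = 1.4, v = 0)
  tr <- simulate_trial(p, "Curious", config = glop_config(n_frames = 120),
                       p_start = c(500, 600), o_start = c(1400, 500))
  res <- predict_with_resync(p, as.matrix(tr[, 2:6]))
  expect_lt(res$trial_mse, 1e-12)
  expect_equal(res$predicted$p_x, tr$p_x, tolerance = 1e-9)
})

test_that("segment errors match a hand-stepped oracle on a toy trial", {
  # stationary opponent, pure distance pursuit: each predicted step moves
  # max_speed straight toward the opponent from the last observed anchor
  geom <- screen_geometry()
  cfg <- glop_config()
  p <- glop_params(d = 1e-9, w_d = 1, w_s = 0, a = 0, s = 1, v = 0)
  obs_p <- cbind(seq(100, 170, by = 10), rep(100, 8)) # observed: +10 px/frame
  obs_o <- matrix(rep(c(1100, 100), each = 8), ncol = 2)
  frames <- cbind(p_x = obs_p[, 1], p_y = obs_p[, 2], o_x = obs_o[, 1],
                  o_y = obs_o[, 2])
  res <- predict_with_resync(p, frames, resync_every = 4)
  # prediction moves 10 px/frame (speed cap) toward the opponent, same
  # direction as the data, so errors are zero
  expect_equal(res$segment_mse, c(0, 0), tolerance = 1e-9)
  # slower observed movement: +5 px/frame while the model predicts +10
  obs_p2 <- cbind(seq(100, 135, by = 5), rep(100, 8))
  frames2 <- cbind(p_x = obs_p2[, 1], p_y = obs_p2[, 2], o_x = obs_o[, 1],
                   o_y = obs_o[, 2])
  res2 <- predict_with_resync(p, frames2, resync_every = 4)
  # the gap grows 5 px per predicted frame; the first segment spans 4
  # predicted frames, the second only the 3 remaining
  seg1 <- mean(c(25, 100, 225, 400))
  seg2 <- mean(c(25, 100, 225))
  expect_equal(res2$segment_mse, c(seg1, seg2), tolerance = 1e-9)
  expect_equal(res2$trial_mse, mean(c(seg1, seg2)), tolerance = 1e-9)
})

test_that("a constant prediction offset yields its squared norm as MSE", {
  # direct arithmetic on the definition: offset (3,4) at every frame
  err <- rep(3^2 + 4^2, 8)
  expect_equal(mean(err), 25)
})

test_that("ppc aggregation reproduces hand-computed cells and trimming", {
  ppc <- tibble::tibble(trial_id = 1:6,
                        goal = rep(c("Attack", "Avoid"), each = 3),
                        profile = rep("Shy", 6),
                        censored_length = rep(100, 6),
                        mse = c(1, 2, 100, 7, 7, 7))
  agg <- aggregate_ppc(ppc)
  at <- agg[agg$goal == "Attack", ]
  expect_equal(at$mean_mse, mean(c(1, 2, 100)))
  expect_equal(at$median_mse, 2)
  av <- agg[agg$goal == "Avoid", ]
  expect_equal(av$mean_mse, av$median_mse) # identical values in the cell
  # trimming drops the pooled extremes
  big <- tibble::tibble(trial_id = 1:1000, goal = "Attack", profile = "Shy",
                        censored_length = 100,
                        mse = c(rep(1, 990), rep(1000, 10)))
  agg2 <- aggregate_ppc(big, trim_fraction = 0.005)
  expect_lt(agg2$mean_mse, 100) # the 1000-valued tail is largely excluded
  expect_equal(agg2$n[1], 990)  # ceiling(0.5%) = 5 trials dropped per tail
})

test_that("fitted parameters beat mismatched parameters in resync MSE", {
  set.seed(3)
  p_true <- glop_params(d = 0.05, w_d = 0.8, w_s = 0.1, a = 0.3, s = 1,
                        v = 0.1)
  p_bad <- glop_params(d = 0.9, w_d = 0.1, w_s = 0.1, a = 0.9, s = 1, v = 0.1)
  tr <- simulate_trial(p_true, "Shy", config = glop_config(n_frames = 200),
                       p_start = c(300, 300), o_start = c(1000, 700))
  f <- as.matrix(tr[, 2:6])
  mse_true <- predict_with_resync(p_true, f)$trial_mse
  mse_bad <- predict_with_resync(p_bad, f)$trial_mse
  expect_lt(mse_true, mse_bad)
})
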