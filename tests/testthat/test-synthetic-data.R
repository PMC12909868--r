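test_that("prior draws respect bounds and the weight simplex", {
  set.seed(1)
  p <- sample_params(2e4)
  expect_silent(validate_glop_params(p))
  expect_true(all(abs(p$w_d + p$w_s + p$w_p - 1) < 1e-9))
})

test_that("prior draws match the stated distribution means", {
  set.seed(2)
  p <- sample_params(1e6)
  expect_equal(mean(p$d), 0.3 / 0.8, tolerance = 0.005)  # Beta(.3,.5)
  expect_equal(mean(p$a), 5 / 6, tolerance = 0.005)      # Beta(5,1)
  expect_equal(mean(p$s), 1, tolerance = 0.01)           # Gamma(2,2), rate
  expect_equal(mean(p$v), 0.4, tolerance = 0.01)         # Gamma(2,5), rate
  # weights are exchangeable: each averages 1/3
  expect_equal(mean(p$w_d), 1 / 3, tolerance = 0.005)
  expect_equal(mean(p$w_s), 1 / 3, tolerance = 0.005)
})

test_that("training sets balance profiles and reproduce under a seed", {
  cfg <- tiny_config()
  set.seed(3)
  tr <- generate_training_set(20, config = cfg, censor = FALSE)
  expect_lte(nrow(tr), 20)
  expect_true(all(table(tr$profile) <= 4))
  expect_equal(length(unique(round(tr$d, 12))), nrow(tr)) # distinct draws
  expect_true(all(is.na(tr$goal)))
  set.seed(3)
  tr2 <- generate_training_set(20, config = cfg, censor = FALSE)
  expect_identical(tr, tr2)
})

test_that("first-step-collision filter keeps exactly frame-1-alive trials", {
  p <- glop_params(d = 0.2, w_d = 1, w_s = 0, a = 0, s = 1, v = 0)
  f_dead <- make_frames(c(0, 0, 1, 1), c(10, 10, 11, 11), alive = c(0, 0))
  f_late <- make_frames(c(0, 0, 1, 1), c(500, 500, 30, 8), alive = c(1, 0))
  f_ok <- make_frames(c(0, 0, 1, 1), c(500, 500, 499, 499), alive = c(1, 1))
  trials <- dplyr::bind_rows(make_trial(f_dead, params = p),
                             make_trial(f_late, params = p),
                             make_trial(f_ok, params = p))
  kept <- filter_first_step_collisions(trials)
  expect_equal(nrow(kept), 2) # frame-2 collision retained, frame-1 removed
  expect_identical(kept$frames, list(f_late, f_ok))
})

test_that("censoring follows the min(draw, length) rule", {
  p <- glop_params(d = 0.2, w_d = 1, w_s = 0, a = 0.5, s = 1, v = 0)
  short <- make_trial(make_frames(matrix(0, 20, 2), matrix(500, 20, 2)),
                      params = p)
  set.seed(4)
  out <- censor_trials(short, max_steps = 600)
  # a 20-frame trial can never exceed its own length
  expect_lte(out$censored_length, 20)
  expect_gte(out$censored_length, 2)
  # draws above the trial length leave the trial unchanged at full length
  set.seed(5)
  many <- censor_trials(short[rep(1, 200), ], max_steps = 600)
  expect_true(any(many$censored_length == 20))
})

test_that("goal-labeled sets have the 3 x 5 cell structure and d ordering", {
  set.seed(6)
  tr <- generate_goal_labeled_set(3, reps_per_cell = 2,
                                  config = tiny_config())
  expect_equal(nrow(tr), 90) # 3 participants x 3 goals x 5 profiles x 2
  expect_equal(sort(unique(tr$goal)), sort(goal_labels()))
  counts <- table(tr$goal, tr$profile)
  expect_true(all(counts == 6))
  d_means <- tapply(tr$d, tr$goal, mean)
  expect_lt(d_means["Attack"], d_means["Inspect"])
  expect_lt(d_means["Inspect"], d_means["Avoid"])
  # participants are blocks: one parameter draw per participant x goal
  per_block <- tapply(tr$d, interaction(tr$participant, tr$goal),
                      function(x) length(unique(x)))
  expect_true(all(per_block == 1))
})

test_that("generated trials keep the alive flag monotone", {
  set.seed(7)
  tr <- generate_training_set(25, config = glop_config(n_frames = 120))
  ok <- vapply(tr$frames, function(f) all(diff(f[, "alive"]) <= 0),
               logical(1))
  expect_true(all(ok))
  expect_true(all(tr$censored_length >= 2))
  expect_true(all(tr$censored_length == tr$n_frames))
})

test_that("length replication expands trials to every requested prefix", {
  p <- glop_params(d = 0.2, w_d = 1, w_s = 0, a = 0.5, s = 1, v = 0)
  tr <- make_trial(make_frames(matrix(0, 50, 2), matrix(500, 50, 2)),
                   params = p)
  out <- replicate_censored(tr, c(10, 30, 50, 80))
  expect_equal(nrow(out), 3) # 80 exceeds the trial and is dropped
  expect_equal(sort(out$censored_length), c(10, 30, 50))
})

test_that("participant-level splits are disjoint", {
  set.seed(8)
  tr <- generate_goal_labeled_set(6, config = tiny_config())
  sp <- split_participants(tr, n_test = 2, n_val = 1)
  tab <- table(sp$participant, sp$split)
  expect_true(all(rowSums(tab > 0) == 1)) # each participant in one split
  expect_equal(sum(tab[, "test"] > 0), 2)
  expect_equal(sum(tab[, "validation"] > 0), 1)
})
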