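#' Classifier input kinds
#'
#' The five goal-classification networks share one architecture — fully
#' connected layers of 100, 60, 30, 20, 10 and 3 units with swish
#' activations, dropout on the first fully connected layer and a softmax
#' head — and differ only in their input: `"model"` takes the 12
#' posterior mean/variance features from the estimation network,
#' `"position"` takes the resampled 5-channel time series through a gated
#' recurrent front end, `"summary"` takes the 5 summary statistics, and the
#' two ensemble kinds take the concatenated 3-class probability outputs of
#' their (frozen) component networks.
#'
#' @return Character vector of the five input kinds.
#' @export
classifier_kinds <- function() {
  c("model", "position", "summary", "position+model", "summary+model")
}

classifier_input_dim <- function(kind) {
  switch(kind, model = 12L, summary = 5L, position = 5L,
         "position+model" = 6L, "summary+model" = 6L,
         stop("unknown classifier input kind: ", kind))
}

#' Build classifier inputs from a trial table
#'
#' @param trials A trial tibble with `frames`, `profile`, `censored_length`.
#' @param kind One of [classifier_kinds()].
#' @param estimator A trained [train_estimator()] (required for the
#'   `"model"` kind).
#' @param components Named list of the two trained component classifiers
#'   (required for ensemble kinds, e.g. `list(summary = ..., model = ...)`).
#' @param n_draws Dropout draws per trial for the `"model"` kind.
#' @param target_length Resampled series length for the `"position"` kind.
#' @return A feature matrix, or a 3-d array for the `"position"` kind.
#' @export
classifier_inputs <- function(trials, kind, estimator = NULL,
                              components = NULL, n_draws = 100,
                              target_length = 138) {
  kind <- match.arg(kind, classifier_kinds())
  if (kind == "summary") {
    codes <- match(trials$profile, opponent_profiles())
    rows <- lapply(seq_len(nrow(trials)), function(i)
      summary_stats(trials$frames[[i]][seq_len(trials$censored_length[i]), ,
                                       drop = FALSE],
                    codes[i], strict = FALSE))
    return(as.matrix(dplyr::bind_rows(rows)))
  }
  if (kind == "position") {
    x <- encode_trials(trials, target_length)
    return(x[, , -1, drop = FALSE]) # raw series only, no summary column
  }
  if (kind == "model") {
    if (is.null(estimator)) stop("`estimator` required for model-kind inputs")
    return(as.matrix(posterior_features(trials, estimator, n = n_draws)))
  }
  # ensemble kinds: concatenated component class probabilities
  if (is.null(components) || length(components) != 2)
    stop("ensemble kinds need a list of two component classifiers")
  probs <- lapply(components, function(cl)
    as.matrix(predict_goals(trials, cl, estimator = estimator,
                            n_draws = n_draws)[, goal_labels()]))
  do.call(cbind, probs)
}

#' Train a goal classifier
#'
#' Trains one of the five classification networks on a goal-labeled trial
#' table. Splits are taken from the table's `split` column when present
#' (participant-level, see [split_participants()]); otherwise a random
#' trial-level validation fraction is held out. Time-series (`"position"`)
#' networks count `iterations` as minibatch updates with validation every
#' 100 updates; feature networks count them as epochs with validation after
#' each.
#'
#' @param trials A labeled trial tibble with a `goal` column.
#' @param kind One of [classifier_kinds()].
#' @param iterations Minibatch updates (time-series) or epochs (features).
#' @param estimator Trained estimator (for `"model"` inputs).
#' @param components Named list of two trained component classifiers (for
#'   ensembles; they stay frozen).
#' @param lr,batch,p_drop,clipnorm Optimizer settings.
#' @param n_draws Dropout draws for model-kind features.
#' @param target_length Series length for position-kind inputs.
#' @param val_frac Validation fraction when no `split` column exists.
#' @return An object of class `glop_classifier`.
#' @export
train_classifier <- function(trials, kind, iterations = 4685,
                             estimator = NULL, components = NULL, lr = 1e-3,
                             batch = 64, p_drop = 0.5, clipnorm = 5,
                             n_draws = 100, target_length = 138,
                             val_frac = 0.2) {
  kind <- match.arg(kind, classifier_kinds())
  stopifnot("goal" %in% names(trials))
  recurrent <- kind == "position"
  if ("split" %in% names(trials)) {
    if (any(trials$split == "test"))
      trials <- trials[trials$split != "test", , drop = FALSE]
    train_idx <- which(trials$split == "train")
    val_idx <- which(trials$split == "validation")
    if ("participant" %in% names(trials) &&
        length(intersect(trials$participant[train_idx],
                         trials$participant[val_idx])) > 0)
      stop("label leakage: a participant appears in both train and validation")
  } else {
    n <- nrow(trials)
    val_idx <- sort(sample(n, max(1, round(val_frac * n))))
    train_idx <- setdiff(seq_len(n), val_idx)
  }
  x <- classifier_inputs(trials, kind, estimator, components, n_draws,
                         target_length)
  y <- goal_onehot(trials$goal)
  norm <- quiet_zero_variance(
    if (recurrent) fit_normalizer(x[train_idx, , , drop = FALSE])
    else fit_normalizer(x[train_idx, , drop = FALSE]))
  xn <- apply_normalizer(x, norm)
  net <- cpp_net_init(recurrent, classifier_input_dim(kind),
                      if (recurrent) as.integer(target_length - 1) else 0L,
                      c(100L, 60L, 30L, 20L, 10L), 3L, "softmax", p_drop)
  fit <- cpp_net_train(net, xn, y, train_idx, val_idx,
                       as.integer(iterations), recurrent, as.integer(batch),
                       lr, clipnorm, if (recurrent) 100L else 0L)
  structure(
    list(net = fit$net, kind = kind, normalizer = norm,
         components = components, target_length = as.integer(target_length),
         n_draws = as.integer(n_draws), history = net_history(fit$history),
         iterations = as.integer(iterations),
         n_train = length(train_idx), n_val = length(val_idx)),
    class = "glop_classifier"
  )
}

goal_onehot <- function(goal) {
  lv <- goal_labels()
  stopifnot(all(goal %in% lv))
  y <- matrix(0, length(goal), length(lv), dimnames = list(NULL, lv))
  y[cbind(seq_along(goal), match(goal, lv))] <- 1
  y
}

#' @export
print.glop_classifier <- function(x, ...) {
  cat(sprintf("<glop_classifier> kind = %s (%d iterations)\n", x$kind,
              x$iterations))
  va <- x$history$value[x$history$metric == "val_acc"]
  if (length(va))
    cat(sprintf("  final validation accuracy: %.1f%%\n",
                100 * utils::tail(va, 1)))
  invisible(x)
}

#' Predict goal probabilities
#'
#' @param trials A trial tibble.
#' @param classifier A trained [train_classifier()] object.
#' @param estimator Trained estimator, needed when the classifier (or an
#'   ensemble component) uses model-kind inputs.
#' @param n_draws Dropout draws for model-kind features.
#' @return A tibble with columns `Attack`, `Avoid`, `Inspect` (probabilities
#'   summing to 1) and `predicted` (argmax label).
#' @export
predict_goals <- function(trials, classifier, estimator = NULL,
                          n_draws = classifier$n_draws %||% 100) {
  x <- classifier_inputs(trials, classifier$kind, estimator,
                         classifier$components, n_draws,
                         classifier$target_length)
  xn <- apply_normalizer(x, classifier$normalizer)
  p <- cpp_net_predict(classifier$net, xn, FALSE)
  colnames(p) <- goal_labels()
  out <- tibble::as_tibble(p)
  out$predicted <- goal_labels()[max.col(p, ties.method = "first")]
  out
}

#' Real-time goal classification over a growing trial
#'
#' Feeds every prefix of a trial (at a fixed frame stride) through the
#' classifier, emulating frame-by-frame intent inference during play.
#'
#' @param trial A one-row trial tibble.
#' @param classifier A trained classifier.
#' @param stride Frames between evaluation points.
#' @param estimator Trained estimator for model-kind inputs.
#' @return A tibble with one row per evaluation point: `frame`, the three
#'   class probabilities, and `predicted`.
#' @export
classify_realtime <- function(trial, classifier, stride = 60,
                              estimator = NULL) {
  stopifnot(nrow(trial) == 1)
  L <- trial$censored_length[1]
  points <- unique(c(seq(max(2, stride), L, by = stride), L))
  prefixes <- replicate_censored(trial, points)
  out <- predict_goals(prefixes, classifier, estimator)
  out$frame <- prefixes$censored_length
  dplyr::relocate(out, "frame")
}

#' Evaluate a goal classifier
#'
#' Accuracy is the fraction of trials whose argmax prediction matches the
#' true goal; the log likelihood sums, over trials, the log of the
#' probability assigned to the true class (floored at 1e-12 with a warning).
#'
#' @param trials A labeled trial tibble (disjoint from training data).
#' @param classifier A trained classifier.
#' @param estimator Trained estimator for model-kind inputs.
#' @return A one-row tibble with `n`, `accuracy` and `log_lik`.
#' @export
evaluate_classifier <- function(trials, classifier, estimator = NULL) {
  pred <- predict_goals(trials, classifier, estimator)
  p_true <- as.matrix(pred[, goal_labels()])[
    cbind(seq_len(nrow(trials)), match(trials$goal, goal_labels()))]
  if (any(p_true < 1e-12)) {
    warning("true-class probabilities of 0 floored at 1e-12")
    p_true <- pmax(p_true, 1e-12)
  }
  tibble::tibble(
    n = nrow(trials),
    accuracy = mean(pred$predicted == trials$goal),
    log_lik = sum(log(p_true))
  )
}

#' @export
tidy.glop_classifier <- function(x, ...) x$history

#' @export
glance.glop_classifier <- function(x, ...) {
  va <- x$history$value[x$history$metric == "val_acc"]
  ta <- x$history$value[x$history$metric == "train_acc"]
  tibble::tibble(
    kind = x$kind, iterations = x$iterations, n_train = x$n_train,
    n_val = x$n_val,
    final_train_acc = if (length(ta)) utils::tail(ta, 1) else NA_real_,
    final_val_acc = if (length(va)) utils::tail(va, 1) else NA_real_
  )
}
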