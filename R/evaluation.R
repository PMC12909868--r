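#' Parameter-recovery analysis
#'
#' Pearson correlations between generating and estimated parameter values,
#' overall and within censored-length bins, the standard check that a
#' simulation-based estimator identifies its parameters. Bins with fewer
#' than 3 trials, or with zero variance in either series, are reported as
#' `NA` rather than 0.
#'
#' @param truth Data frame of generating parameters (columns
#'   `d, w_d, w_s, a, s, v`; extra columns ignored).
#' @param estimates Data frame of estimated parameters, same rows.
#' @param lengths Censored lengths in frames, one per row.
#' @param bin_edges Bin edges in seconds over the trial duration.
#' @param fps Frame rate used to convert lengths to seconds.
#' @return A tibble of class `glop_recovery` with columns `parameter`,
#'   `bin` (factor, `"overall"` plus one level per bin), `lower`, `upper`
#'   (seconds), `n` and `r`.
#' @export
recovery_analysis <- function(truth, estimates, lengths,
                              bin_edges = c(0, 2, 4, 6, 8, 10), fps = 60) {
  pars <- c("d", "w_d", "w_s", "a", "s", "v")
  stopifnot(all(pars %in% names(truth)), all(pars %in% names(estimates)),
            nrow(truth) == nrow(estimates),
            length(lengths) == nrow(truth))
  secs <- lengths / fps
  bin <- cut(secs, breaks = bin_edges, include.lowest = FALSE)
  safe_r <- function(a, b) {
    if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0)
      return(NA_real_)
    stats::cor(a, b)
  }
  rows <- list()
  for (p in pars) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      parameter = p, bin = "overall", lower = min(bin_edges),
      upper = max(bin_edges), n = nrow(truth),
      r = safe_r(truth[[p]], estimates[[p]])
    )
    for (k in seq_len(length(bin_edges) - 1)) {
      sel <- which(as.integer(bin) == k)
      rows[[length(rows) + 1]] <- tibble::tibble(
        parameter = p, bin = levels(bin)[k], lower = bin_edges[k],
        upper = bin_edges[k + 1], n = length(sel),
        r = safe_r(truth[[p]][sel], estimates[[p]][sel])
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$parameter <- factor(out$parameter, levels = pars)
  class(out) <- c("glop_recovery", class(out))
  out
}

#' Resynchronized trajectory prediction
#'
#' Simulates the participant's mean trajectory (movement noise disabled)
#' under a given parameter set against the observed opponent positions,
#' resynchronizing the predicted position (and previous-step vector) with
#' the observed participant trajectory every `resync_every` frames so long
#' trials cannot drift arbitrarily far. Prediction error is the mean squared
#' Euclidean pixel distance between predicted and observed participant
#' positions within each segment before resynchronization.
#'
#' @param params A [glop_params()] row (or any one-row data frame with the
#'   seven parameter columns).
#' @param frames Observed frame matrix (columns `p_x, p_y, o_x, o_y`, at
#'   least 2 rows; typically truncated to the censored length).
#' @param resync_every Frames between resynchronizations (default 4, i.e.
#'   15 times per second at 60 Hz).
#' @param geom,config Geometry and configuration.
#' @return A list with `predicted` (tibble `frame, p_x, p_y`),
#'   `segment_mse` (numeric vector, px^2) and `trial_mse` (mean of segment
#'   MSEs).
#' @export
predict_with_resync <- function(params, frames, resync_every = 4,
                                geom = screen_geometry(),
                                config = glop_config()) {
  validate_glop_params(params)
  stopifnot(nrow(frames) >= 2)
  obs <- as.matrix(frames[, c("p_x", "p_y", "o_x", "o_y")])
  res <- cpp_predict_resync(as_param_vector(params), obs,
                            as.integer(resync_every), unclass(geom),
                            unclass(config))
  list(
    predicted = tibble::tibble(frame = seq_len(nrow(obs)),
                               p_x = res$predicted[, 1],
                               p_y = res$predicted[, 2]),
    segment_mse = as.numeric(res$segment_mse),
    trial_mse = mean(res$segment_mse)
  )
}

#' Posterior predictive check over a trial table
#'
#' Runs [predict_with_resync()] for every trial under the supplied
#' parameter estimates and collects per-trial mean squared errors.
#'
#' @param trials A trial tibble (`frames`, `censored_length`, and `goal` /
#'   `profile` labels if present).
#' @param estimates Data frame of fitted parameters, one row per trial
#'   (must include the seven parameter columns; `w_p` is recomputed from
#'   `w_d` and `w_s` if missing).
#' @param resync_every,geom,config Passed to [predict_with_resync()].
#' @return A tibble with `trial_id` (row index), `goal`, `profile`,
#'   `censored_length` and `mse`.
#' @export
ppc_analysis <- function(trials, estimates, resync_every = 4,
                         geom = screen_geometry(), config = glop_config()) {
  stopifnot(nrow(trials) == nrow(estimates))
  if (!"w_p" %in% names(estimates))
    estimates$w_p <- 1 - estimates$w_d - estimates$w_s
  # estimated weights come from independent logits; renormalize any draw
  # that left the simplex so the simulator's convexity contract holds
  neg <- estimates$w_p < 0
  if (any(neg)) {
    tot <- estimates$w_d[neg] + estimates$w_s[neg]
    estimates$w_d[neg] <- estimates$w_d[neg] / tot
    estimates$w_s[neg] <- estimates$w_s[neg] / tot
    estimates$w_p[neg] <- 0
  }
  mse <- numeric(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    f <- trials$frames[[i]][seq_len(trials$censored_length[i]), ,
                            drop = FALSE]
    mse[i] <- predict_with_resync(estimates[i, ], f, resync_every, geom,
                                  config)$trial_mse
  }
  tibble::tibble(
    trial_id = trials$trial_id %||% seq_len(nrow(trials)),
    goal = trials$goal %||% NA_character_,
    profile = trials$profile %||% NA_character_,
    censored_length = trials$censored_length,
    mse = mse
  )
}

#' Aggregate posterior-predictive errors by goal and profile
#'
#' Mean and median per-trial MSE for each goal-by-profile cell, optionally
#' after symmetric trimming of the pooled MSE distribution (e.g.
#' `trim_fraction = 0.005` drops 0.5% of trials in each tail, retaining
#' 99%) to blunt the strong right skew of prediction errors.
#'
#' @param ppc A tibble from [ppc_analysis()].
#' @param trim_fraction Fraction trimmed per tail of the pooled
#'   distribution (0 = no trimming).
#' @return A tibble with `goal`, `profile`, `n`, `mean_mse`, `median_mse`.
#' @export
aggregate_ppc <- function(ppc, trim_fraction = 0) {
  stopifnot(trim_fraction >= 0, trim_fraction < 0.5)
  if (trim_fraction > 0) {
    # drop ceiling(trim * n) trials from each tail of the pooled distribution
    k <- ceiling(trim_fraction * nrow(ppc))
    ord <- order(ppc$mse)
    keep <- ord[seq.int(k + 1, nrow(ppc) - k)]
    ppc <- ppc[sort(keep), , drop = FALSE]
  }
  dplyr::summarise(
    dplyr::group_by(ppc, .data$goal, .data$profile),
    n = dplyr::n(),
    mean_mse = mean(.data$mse),
    median_mse = stats::median(.data$mse),
    .groups = "drop"
  )
}
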