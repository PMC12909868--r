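#' Approach index
#'
#' Signed cosine of the angle between the participant's displacement and the
#' unit vector toward the opponent: 1 when moving straight at the opponent,
#' -1 when moving straight away, 0 when moving orthogonally.
#'
#' @param p_step Participant displacement (length-2, px/frame, nonzero).
#' @param t_hat Unit vector toward the opponent.
#' @return Scalar in `[-1, 1]`.
#' @export
approach_index <- function(p_step, t_hat) {
  nrm <- sqrt(sum(p_step^2))
  if (nrm == 0) stop("zero-motion frame: approach index undefined")
  sum(p_step * t_hat) / nrm
}

#' Summary statistics of a (censored) trial
#'
#' Five scalar features: the opponent profile code (1-5), the circular mean
#' and circular variance of the direction angle of the participant-to-
#' opponent vector, and the mean and variance of the per-frame approach
#' index. Zero-motion frames are skipped for the approach series; an
#' all-stationary participant is a degenerate trial and errors unless
#' `strict = FALSE`, in which case the approach statistics are zero.
#'
#' @param frames Matrix with columns `p_x, p_y, o_x, o_y` (and optionally
#'   `alive`), already truncated to the censored length.
#' @param profile Opponent profile name or code 1-5.
#' @param strict Error on degenerate (all-stationary) trials?
#' @return A one-row tibble: `profile_code`, `angle_mean`, `angle_var`,
#'   `approach_mean`, `approach_var`.
#' @export
summary_stats <- function(frames, profile, strict = TRUE) {
  stopifnot(nrow(frames) >= 2)
  code <- if (is.character(profile)) match(profile, opponent_profiles())
          else as.integer(profile)
  if (is.na(code) || code < 1 || code > 5) stop("invalid opponent profile")
  dx <- frames[, 3] - frames[, 1]
  dy <- frames[, 4] - frames[, 2]
  sep <- sqrt(dx^2 + dy^2)
  ok <- sep > 0
  if (any(ok)) {
    theta <- atan2(dy[ok], dx[ok])
    cbar <- mean(cos(theta))
    sbar <- mean(sin(theta))
    angle_mean <- atan2(sbar, cbar)
    angle_var <- 1 - sqrt(cbar^2 + sbar^2) # circular variance, 1 - R
  } else {
    angle_mean <- 0
    angle_var <- 0
  }
  n <- nrow(frames)
  sx <- diff(frames[, 1])
  sy <- diff(frames[, 2])
  spd <- sqrt(sx^2 + sy^2)
  move <- spd > 0 & sep[-n] > 0
  if (!any(move)) {
    if (strict) stop("degenerate trial: participant never moves")
    approach_mean <- 0
    approach_var <- 0
  } else {
    ai <- (sx[move] * dx[-n][move] + sy[move] * dy[-n][move]) /
      (spd[move] * sep[-n][move])
    approach_mean <- mean(ai)
    approach_var <- if (sum(move) > 1) stats::var(ai) else 0
  }
  tibble::tibble(profile_code = code, angle_mean = angle_mean,
                 angle_var = angle_var, approach_mean = approach_mean,
                 approach_var = approach_var)
}

#' Fixed-length network input for one trial
#'
#' Encodes a censored trial as the 5 x `target_length` matrix the estimation
#' network consumes: column 1 carries the five summary statistics, columns
#' 2 to `target_length` carry the trial's `(alive, p_x, p_y, o_x, o_y)`
#' series resampled to `target_length - 1` time points by linear
#' interpolation (nearest neighbor for the alive flag, which stays binary).
#' Resampling reconciles variable censored lengths with the fixed input
#' shape.
#'
#' @param frames Matrix with columns `p_x, p_y, o_x, o_y, alive`.
#' @param profile Opponent profile name or code.
#' @param censored_length Number of leading frames to encode (>= 2).
#' @param target_length Total number of columns (default 138).
#' @param strict Passed to [summary_stats()].
#' @param method Time-axis layout: `"resample"` (default) stretches the
#'   censored prefix over all 137 columns by linear interpolation;
#'   `"decimate"` samples the censored prefix on the fixed 137-point grid
#'   spanning the full trial horizon and zero-pads columns beyond the
#'   censored length, so every column advances time by the same interval;
#'   `"recent"` encodes the last 137 frames at full rate, left-padded.
#' @param horizon Nominal full trial length in frames (time base of the
#'   `"decimate"` grid).
#' @return A 5 x `target_length` numeric matrix, rows
#'   `(summary | alive, p_x, p_y, o_x, o_y)`.
#' @export
build_estimation_input <- function(frames, profile, censored_length =
                                     nrow(frames), target_length = 138,
                                   strict = FALSE,
                                   method = c("resample", "decimate",
                                              "recent"),
                                   horizon = 600) {
  method <- match.arg(method)
  stopifnot(censored_length >= 2, censored_length <= nrow(frames),
            target_length >= 2)
  f <- frames[seq_len(censored_length), , drop = FALSE]
  ss <- summary_stats(f, profile, strict = strict)
  nt <- target_length - 1
  series <- matrix(0, 5, nt)
  if (method == "resample") {
    at <- seq(1, censored_length, length.out = nt)
  } else if (method == "decimate") {
    at <- round(seq(1, max(horizon, censored_length), length.out = nt))
    at <- at[at <= censored_length]
  } else { # recent
    at <- seq(max(1, censored_length - nt + 1), censored_length)
  }
  lo <- floor(at)
  hi <- ceiling(at)
  wfrac <- at - lo
  keep <- seq_along(at)
  if (method == "recent") keep <- nt - length(at) + seq_along(at)
  series[1, keep] <- f[, "alive"][round(at)]
  series[2, keep] <- (1 - wfrac) * f[lo, "p_x"] + wfrac * f[hi, "p_x"]
  series[3, keep] <- (1 - wfrac) * f[lo, "p_y"] + wfrac * f[hi, "p_y"]
  series[4, keep] <- (1 - wfrac) * f[lo, "o_x"] + wfrac * f[hi, "o_x"]
  series[5, keep] <- (1 - wfrac) * f[lo, "o_y"] + wfrac * f[hi, "o_y"]
  out <- cbind(
    c(ss$profile_code, ss$angle_mean, ss$angle_var, ss$approach_mean,
      ss$approach_var),
    series
  )
  rownames(out) <- c("alive", "p_x", "p_y", "o_x", "o_y")
  out
}

#' Encode a trial table for the estimation network
#'
#' Applies [build_estimation_input()] to every row of a trial tibble and
#' stacks the results into an `n x 5 x target_length` array (sample by
#' channel by time), the layout the network trainer consumes.
#'
#' @param trials A trial tibble with `frames`, `profile` and
#'   `censored_length` columns.
#' @param target_length Number of input columns (default 138).
#' @param method,horizon Passed to [build_estimation_input()].
#' @return Numeric array of dimension `c(nrow(trials), 5, target_length)`.
#' @export
encode_trials <- function(trials, target_length = 138,
                          method = "resample", horizon = 600) {
  n <- nrow(trials)
  out <- array(0, dim = c(n, 5, target_length))
  codes <- match(trials$profile, opponent_profiles())
  for (i in seq_len(n)) {
    out[i, , ] <- build_estimation_input(trials$frames[[i]], codes[i],
                                         trials$censored_length[i],
                                         target_length, method = method,
                                         horizon = horizon)
  }
  out
}

# evaluate an expression with the expected zero-variance normalizer warning
# muffled (the alive channel is constant over early columns by design)
quiet_zero_variance <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("zero-variance", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

logit <- function(x) log(x / (1 - x))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Transform GLOP parameters to the unconstrained scale
#'
#' Doubly bounded parameters (`d`, `w_d`, `w_s`, `a`) are logit-transformed
#' and positive parameters (`s`, `v`) log-transformed, so the estimation
#' network can regress on unconstrained targets whose inverse maps always
#' respect the theoretical ranges. Values at the boundary are clipped to
#' `[1e-6, 1 - 1e-6]` with a warning.
#'
#' @param params A data frame with the seven parameter columns.
#' @return A tibble with columns
#'   `logit_d, logit_w_d, logit_w_s, logit_a, log_s, log_v`.
#' @export
transform_params <- function(params) {
  clip <- function(x) {
    if (any(x < 1e-6 | x > 1 - 1e-6)) {
      warning("boundary parameter values clipped before logit transform")
      x <- pmin(pmax(x, 1e-6), 1 - 1e-6)
    }
    x
  }
  clip_pos <- function(x) {
    if (any(x < 1e-6)) {
      warning("near-zero parameter values clipped before log transform")
      x <- pmax(x, 1e-6)
    }
    x
  }
  tibble::tibble(
    logit_d = logit(clip(params$d)),
    logit_w_d = logit(clip(params$w_d)),
    logit_w_s = logit(clip(params$w_s)),
    logit_a = logit(clip(params$a)),
    log_s = log(clip_pos(params$s)),
    log_v = log(clip_pos(params$v))
  )
}

#' @rdname transform_params
#' @param transformed A data frame as returned by [transform_params()].
#' @return For `inverse_transform_params()`: a tibble with the seven natural
#'   parameters, `w_p` reconstructed as `1 - w_d - w_s`.
#' @export
inverse_transform_params <- function(transformed) {
  w_d <- inv_logit(transformed$logit_w_d)
  w_s <- inv_logit(transformed$logit_w_s)
  tibble::tibble(
    d = inv_logit(transformed$logit_d),
    w_d = w_d, w_s = w_s, w_p = 1 - w_d - w_s,
    a = inv_logit(transformed$logit_a),
    s = exp(transformed$log_s),
    v = exp(transformed$log_v)
  )
}

transformed_names <- function() {
  c("logit_d", "logit_w_d", "logit_w_s", "logit_a", "log_s", "log_v")
}

#' Z-score normalizer
#'
#' Fits per-feature means and standard deviations on training data only;
#' the stored normalizer is then reused for validation, test and deployment
#' inputs. Zero-variance features get SD 1 (with a warning) so constant
#' features normalize to zero.
#'
#' @param x Numeric matrix (samples x features) or 3-d array
#'   (samples x channels x time), which is treated as a flattened feature
#'   matrix.
#' @return A list of class `glop_normalizer` with `mean`, `sd` and `dim`.
#' @export
fit_normalizer <- function(x) {
  dm <- dim(x)
  if (length(dm) == 3) x <- matrix(x, nrow = dm[1])
  mu <- colMeans(x)
  # population SD: a two-point feature {1, 3} normalizes to {-1, 1}
  sd <- sqrt(colMeans(sweep(x, 2, mu, "-")^2))
  if (nrow(x) < 2) sd[] <- NA
  zero <- !is.finite(sd) | sd == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance feature(s); SD replaced by 1")
    sd[zero] <- 1
  }
  structure(list(mean = mu, sd = sd, dim = dm[-1]), class = "glop_normalizer")
}

#' @rdname fit_normalizer
#' @param normalizer A fitted `glop_normalizer`.
#' @return For `apply_normalizer()`: the normalized input with the original
#'   shape.
#' @export
apply_normalizer <- function(x, normalizer) {
  dm <- dim(x)
  flat <- if (length(dm) == 3) matrix(x, nrow = dm[1]) else x
  flat <- sweep(flat, 2, normalizer$mean, "-")
  flat <- sweep(flat, 2, normalizer$sd, "/")
  if (length(dm) == 3) array(flat, dim = dm) else flat
}
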