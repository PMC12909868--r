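#' GLOP generative parameters
#'
#' The seven free parameters of the global-local objective pursuit model:
#' preferred distance `d` (fraction of the screen diagonal), the three
#' motivational weights `w_d` (distance strength), `w_s` (spatial strength)
#' and `w_p` (pace matching) which live on the unit simplex, autocorrelation
#' `a`, spatial sensitivity `s` and movement variability `v`.
#'
#' @param d Preferred distance in (0, 1), as a fraction of `dist_max`.
#' @param w_d,w_s,w_p Motivational weights in `[0, 1]`, summing to 1. `w_p`
#'   defaults to `1 - w_d - w_s`.
#' @param a Autocorrelation weight in (0, 1).
#' @param s Spatial sensitivity exponent, positive.
#' @param v Movement variability scale, non-negative.
#' @return A one-row tibble of class `glop_params`.
#' @examples
#' glop_params(d = 0.2, w_d = 0.5, w_s = 0.3, a = 0.8, s = 1.5, v = 0.2)
#' @export
glop_params <- function(d, w_d, w_s, w_p = 1 - w_d - w_s, a, s, v) {
  p <- tibble::tibble(d = as.numeric(d), w_d = as.numeric(w_d),
                      w_s = as.numeric(w_s), w_p = as.numeric(w_p),
                      a = as.numeric(a), s = as.numeric(s), v = as.numeric(v))
  validate_glop_params(p)
  class(p) <- c("glop_params", class(p))
  p
}

param_names <- function() c("d", "w_d", "w_s", "w_p", "a", "s", "v")

#' Validate GLOP parameter rows
#'
#' Checks bounds and the weight-simplex constraint `w_d + w_s + w_p = 1`
#' (tolerance 1e-9) for every row of a parameter table.
#'
#' @param params A data frame with columns `d, w_d, w_s, w_p, a, s, v`.
#' @param tol Simplex tolerance.
#' @return `params`, invisibly; errors on violation.
#' @export
validate_glop_params <- function(params, tol = 1e-9) {
  stopifnot(all(param_names() %in% names(params)))
  with(params, {
    if (any(d <= 0 | d >= 1)) stop("`d` must lie strictly in (0, 1)")
    if (any(w_d < 0 | w_d > 1 | w_s < 0 | w_s > 1 | w_p < 0 | w_p > 1))
      stop("weights must lie in [0, 1]")
    if (any(abs(w_d + w_s + w_p - 1) > tol))
      stop("weights must sum to 1 (w_d + w_s + w_p = 1)")
    if (any(a < 0 | a > 1)) stop("`a` must lie in [0, 1]")
    if (any(s <= 0)) stop("`s` must be positive")
    if (any(v < 0)) stop("`v` must be non-negative")
  })
  invisible(params)
}

as_param_vector <- function(params, row = 1) {
  unlist(params[row, param_names()], use.names = TRUE)
}

#' Prior distributions over GLOP parameters
#'
#' The sampling distributions used to generate training data for amortized
#' estimation: `d ~ Beta(0.3, 0.5)`, the three motivational weights drawn
#' independently from `Gamma(2, 2)` and normalized to the simplex,
#' `a ~ Beta(5, 1)`, `s ~ Gamma(2, 2)` and `v ~ Gamma(2, 5)`. Gamma entries
#' are shape/rate.
#'
#' @param d_shape1,d_shape2 Beta parameters for `d`.
#' @param w_shape,w_rate Gamma parameters shared by the three weights.
#' @param a_shape1,a_shape2 Beta parameters for `a`.
#' @param s_shape,s_rate Gamma parameters for `s`.
#' @param v_shape,v_rate Gamma parameters for `v`.
#' @return A list of class `glop_prior`.
#' @examples
#' pr <- glop_prior()
#' sample_params(5, pr)
#' @export
glop_prior <- function(d_shape1 = 0.3, d_shape2 = 0.5,
                       w_shape = 2, w_rate = 2,
                       a_shape1 = 5, a_shape2 = 1,
                       s_shape = 2, s_rate = 2,
                       v_shape = 2, v_rate = 5) {
  structure(
    list(d_shape1 = d_shape1, d_shape2 = d_shape2, w_shape = w_shape,
         w_rate = w_rate, a_shape1 = a_shape1, a_shape2 = a_shape2,
         s_shape = s_shape, s_rate = s_rate, v_shape = v_shape,
         v_rate = v_rate),
    class = "glop_prior"
  )
}

#' Sample GLOP parameters from the prior
#'
#' @param n Number of parameter draws.
#' @param prior A [glop_prior()].
#' @return A tibble with `n` rows and columns `d, w_d, w_s, w_p, a, s, v`;
#'   weight rows sum to one by construction.
#' @export
sample_params <- function(n, prior = glop_prior()) {
  stopifnot(inherits(prior, "glop_prior"), n >= 1)
  d <- stats::rbeta(n, prior$d_shape1, prior$d_shape2)
  g <- matrix(stats::rgamma(3 * n, shape = prior$w_shape, rate = prior$w_rate),
              ncol = 3)
  g <- g / rowSums(g)
  a <- stats::rbeta(n, prior$a_shape1, prior$a_shape2)
  s <- stats::rgamma(n, shape = prior$s_shape, rate = prior$s_rate)
  v <- stats::rgamma(n, shape = prior$v_shape, rate = prior$v_rate)
  # keep bounded parameters strictly interior so logit transforms are finite
  eps <- 1e-6
  tibble::tibble(
    d = pmin(pmax(d, eps), 1 - eps),
    w_d = g[, 1], w_s = g[, 2], w_p = g[, 3],
    a = pmin(pmax(a, eps), 1 - eps),
    s = pmax(s, eps), v = pmax(v, eps)
  )
}

#' Goal-conditional parameter distributions
#'
#' Synthetic stand-in for the empirical relation between a player's assigned
#' goal and their movement parameters: preferred distance is lowest when
#' attacking, intermediate when inspecting and highest when avoiding. Each
#' goal maps to a Beta distribution over `d`; the remaining parameters come
#' from the shared prior.
#'
#' @param attack,inspect,avoid Length-2 numeric vectors of Beta shape
#'   parameters for `d` under each goal.
#' @param prior A [glop_prior()] supplying the non-`d` parameters.
#' @param w_shape Length-3 Gamma shape parameters for the motivational
#'   weights `(w_d, w_s, w_p)` before simplex normalization; the default
#'   `c(2, 2, 2)` matches the exchangeable prior, while asymmetric shapes
#'   express goal populations whose motivation leans on one component
#'   (e.g. strongly distance-driven players).
#' @return A list of class `label_param_map`.
#' @examples
#' m <- label_param_map()
#' @export
label_param_map <- function(attack = c(1, 9), inspect = c(4, 8),
                            avoid = c(9, 3), prior = glop_prior(),
                            w_shape = c(2, 2, 2)) {
  stopifnot(length(w_shape) == 3, all(w_shape > 0))
  structure(
    list(d_beta = list(Attack = attack, Inspect = inspect, Avoid = avoid),
         prior = prior, w_shape = w_shape),
    class = "label_param_map"
  )
}

#' @rdname label_param_map
#' @param n Number of draws.
#' @param map A [label_param_map()].
#' @param goal One of `"Attack"`, `"Avoid"`, `"Inspect"`.
#' @export
sample_goal_params <- function(n, map, goal) {
  stopifnot(inherits(map, "label_param_map"),
            goal %in% names(map$d_beta))
  p <- sample_params(n, map$prior)
  sh <- map$d_beta[[goal]]
  eps <- 1e-6
  p$d <- pmin(pmax(stats::rbeta(n, sh[1], sh[2]), eps), 1 - eps)
  if (any(map$w_shape != 2)) {
    g <- matrix(stats::rgamma(3 * n, shape = rep(map$w_shape, each = n),
                              rate = 2), ncol = 3)
    g <- g / rowSums(g)
    p$w_d <- g[, 1]
    p$w_s <- g[, 2]
    p$w_p <- g[, 3]
  }
  p
}

#' Goal labels
#' @return Character vector `c("Attack", "Avoid", "Inspect")`.
#' @export
goal_labels <- function() c("Attack", "Avoid", "Inspect")
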