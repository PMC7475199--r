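#' Intrinsic palatability of the two foods
#'
#' The model distinguishes two food groups, healthy (H, e.g. fruits and
#' vegetables) and unhealthy (U). Each has a fixed intrinsic palatability
#' `beta` that acts as the ceiling of learned preference: an agent's perceived
#' valuation converges toward it under repeated consumption. Both are
#' normalized to 1 by default, so learned preference lives on a common
#' \[0, 1) scale.
#'
#' @param beta_h Intrinsic palatability of healthy food (> 0). Default 1.
#' @param beta_u Intrinsic palatability of unhealthy food (> 0). Default 1.
#' @return An object of class `palatability`.
#' @examples
#' palatability()
#' @export
palatability <- function(beta_h = 1, beta_u = 1) {
  if (!is_scalar_number(beta_h) || beta_h <= 0)
    stop("`beta_h` must be a single number > 0", call. = FALSE)
  if (!is_scalar_number(beta_u) || beta_u <= 0)
    stop("`beta_u` must be a single number > 0", call. = FALSE)
  structure(list(beta_h = beta_h, beta_u = beta_u), class = "palatability")
}

#' An agent's preference state
#'
#' Holds the perceived valuation of healthy food `v_hat_h` (starts at 0:
#' preference completely unformed), the perceived valuation of unhealthy food
#' `v_hat_u` (fixed at 1: that preference is fully formed from the outset and
#' is never updated), and the agent's learning speed `alpha`, the fraction of
#' the prediction error absorbed at each healthy-consumption event.
#'
#' @param v_hat_h Perceived valuation of healthy food, in \[0, 1). Default 0.
#' @param v_hat_u Perceived valuation of unhealthy food; fixed at 1.
#' @param alpha Learning speed, in (0, 1].
#' @return An object of class `preference_state`.
#' @examples
#' preference_state(alpha = 0.05)
#' @export
preference_state <- function(v_hat_h = 0, v_hat_u = 1, alpha) {
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha > 1)
    stop("`alpha` must be a single number in (0, 1]", call. = FALSE)
  if (!is_scalar_number(v_hat_h) || v_hat_h < 0 || v_hat_h >= 1)
    stop("`v_hat_h` must be a single number in [0, 1)", call. = FALSE)
  if (!is_scalar_number(v_hat_u) || v_hat_u != 1)
    stop("`v_hat_u` is fixed at 1 in this model", call. = FALSE)
  structure(list(v_hat_h = v_hat_h, v_hat_u = v_hat_u, alpha = alpha),
            class = "preference_state")
}

#' @export
print.preference_state <- function(x, ...) {
  cat(sprintf("<preference_state> v_hat_h = %.4f, v_hat_u = %g, alpha = %g\n",
              x$v_hat_h, x$v_hat_u, x$alpha))
  invisible(x)
}

#' Temporal-difference update of healthy-food preference
#'
#' Applied whenever the agent consumes healthy food. The perceived valuation
#' moves a fraction `alpha` of the way toward the intrinsic palatability:
#' `v' = v + alpha * (beta_h - v)`. The unhealthy-food valuation is never
#' updated, and learned preference is never forgotten, so `v_hat_h` is
#' non-decreasing across any update sequence and bounded by `beta_h`. After
#' `n` consecutive updates from 0 the closed form is
#' `beta_h * (1 - (1 - alpha)^n)`.
#'
#' @param state A [preference_state()].
#' @param pal A [palatability()]. Default `palatability()`.
#' @return The updated `preference_state`.
#' @examples
#' tdl_update(preference_state(alpha = 0.1))$v_hat_h  # 0.1
#' @export
tdl_update <- function(state, pal = palatability()) {
  stopifnot(inherits(state, "preference_state"), inherits(pal, "palatability"))
  state$v_hat_h <- state$v_hat_h + state$alpha * (pal$beta_h - state$v_hat_h)
  state
}

#' Luce choice probability of healthy food
#'
#' In a choice situation the agent picks healthy food with probability
#' `v_hat_h / (v_hat_u + v_hat_h)`. Under the normalization
#' `v_hat_u = beta_h = 1` this is bounded above by 1/2: even a fully learned
#' preference gives a coin flip against the equally palatable unhealthy
#' option. If both valuations are zero the healthy food is never chosen
#' (probability 0, by convention).
#'
#' @param state A [preference_state()].
#' @return Choice probability in \[0, 0.5\] under the default normalization.
#' @examples
#' choice_prob(preference_state(v_hat_h = 0.889, alpha = 0.05))
#' @export
choice_prob <- function(state) {
  stopifnot(inherits(state, "preference_state"))
  tot <- state$v_hat_u + state$v_hat_h
  if (tot == 0) return(0)
  state$v_hat_h / tot
}

#' Food-environment parameters
#'
#' Governs the yearly draw of gamma, the probability that a given day puts the
#' agent in the healthy-only situation. Agents living in a food desert draw
#' gamma uniformly on (0, p1); agents in a healthy food environment draw
#' uniformly on (p1, p2). Receiving FFVP in a year adds the augmentation
#' constant `a` to the draw (clipped at 1), so the program raises healthy-food
#' exposure regardless of the residential environment.
#'
#' @param p1 Upper bound of the food-desert interval, in (0, 1).
#' @param p2 Upper bound of the healthy-environment interval, in (p1, 1\].
#' @param a FFVP augmentation constant, >= 0.
#' @return An object of class `environment_params`.
#' @examples
#' environment_params(p1 = 0.15, p2 = 0.65, a = 0.3)
#' @export
environment_params <- function(p1, p2, a) {
  if (!is_scalar_number(p1) || p1 <= 0 || p1 >= 1)
    stop("`p1` must be a single number in (0, 1)", call. = FALSE)
  if (!is_scalar_number(p2) || p2 <= p1 || p2 > 1)
    stop("`p2` must be a single number in (p1, 1]", call. = FALSE)
  if (!is_scalar_number(a) || a < 0)
    stop("`a` must be a single number >= 0", call. = FALSE)
  structure(list(p1 = p1, p2 = p2, a = a), class = "environment_params")
}

#' Draw the healthy-situation probability gamma
#'
#' One draw per agent-year. Without FFVP the draw is uniform on (0, p1) for
#' food-desert agents and on (p1, p2) otherwise; with FFVP the same uniform
#' draw is augmented by the constant `a` and clipped to at most 1. With
#' `a = 0` the FFVP and no-FFVP draws are identical under a matched seed.
#'
#' @param desert Logical: does the agent live in a food desert this year?
#' @param ffvp Logical: does the agent receive FFVP this year?
#' @param env An [environment_params()].
#' @param n Number of draws (default 1).
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
draw_gamma <- function(desert, ffvp, env, n = 1) {
  stopifnot(inherits(env, "environment_params"),
            is.logical(desert), length(desert) == 1L, !is.na(desert),
            is.logical(ffvp), length(ffvp) == 1L, !is.na(ffvp))
  g <- if (desert) stats::runif(n, 0, env$p1) else stats::runif(n, env$p1, env$p2)
  if (ffvp) g <- pmin(g + env$a, 1)
  g
}

#' Servings model
#'
#' The count of daily servings of healthy food is generated by pushing a
#' uniform draw on (0, `v_hat_h`\] through the Poisson quantile function with
#' mean `lam`. A fully learned preference (`v_hat_h` near 1) therefore yields
#' draws distributed nearly Poisson(`lam`), while an unformed preference
#' truncates the draw toward low counts.
#'
#' @param lam Mean of the Poisson servings distribution (servings/day, > 0).
#' @return An object of class `serving_model`.
#' @examples
#' serving_model(lam = 2.8)
#' @export
serving_model <- function(lam) {
  if (!is_scalar_number(lam) || lam <= 0)
    stop("`lam` must be a single number > 0", call. = FALSE)
  structure(list(lam = lam), class = "serving_model")
}

#' Poisson quantile (inverse CDF)
#'
#' Smallest nonnegative integer `k` such that the Poisson(`lam`) CDF at `k`
#' is at least `u`. The quantile diverges as `u` approaches 1, which is why
#' the model requires perceived valuations to stay strictly below 1.
#'
#' @param u Probabilities in \[0, 1). Values >= 1 are a domain error.
#' @param lam Poisson mean, > 0.
#' @return Integer vector of servings counts.
#' @examples
#' poisson_quantile(c(0, 0.5, 0.9), lam = 2.5)
#' @export
poisson_quantile <- function(u, lam) {
  if (!is.numeric(u) || any(!is.finite(u)) || any(u < 0) || any(u >= 1))
    stop("`u` must be numeric in [0, 1)", call. = FALSE)
  if (!is_scalar_number(lam) || lam <= 0)
    stop("`lam` must be a single number > 0", call. = FALSE)
  as.integer(stats::qpois(u, lam))
}

#' Draw a daily servings count from the learned preference
#'
#' Draws `u` uniformly on (0, `v_hat_h`\] and returns
#' `poisson_quantile(u, lam)`. The resulting count distribution is
#' stochastically increasing in `v_hat_h`. An agent with a completely
#' unformed preference (`v_hat_h = 0`) deterministically consumes 0 servings
#' and no random number is consumed.
#'
#' @param state A [preference_state()].
#' @param model A [serving_model()].
#' @param n Number of draws (default 1).
#' @return Integer vector of servings counts.
#' @export
draw_servings <- function(state, model, n = 1) {
  stopifnot(inherits(state, "preference_state"), inherits(model, "serving_model"))
  if (state$v_hat_h == 0) return(integer(n))
  u <- stats::runif(n, 0, state$v_hat_h)
  poisson_quantile(u, model$lam)
}
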