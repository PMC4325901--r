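#' Initial reward belief
#'
#' The subject's belief about each action's reward rate is a beta
#' distribution; training starts from the same prior for both actions
#' (uniform, `Beta(1, 1)`, by default).
#'
#' @param prior_alpha,prior_beta positive beta parameters shared by both
#'   actions.
#' @return An object of class `nf_belief`: a list with positive elements
#'   `alpha_T`, `beta_T`, `alpha_F`, `beta_F`.
#' @examples
#' init_belief()            # uniform priors
#' anticipated_rewards(init_belief(2, 2))
#' @export
init_belief <- function(prior_alpha = 1, prior_beta = 1) {
  stopifnot(is.numeric(prior_alpha), length(prior_alpha) == 1L,
            is.numeric(prior_beta), length(prior_beta) == 1L)
  if (!is.finite(prior_alpha) || prior_alpha <= 0 ||
      !is.finite(prior_beta) || prior_beta <= 0)
    stop("beta priors must be positive")
  structure(list(alpha_T = prior_alpha, beta_T = prior_beta,
                 alpha_F = prior_alpha, beta_F = prior_beta),
            class = "nf_belief")
}

#' @export
print.nf_belief <- function(x, ...) {
  r <- anticipated_rewards(x)
  cat(sprintf("Beta beliefs: trained (%g, %g)  false (%g, %g)\n",
              x$alpha_T, x$beta_T, x$alpha_F, x$beta_F))
  cat(sprintf("  anticipated rewards r_T = %.4f, r_F = %.4f\n",
              r[["r_T"]], r[["r_F"]]))
  invisible(x)
}

#' Anticipated reward of each action
#'
#' Posterior mean reward rate under the current beta beliefs:
#' \eqn{r_T = \alpha_T/(\alpha_T+\beta_T)} and likewise for the false action.
#'
#' @param belief an [nf_belief] object.
#' @return Named numeric vector `c(r_T, r_F)`.
#' @export
anticipated_rewards <- function(belief) {
  stopifnot(inherits(belief, "nf_belief"))
  c(r_T = belief$alpha_T / (belief$alpha_T + belief$beta_T),
    r_F = belief$alpha_F / (belief$alpha_F + belief$beta_F))
}

#' Cumulative beta confidence
#'
#' The regularized incomplete beta function \eqn{I_x(\alpha, \beta)}, i.e.
#' the beta CDF at `x`: the subject's confidence that a reward rate with
#' belief `Beta(alpha, beta)` lies below `x`. The complement `1 - F` is the
#' confidence that the rate exceeds `x`, which is what action selection
#' compares (see [action_probabilities()]).
#'
#' @param x evaluation point(s) in `[0, 1]`.
#' @param alpha,beta positive beta parameters.
#' @return `I_x(alpha, beta)`, vectorized over `x`.
#' @export
belief_confidence <- function(x, alpha, beta) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("'x' must lie in [0, 1]")
  if (any(alpha <= 0) || any(beta <= 0))
    stop("beta parameters must be positive")
  stats::pbeta(x, alpha, beta)
}

.orientations <- c("confidence", "swapped", "as_printed")

## core action-selection rule, vectorized over belief vectors
.action_prob_T <- function(aT, bT, aF, bF, orientation) {
  rT <- aT / (aT + bT)
  rF <- aF / (aF + bF)
  FT_rF <- stats::pbeta(rF, aT, bT)  # lower-tail conf. of trained at r_F
  FF_rT <- stats::pbeta(rT, aF, bF)  # lower-tail conf. of false at r_T
  switch(orientation,
    confidence = {
      ## upper-tail reading: confidence each rate EXCEEDS the rival's mean
      num <- 1 - FT_rF
      den <- (1 - FT_rF) + (1 - FF_rT)
      ifelse(den == 0, 0.5, num / den)
    },
    swapped = {
      num <- FF_rT
      den <- FF_rT + FT_rF
      ifelse(den == 0, 0.5, num / den)
    },
    as_printed = {
      num <- FT_rF
      den <- FF_rT + FT_rF
      ifelse(den == 0, 0.5, num / den)
    })
}

#' Action-selection probabilities
#'
#' Probability of choosing the trained versus the false action by comparing
#' the relative beta confidences of the two reward beliefs. Three readings
#' of the selection rule are provided:
#'
#' * `"confidence"` (default): the cumulative-beta comparison with `F` read
#'   as the upper-tail confidence that an action's reward rate exceeds the
#'   rival action's anticipated reward,
#'   \eqn{P(a_T) = \bar F(r_F;\alpha_T,\beta_T) /
#'   (\bar F(r_F;\alpha_T,\beta_T) + \bar F(r_T;\alpha_F,\beta_F))} with
#'   \eqn{\bar F = 1 - F}. Confidence that the trained action is better
#'   increases \eqn{P(a_T)}; this is the orientation that produces operant
#'   conditioning toward the trained action and it reproduces the benchmark
#'   training dynamics (see the package vignette).
#' * `"swapped"`: lower-tail CDFs with the numerators exchanged,
#'   \eqn{P(a_T) = F(r_T;\alpha_F,\beta_F)/(F(r_T;\alpha_F,\beta_F) +
#'   F(r_F;\alpha_T,\beta_T))}; also prefers the believed-better action.
#' * `"as_printed"`: lower-tail CDFs arranged so that
#'   \eqn{P(a_T) \propto F(r_F;\alpha_T,\beta_T)}; kept for auditing, it
#'   assigns the larger probability to the action believed worse.
#'
#' The degenerate 0/0 normalization (both confidences zero) returns
#' `(0.5, 0.5)`. The two probabilities always sum to one.
#'
#' @param belief an [nf_belief] object.
#' @param orientation selection-rule reading, see Details.
#' @return Named numeric vector `c(p_T, p_F)` with `p_T + p_F == 1`.
#' @examples
#' b <- init_belief()
#' b$alpha_T <- 2; b$beta_F <- 2
#' action_probabilities(b)                 # 8/9 for the trained action
#' action_probabilities(b, "as_printed")   # 1/9 as typeset
#' @export
action_probabilities <- function(belief, orientation = .orientations) {
  stopifnot(inherits(belief, "nf_belief"))
  orientation <- match.arg(orientation)
  p_T <- .action_prob_T(belief$alpha_T, belief$beta_T,
                        belief$alpha_F, belief$beta_F, orientation)
  c(p_T = p_T, p_F = 1 - p_T)
}

.variants <- c("selection_weighted", "as_printed")
.sigma_dirs <- c("toward_trained", "printed_recursion")

#' Subject state on the continuum
#'
#' Tracks the state position `sigma` together with the (expected or
#' integer) counts of trained and false actions taken. Under the default
#' direction convention (`"toward_trained"`, see [expected_update()]) each
#' trained action moves the subject one step `delta` toward the trained
#' state, i.e. `sigma = -(n_trained - n_false) * step`; under
#' `"printed_recursion"` the sign is reversed.
#'
#' @param sigma initial state position.
#' @param n_trained,n_false accumulated action counts.
#' @return An object of class `nf_state`.
#' @export
nf_state <- function(sigma = 0, n_trained = 0, n_false = 0) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, is.finite(sigma),
            n_trained >= 0, n_false >= 0)
  structure(list(sigma = sigma, n_trained = n_trained, n_false = n_false),
            class = "nf_state")
}

#' One deterministic (expectation) learning iteration
#'
#' Advances beliefs and state by the expected values of the stochastic
#' update: with selection probabilities \eqn{(p_T, p_F)} from
#' [action_probabilities()] and reward probabilities \eqn{(q_T, q_F)} at
#' the current `(theta, sigma)`, each action's \eqn{\alpha} grows by
#' \eqn{p_a q_a} and its \eqn{\beta} by \eqn{p_a(1-q_a)} (variant
#' `"selection_weighted"`, the exact one-step expectation) or by
#' \eqn{1 - p_a q_a} (variant `"as_printed"`, which adds a full
#' pseudo-observation to both actions every iteration). The state moves by
#' the expected net step \eqn{(p_T - p_F)\delta}, toward the trained state
#' under the default direction.
#'
#' @param belief an [nf_belief].
#' @param state an [nf_state].
#' @param theta classifier threshold for this iteration.
#' @param env an [nf_env].
#' @param variant belief-update decomposition, see Details.
#' @param orientation passed to [action_probabilities()].
#' @param sigma_dir `"toward_trained"` (trained-action preference decreases
#'   `sigma`, raising both reward probabilities: the operant-conditioning
#'   direction) or `"printed_recursion"` (the opposite sign, under which
#'   training extinguishes its own reward).
#' @return `list(belief, state, p = c(p_T, p_F), q = c(q_T, q_F))`.
#' @export
expected_update <- function(belief, state, theta, env,
                            variant = .variants,
                            orientation = .orientations,
                            sigma_dir = .sigma_dirs) {
  stopifnot(inherits(belief, "nf_belief"), inherits(state, "nf_state"),
            inherits(env, "nf_env"))
  variant <- match.arg(variant)
  orientation <- match.arg(orientation)
  sigma_dir <- match.arg(sigma_dir)

  p <- action_probabilities(belief, orientation)
  q <- .reward_probs(theta, state$sigma, env)
  inc <- .belief_increments(p[["p_T"]], p[["p_F"]], q$q_T, q$q_F, variant)
  belief$alpha_T <- belief$alpha_T + inc$da_T
  belief$beta_T <- belief$beta_T + inc$db_T
  belief$alpha_F <- belief$alpha_F + inc$da_F
  belief$beta_F <- belief$beta_F + inc$db_F

  dsig <- .sigma_sign(sigma_dir) * (p[["p_T"]] - p[["p_F"]]) * env$step
  state$sigma <- state$sigma + dsig
  state$n_trained <- state$n_trained + p[["p_T"]]
  state$n_false <- state$n_false + p[["p_F"]]
  list(belief = belief, state = state,
       p = p, q = c(q_T = q$q_T, q_F = q$q_F))
}

.sigma_sign <- function(sigma_dir) {
  if (sigma_dir == "toward_trained") -1 else 1
}

.belief_increments <- function(p_T, p_F, q_T, q_F, variant) {
  if (variant == "selection_weighted") {
    list(da_T = p_T * q_T, db_T = p_T * (1 - q_T),
         da_F = p_F * q_F, db_F = p_F * (1 - q_F))
  } else {
    list(da_T = p_T * q_T, db_T = 1 - p_T * q_T,
         da_F = p_F * q_F, db_F = 1 - p_F * q_F)
  }
}

#' One stochastic learning iteration
#'
#' Samples an action from the current selection probabilities, samples a
#' Bernoulli reward with the chosen action's reward probability at
#' `(theta, sigma)`, increments that action's `alpha` (if rewarded) or
#' `beta` (if not) by one, and moves the state one full step `delta` in the
#' chosen direction. Uses R's RNG stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @inheritParams expected_update
#' @return `list(belief, state, action, rewarded, p)` where `action` is
#'   `"trained"` or `"false"` and `rewarded` a logical flag.
#' @export
stochastic_step <- function(belief, state, theta, env,
                            orientation = .orientations,
                            sigma_dir = .sigma_dirs) {
  stopifnot(inherits(belief, "nf_belief"), inherits(state, "nf_state"),
            inherits(env, "nf_env"))
  orientation <- match.arg(orientation)
  sigma_dir <- match.arg(sigma_dir)

  p <- action_probabilities(belief, orientation)
  take_T <- stats::runif(1L) < p[["p_T"]]
  q <- .reward_probs(theta, state$sigma, env)
  q_a <- if (take_T) q$q_T else q$q_F
  rewarded <- stats::runif(1L) < q_a

  if (take_T) {
    if (rewarded) belief$alpha_T <- belief$alpha_T + 1
    else belief$beta_T <- belief$beta_T + 1
    state$n_trained <- state$n_trained + 1L
  } else {
    if (rewarded) belief$alpha_F <- belief$alpha_F + 1
    else belief$beta_F <- belief$beta_F + 1
    state$n_false <- state$n_false + 1L
  }
  dir <- .sigma_sign(sigma_dir) * (if (take_T) 1 else -1)
  state$sigma <- state$sigma + dir * env$step
  list(belief = belief, state = state,
       action = if (take_T) "trained" else "false",
       rewarded = rewarded, p = p)
}
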