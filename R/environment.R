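#' Neurofeedback reward environment
#'
#' Constructs the fixed reward environment of a linear-classifier
#' neurofeedback task. Two logistic curves over the threshold/state
#' continuum give the probability of reward for the trained action
#' \eqn{P(r|a_T) = 1/(1+e^{D(\theta - \Delta + \sigma)})} and for the false
#' action \eqn{P(r|a_F) = 1/(1+e^{D(\theta + \Delta + \sigma)})}, where
#' \eqn{\theta} is the classifier threshold set by the instructor and
#' \eqn{\sigma} the subject's position on the state continuum.
#'
#' @param D discriminatory steepness of the classifier (dimensionless,
#'   `>= 0`). `D = 0` gives chance-level feedback (both curves flat at 0.5).
#' @param delta_sep \eqn{\Delta}, offset of each reward curve from the state
#'   origin (state-continuum arbitrary units, `>= 0`). The two curves sit at
#'   \eqn{\mp\Delta}; `delta_sep = 0` makes them identical.
#' @param step \eqn{\delta}, the subject's step size per action (state
#'   units, `> 0`).
#' @param name optional label for the environment.
#'
#' @return An object of class `nf_env`: a list with elements `D`,
#'   `delta_sep`, `step` and `name`.
#' @seealso [standard_environment()], [reward_probability()]
#' @examples
#' env <- nf_env(D = 1.7)
#' reward_probability("trained", theta = 0, sigma = 0, env = env)
#' @export
nf_env <- function(D, delta_sep = 1, step = 0.1, name = NULL) {
  stopifnot(is.numeric(D), length(D) == 1L, is.finite(D),
            is.numeric(delta_sep), length(delta_sep) == 1L, is.finite(delta_sep),
            is.numeric(step), length(step) == 1L, is.finite(step))
  if (D < 0) stop("'D' must be >= 0")
  if (delta_sep < 0) stop("'delta_sep' must be >= 0")
  if (step <= 0) stop("'step' must be > 0")
  structure(list(D = D, delta_sep = delta_sep, step = step,
                 name = if (is.null(name)) NA_character_ else as.character(name)),
            class = "nf_env")
}

#' @export
print.nf_env <- function(x, ...) {
  nm <- if (is.na(x$name)) "" else sprintf(" (%s)", x$name)
  cat(sprintf("Neurofeedback environment%s: D = %g, Delta = %g, delta = %g\n",
              nm, x$D, x$delta_sep, x$step))
  cat(sprintf("  peak balanced accuracy %.3f at theta = -sigma\n",
              classification_accuracy(0, 0, x)))
  invisible(x)
}

.actions <- c("trained", "false")

#' Named standard environments
#'
#' The three benchmark environments differing only in discriminatory
#' steepness: `illiterate` (`D = 0.4`, near-chance feedback, modelling BCI
#' illiteracy), `moderate` (`D = 1.7`) and `expert` (`D = 5.9`, near-perfect
#' feedback). All use `delta_sep = 1` and `step = 0.1`.
#'
#' @param name one of `"illiterate"`, `"moderate"`, `"expert"`.
#' @return An [nf_env] object.
#' @examples
#' standard_environment("expert")
#' @export
standard_environment <- function(name) {
  steep <- c(illiterate = 0.4, moderate = 1.7, expert = 5.9)
  if (length(name) != 1L || !is.character(name) || !name %in% names(steep))
    stop("unknown environment; valid names: ",
         paste(names(steep), collapse = ", "))
  nf_env(D = unname(steep[[name]]), delta_sep = 1, step = 0.1, name = name)
}

#' Reward probability of an action
#'
#' Logistic reward-probability curve evaluated at threshold `theta` and
#' state `sigma`. The trained action uses exponent
#' \eqn{D(\theta - \Delta + \sigma)}, the false action
#' \eqn{D(\theta + \Delta + \sigma)}; the trained action is never less
#' likely to be rewarded than the false one.
#'
#' @param action `"trained"` or `"false"`.
#' @param theta classifier threshold (recycled against `sigma`).
#' @param sigma state position.
#' @param env an [nf_env] object.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
reward_probability <- function(action, theta, sigma = 0, env) {
  action <- match.arg(action, .actions)
  stopifnot(inherits(env, "nf_env"))
  off <- if (action == "trained") -env$delta_sep else env$delta_sep
  stats::plogis(-env$D * (theta + off + sigma))
}

## both curves at once, vectorized; used by the simulation engine
.reward_probs <- function(theta, sigma, env) {
  list(q_T = stats::plogis(-env$D * (theta - env$delta_sep + sigma)),
       q_F = stats::plogis(-env$D * (theta + env$delta_sep + sigma)))
}

#' Balanced classification accuracy of the feedback
#'
#' Mean of the sensitivity (probability of rewarding the trained action)
#' and specificity (probability of withholding reward from the false
#' action) at a given threshold and state:
#' \eqn{(P(r|a_T) + 1 - P(r|a_F))/2}. It is maximal at \eqn{\theta = -\sigma}.
#'
#' @inheritParams reward_probability
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
classification_accuracy <- function(theta, sigma = 0, env) {
  stopifnot(inherits(env, "nf_env"))
  q <- .reward_probs(theta, sigma, env)
  (q$q_T + 1 - q$q_F) / 2
}

#' Evenly spaced threshold grid
#'
#' @param lo,hi inclusive grid bounds (`lo <= hi`).
#' @param step_size positive grid resolution.
#' @return Numeric vector of thresholds, class `nf_grid`.
#' @examples
#' g <- threshold_grid(-10, 10, 0.1)
#' length(g)  # 201
#' @export
threshold_grid <- function(lo = -10, hi = 10, step_size = 0.1) {
  stopifnot(is.numeric(lo), is.numeric(hi), is.numeric(step_size),
            length(lo) == 1L, length(hi) == 1L, length(step_size) == 1L)
  if (step_size <= 0) stop("'step_size' must be > 0")
  if (lo > hi) stop("'lo' must be <= 'hi'")
  n <- round((hi - lo) / step_size)
  ## snap to the grid resolution so values print exactly (-0.3, not
  ## -0.2999...), which also makes reported argmin thresholds clean
  digits <- max(0L, ceiling(-log10(step_size))) + 2L
  structure(round(lo + step_size * (0:n), digits),
            class = c("nf_grid", "numeric"), step_size = step_size)
}

## deterministic grid arg-extremum: ties resolved toward the value nearest
## zero, then the smaller value; NA entries are skipped
.arg_extreme <- function(values, grid, which = c("min", "max"), fallback = 0) {
  which <- match.arg(which)
  ok <- is.finite(values)
  if (!any(ok)) return(fallback)
  target <- if (which == "min") min(values[ok]) else max(values[ok])
  cand <- grid[ok & values == target]
  cand[order(abs(cand), cand)][1L]
}

#' Threshold of maximum classification accuracy
#'
#' Grid threshold maximizing [classification_accuracy()]; for the symmetric
#' logistic environment the continuous argmax is \eqn{\theta = -\sigma}.
#' Ties (e.g. `D = 0`, where all thresholds give chance accuracy) are broken
#' toward the threshold nearest zero, then the smaller value.
#'
#' @param env an [nf_env].
#' @param sigma state position at which accuracy is evaluated.
#' @param grid numeric vector of candidate thresholds, see [threshold_grid()].
#' @return A single threshold from `grid`.
#' @export
max_accuracy_threshold <- function(env, sigma = 0, grid = threshold_grid()) {
  stopifnot(inherits(env, "nf_env"))
  if (length(grid) == 0L) stop("'grid' must be non-empty")
  .arg_extreme(classification_accuracy(grid, sigma, env), grid, "max")
}

## single-point Bernoulli KL summands (bits)
.kl_terms <- function(p, q) {
  list(gain = p * log2(p / q), loss = q * log2(q / p))
}

#' Point-wise Kullback-Leibler reward information
#'
#' The two single-point divergence terms between the reward probabilities
#' of the trained (`p = P(r|a_T)`) and the false (`q = P(r|a_F)`) action at
#' a threshold: the gain term \eqn{p \log_2(p/q)} (information carried by a
#' reward obtained by preferring the trained action) and the loss term
#' \eqn{q \log_2(q/p)} (information lost by preferring the false action).
#' Each is one summand of a Bernoulli divergence, not the full two-outcome
#' divergence. The gain term peaks at positive thresholds and the loss term
#' at negative thresholds; with increasing `D` the peaks grow and narrow.
#'
#' @inheritParams classification_accuracy
#' @return A data.frame with columns `theta`, `sigma`, `gain_bits`,
#'   `loss_bits`.
#' @export
kl_divergence_pointwise <- function(theta, sigma = 0, env) {
  stopifnot(inherits(env, "nf_env"))
  q <- .reward_probs(theta, sigma, env)
  kl <- .kl_terms(q$q_T, q$q_F)
  ## identical distributions contribute no information
  kl$gain[q$q_T == q$q_F] <- 0
  kl$loss[q$q_T == q$q_F] <- 0
  data.frame(theta = theta, sigma = sigma,
             gain_bits = kl$gain, loss_bits = kl$loss)
}
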