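#' Simulate a reward-count calibration table
#'
#' Draws binomial success counts for both actions at every grid threshold
#' from the true logistic reward curves of an environment — a synthetic
#' stand-in for the per-threshold reward rates measured on a real recording
#' session, used to exercise [fit_environment()].
#'
#' @param env an [nf_env] (the generating truth).
#' @param sigma state position at which the session is recorded.
#' @param grid thresholds sampled, see [threshold_grid()].
#' @param trials_per_threshold binomial trials per action per threshold.
#' @param seed integer seed.
#' @return A data.frame (class `nf_caltable`) with columns `theta`,
#'   `successes_T`, `trials_T`, `successes_F`, `trials_F`.
#' @export
simulate_reward_counts <- function(env, sigma = 0, grid = threshold_grid(),
                                   trials_per_threshold = 100L, seed) {
  stopifnot(inherits(env, "nf_env"))
  if (trials_per_threshold < 1L) stop("'trials_per_threshold' must be >= 1")
  if (missing(seed) || is.null(seed))
    stop("an explicit 'seed' is required for reproducibility")
  set.seed(as.integer(seed))
  n <- as.integer(trials_per_threshold)
  q <- .reward_probs(as.numeric(grid), sigma, env)
  out <- data.frame(theta = as.numeric(grid),
                    successes_T = stats::rbinom(length(grid), n, q$q_T),
                    trials_T = n,
                    successes_F = stats::rbinom(length(grid), n, q$q_F),
                    trials_F = n)
  class(out) <- c("nf_caltable", "data.frame")
  out
}

.validate_caltable <- function(table) {
  need <- c("theta", "successes_T", "trials_T", "successes_F", "trials_F")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop("calibration table needs columns ", paste(need, collapse = ", "))
  with(table, {
    if (any(successes_T < 0 | successes_T > trials_T) ||
        any(successes_F < 0 | successes_F > trials_F))
      stop("successes must lie in [0, trials] for both actions")
  })
  if (length(unique(table$theta)) < 3L)
    stop("at least 3 distinct thresholds are required for fitting")
  invisible(table)
}

## joint negative binomial log-likelihood of both curves sharing one D and
## symmetric offsets +-Delta about -sigma; par = (log D, log Delta, sigma)
.cal_nll <- function(par, table) {
  D <- exp(par[1L]); Delta <- exp(par[2L]); sigma <- par[3L]
  pT <- stats::plogis(-D * (table$theta - Delta + sigma))
  pF <- stats::plogis(-D * (table$theta + Delta + sigma))
  ## clamp away from 0/1 so saturated counts keep a finite likelihood
  pT <- pmin(pmax(pT, 1e-12), 1 - 1e-12)
  pF <- pmin(pmax(pF, 1e-12), 1 - 1e-12)
  -sum(stats::dbinom(table$successes_T, table$trials_T, pT, log = TRUE)) -
    sum(stats::dbinom(table$successes_F, table$trials_F, pF, log = TRUE))
}

## deterministic derivative-free starting point: D from an empirical
## log-odds regression, Delta from half the gap of the 50% crossings,
## sigma from their midpoint
.cal_start <- function(table) {
  eb <- function(s, n) (s + 0.5) / (n + 1)  # empirical Bayes shrinkage
  pT <- eb(table$successes_T, table$trials_T)
  pF <- eb(table$successes_F, table$trials_F)
  lT <- stats::qlogis(pT); lF <- stats::qlogis(pF)
  bT <- stats::coef(stats::lm(lT ~ table$theta))
  bF <- stats::coef(stats::lm(lF ~ table$theta))
  D0 <- max(mean(c(-bT[2L], -bF[2L])), 1e-3)
  ## 50% crossings: logit = 0 at theta = -intercept/slope
  xT <- -bT[1L] / bT[2L]
  xF <- -bF[1L] / bF[2L]
  Delta0 <- max(abs(xT - xF) / 2, 1e-3)
  sigma0 <- -mean(c(xT, xF))
  c(log(D0), log(Delta0), sigma0)
}

#' Fit the logistic reward environment to a calibration table
#'
#' Maximum-likelihood fit of the two logistic reward curves to binomial
#' per-threshold reward counts, under the model's own parameterization:
#' both curves share one steepness `D` and sit at symmetric offsets
#' \eqn{\mp\Delta} about \eqn{-\sigma} (so `Delta >= 0` by construction and
#' the fitted trained-action curve dominates the false-action curve
#' everywhere). The joint binomial likelihood of both curves is maximized
#' with `stats::optim` (Nelder-Mead on `(log D, log Delta, sigma)`) from a
#' deterministic log-odds starting point.
#'
#' @param table a calibration table, see [simulate_reward_counts()] for the
#'   column contract.
#' @param step subject step size recorded in the fitted environment (not
#'   identifiable from a single-session snapshot).
#' @return An object of class `nf_calfit` with components `coefficients`
#'   (`D`, `delta_sep`, `sigma`), `env` (the fitted [nf_env]), `deviance`
#'   (per curve and total), `df_residual`, `logLik`, `convergence`
#'   (`0` = converged) and `table`. Methods: `print`, `coef`, `summary`,
#'   `predict`, `logLik`.
#' @examples
#' tab <- simulate_reward_counts(standard_environment("moderate"),
#'                               grid = threshold_grid(-6, 6, 1),
#'                               trials_per_threshold = 200, seed = 1)
#' fit <- fit_environment(tab)
#' coef(fit)
#' @export
fit_environment <- function(table, step = 0.1) {
  .validate_caltable(table)
  tot_s <- sum(table$successes_T) + sum(table$successes_F)
  tot_n <- sum(table$trials_T) + sum(table$trials_F)
  if (tot_s == 0L || tot_s == tot_n)
    stop("non-identifiable table: all failures or all successes everywhere")

  start <- .cal_start(table)
  opt <- stats::optim(start, .cal_nll, table = table, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  ## polish with a second pass from the first optimum
  opt <- stats::optim(opt$par, .cal_nll, table = table,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  D <- exp(opt$par[1L]); Delta <- exp(opt$par[2L]); sigma <- opt$par[3L]
  env <- nf_env(D = D, delta_sep = Delta, step = step, name = "fitted")

  ## per-curve deviance against the saturated model
  dev_curve <- function(s, n, p) {
    ph <- pmin(pmax(s / n, 1e-12), 1 - 1e-12)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    2 * sum(s * log(ph / p) + (n - s) * log((1 - ph) / (1 - p)))
  }
  pT <- stats::plogis(-D * (table$theta - Delta + sigma))
  pF <- stats::plogis(-D * (table$theta + Delta + sigma))
  dev <- c(trained = dev_curve(table$successes_T, table$trials_T, pT),
           false = dev_curve(table$successes_F, table$trials_F, pF))

  structure(list(
    coefficients = c(D = D, delta_sep = Delta, sigma = sigma),
    env = env,
    deviance = c(dev, total = sum(dev)),
    df_residual = 2L * nrow(table) - 3L,
    logLik = -opt$value,
    convergence = opt$convergence,
    table = table), class = "nf_calfit")
}

#' @export
coef.nf_calfit <- function(object, ...) object$coefficients

#' @export
logLik.nf_calfit <- function(object, ...) {
  structure(object$logLik, df = 3L, class = "logLik")
}

#' @export
print.nf_calfit <- function(x, ...) {
  cat("Logistic reward-environment fit\n")
  cat(sprintf("  D = %.4f, Delta = %.4f, sigma = %.4f\n",
              x$coefficients[["D"]], x$coefficients[["delta_sep"]],
              x$coefficients[["sigma"]]))
  cat(sprintf("  deviance %.2f on %d df%s\n", x$deviance[["total"]],
              x$df_residual,
              if (x$convergence == 0) "" else "  (optimizer did not converge)"))
  invisible(x)
}

#' @export
summary.nf_calfit <- function(object, ...) {
  cat("Logistic reward-environment fit (shared D, symmetric offsets)\n\n")
  print(data.frame(estimate = object$coefficients))
  cat(sprintf("\nDeviance: trained %.2f, false %.2f, total %.2f on %d df\n",
              object$deviance[["trained"]], object$deviance[["false"]],
              object$deviance[["total"]], object$df_residual))
  cat(sprintf("Log-likelihood: %.2f   convergence: %s\n", object$logLik,
              if (object$convergence == 0) "ok" else object$convergence))
  invisible(object)
}

#' Predicted reward probabilities from a calibration fit
#'
#' @param object an `nf_calfit`.
#' @param theta thresholds at which to evaluate the fitted curves; defaults
#'   to the fitted table's thresholds.
#' @param ... unused.
#' @return A data.frame with columns `theta`, `p_T`, `p_F`.
#' @export
predict.nf_calfit <- function(object, theta = object$table$theta, ...) {
  cf <- object$coefficients
  data.frame(
    theta = theta,
    p_T = stats::plogis(-cf[["D"]] * (theta - cf[["delta_sep"]] + cf[["sigma"]])),
    p_F = stats::plogis(-cf[["D"]] * (theta + cf[["delta_sep"]] + cf[["sigma"]])))
}

#' @export
plot.nf_calfit <- function(x, ...) {
  tab <- x$table
  th <- seq(min(tab$theta), max(tab$theta), length.out = 200L)
  pr <- predict(x, th)
  graphics::plot(tab$theta, tab$successes_T / tab$trials_T, col = "blue",
                 pch = 16, ylim = c(0, 1), xlab = "threshold",
                 ylab = "reward probability", ...)
  graphics::points(tab$theta, tab$successes_F / tab$trials_F, col = "red",
                   pch = 16)
  graphics::lines(th, pr$p_T, col = "blue")
  graphics::lines(th, pr$p_F, col = "red")
  graphics::legend("topright", c("trained", "false"), col = c("blue", "red"),
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}
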