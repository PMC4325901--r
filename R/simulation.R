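## ---------------------------------------------------------------------------
## Deterministic expectation engine
##
## Runs the expectation recursion simultaneously for K independent "columns".
## Two layouts share the same inner loop:
##   * sweep:    `thetas` is a K-vector, each column keeps its own fixed
##               threshold for the whole run;
##   * schedule: `schedule` is an n_iter-vector and K = 1, the threshold is
##               looked up per iteration (open-loop replay).
## p[i, k] is the trained-action probability BEFORE the i-th update; the
## matrix has n_iter + 1 rows so that the efficiency of iteration n_iter is
## defined. Belief/state trajectories are stored only when `keep = "trace"`.
## ---------------------------------------------------------------------------
.nf_engine <- function(env, thetas = NULL, schedule = NULL, n_iter,
                       variant, orientation, sigma_dir,
                       prior_alpha = 1, prior_beta = 1, sigma0 = 0,
                       keep = c("p", "trace")) {
  keep <- match.arg(keep)
  fixed <- !is.null(thetas)
  K <- if (fixed) length(thetas) else 1L
  sgn <- .sigma_sign(sigma_dir)

  aT <- aF <- rep(prior_alpha, K)
  bT <- bF <- rep(prior_beta, K)
  sigma <- rep(sigma0, K)
  p <- matrix(NA_real_, n_iter + 1L, K)
  tr <- if (keep == "trace")
    matrix(NA_real_, n_iter, 12L,
           dimnames = list(NULL, c("theta", "sigma", "alpha_T", "beta_T",
                                   "alpha_F", "beta_F", "r_T", "r_F",
                                   "p_T", "p_F", "q_T", "q_F")))
  for (i in seq_len(n_iter + 1L)) {
    p_T <- .action_prob_T(aT, bT, aF, bF, orientation)
    p[i, ] <- p_T
    if (i > n_iter) break
    th <- if (fixed) thetas else schedule[i]
    p_F <- 1 - p_T
    q <- .reward_probs(th, sigma, env)
    if (keep == "trace")
      tr[i, ] <- c(th, sigma, aT, bT, aF, bF,
                   aT / (aT + bT), aF / (aF + bF),
                   p_T, p_F, q$q_T, q$q_F)
    inc <- .belief_increments(p_T, p_F, q$q_T, q$q_F, variant)
    aT <- aT + inc$da_T; bT <- bT + inc$db_T
    aF <- aF + inc$da_F; bF <- bF + inc$db_F
    sigma <- sigma + sgn * (p_T - p_F) * env$step
  }
  list(p = p, trace = tr)
}

.run_meta <- function(env, n_iter, variant, orientation, sigma_dir,
                      schedule_mode, seed = NULL) {
  list(env = env, n_iter = n_iter, variant = variant,
       orientation = orientation, sigma_dir = sigma_dir,
       schedule_mode = schedule_mode, seed = seed)
}

.as_trace <- function(eng, n_iter, meta, eps = 1e-12) {
  tr <- eng$trace
  out <- data.frame(iteration = seq_len(n_iter), tr[, 1:12, drop = FALSE])
  out$entropy_bits <- .entropy_bits(out$p_T)
  out$efficiency <- .efficiency(eng$p[seq_len(n_iter), 1L],
                                eng$p[seq_len(n_iter) + 1L, 1L], eps)
  attr(out, "meta") <- meta
  class(out) <- c("nf_trace", "data.frame")
  out
}

#' Fixed-threshold training run (expectation mode)
#'
#' Deterministic trajectory of the expectation recursion at a constant
#' classifier threshold, starting from uniform priors and `sigma = 0`.
#' Reward probabilities are refreshed from `(theta, sigma_i)` between
#' iterations. Entropy at iteration `i` is computed from the selection
#' probability before the i-th update; efficiency spans updates `i` to
#' `i + 1`. Iterations are 1-based.
#'
#' @param env an [nf_env].
#' @param theta fixed classifier threshold.
#' @param n_iter number of learning iterations (`>= 1`).
#' @param variant,orientation,sigma_dir model conventions, see
#'   [expected_update()].
#' @param prior_alpha,prior_beta shared beta priors.
#' @param sigma0 initial state position.
#' @return An `nf_trace`: a data.frame with one row per iteration and
#'   columns `iteration`, `theta`, `sigma`, `alpha_T`, `beta_T`, `alpha_F`,
#'   `beta_F`, `r_T`, `r_F`, `p_T`, `p_F`, `q_T`, `q_F`, `entropy_bits`,
#'   `efficiency`; run metadata in `attr(, "meta")`.
#' @examples
#' tr <- run_fixed(standard_environment("expert"), theta = 0, n_iter = 50)
#' tail(tr$entropy_bits, 1) < tr$entropy_bits[10]
#' @export
run_fixed <- function(env, theta, n_iter = 10000L,
                      variant = .variants, orientation = .orientations,
                      sigma_dir = .sigma_dirs,
                      prior_alpha = 1, prior_beta = 1, sigma0 = 0) {
  stopifnot(inherits(env, "nf_env"), is.numeric(theta), length(theta) == 1L,
            n_iter >= 1L)
  variant <- match.arg(variant)
  orientation <- match.arg(orientation)
  sigma_dir <- match.arg(sigma_dir)
  eng <- .nf_engine(env, thetas = theta, n_iter = as.integer(n_iter),
                    variant = variant, orientation = orientation,
                    sigma_dir = sigma_dir, prior_alpha = prior_alpha,
                    prior_beta = prior_beta, sigma0 = sigma0, keep = "trace")
  .as_trace(eng, as.integer(n_iter),
            .run_meta(env, n_iter, variant, orientation, sigma_dir, "fixed"))
}

#' Fixed-threshold sweep over a grid
#'
#' Runs [run_fixed()] independently for every grid threshold and assembles
#' the entropy and efficiency matrices `H[iteration, theta]` and
#' `IE[iteration, theta]`, together with the per-iteration
#' entropy-minimizing and efficiency-maximizing threshold vectors (see
#' [optimal_threshold_vectors()]). The efficiency argmax skips
#' post-singularity (undefined) entries.
#'
#' @param env an [nf_env].
#' @param grid thresholds, see [threshold_grid()].
#' @inheritParams run_fixed
#' @param eps singularity guard forwarded to [instructional_efficiency()].
#' @return An object of class `nf_sweep`: a list with elements `grid`,
#'   `n_iter`, `H`, `IE` (matrices, iterations in rows), `theta_entropy`,
#'   `theta_ie` (per-iteration threshold vectors) and `meta`.
#' @examples
#' sw <- threshold_sweep(standard_environment("moderate"),
#'                       threshold_grid(-2, 2, 0.5), n_iter = 100)
#' range(sw$theta_entropy)
#' @export
threshold_sweep <- function(env, grid = threshold_grid(), n_iter = 10000L,
                            variant = .variants, orientation = .orientations,
                            sigma_dir = .sigma_dirs,
                            prior_alpha = 1, prior_beta = 1, sigma0 = 0,
                            eps = 1e-12) {
  stopifnot(inherits(env, "nf_env"), length(grid) >= 1L, n_iter >= 1L)
  variant <- match.arg(variant)
  orientation <- match.arg(orientation)
  sigma_dir <- match.arg(sigma_dir)
  n_iter <- as.integer(n_iter)
  eng <- .nf_engine(env, thetas = as.numeric(grid), n_iter = n_iter,
                    variant = variant, orientation = orientation,
                    sigma_dir = sigma_dir, prior_alpha = prior_alpha,
                    prior_beta = prior_beta, sigma0 = sigma0, keep = "p")
  idx <- seq_len(n_iter)
  H <- .entropy_bits(eng$p[idx, , drop = FALSE])
  IE <- .efficiency(eng$p[idx, , drop = FALSE],
                    eng$p[idx + 1L, , drop = FALSE], eps)
  out <- structure(
    list(grid = as.numeric(grid), n_iter = n_iter, H = H, IE = IE,
         meta = .run_meta(env, n_iter, variant, orientation, sigma_dir,
                          "sweep")),
    class = "nf_sweep")
  vec <- optimal_threshold_vectors(out)
  out$theta_entropy <- vec$entropy_vector
  out$theta_ie <- vec$efficiency_vector
  out
}

#' Optimal threshold vectors of a sweep
#'
#' Extracts, for every iteration, the grid threshold minimizing action
#' entropy and the one maximizing instructional efficiency. Ties are broken
#' toward the threshold nearest zero, then the smaller value; undefined
#' (post-singularity) efficiencies are skipped, and an all-undefined
#' iteration falls back to the maximum-accuracy threshold 0.
#'
#' @param sweep an `nf_sweep` from [threshold_sweep()].
#' @return `list(entropy_vector, efficiency_vector)`, each of length
#'   `sweep$n_iter` with values on the grid.
#' @export
optimal_threshold_vectors <- function(sweep) {
  stopifnot(inherits(sweep, "nf_sweep"))
  g <- sweep$grid
  list(
    entropy_vector = apply(sweep$H, 1L, .arg_extreme, grid = g, which = "min"),
    efficiency_vector = apply(sweep$IE, 1L, .arg_extreme, grid = g,
                              which = "max"))
}

#' Adaptive-threshold training run
#'
#' Identical recursion to [run_fixed()] except that the threshold of
#' iteration `i` is looked up in `schedule` — an open-loop replay of a
#' pre-computed threshold vector (typically one of the
#' [optimal_threshold_vectors()] of a sweep). A constant (length-1)
#' schedule reproduces [run_fixed()] exactly.
#'
#' @param env an [nf_env].
#' @param schedule numeric vector of per-iteration thresholds; either
#'   length 1 (constant) or length `>= n_iter`.
#' @inheritParams run_fixed
#' @return An `nf_trace`, as for [run_fixed()].
#' @export
run_adaptive <- function(env, schedule, n_iter = length(schedule),
                         variant = .variants, orientation = .orientations,
                         sigma_dir = .sigma_dirs,
                         prior_alpha = 1, prior_beta = 1, sigma0 = 0) {
  stopifnot(inherits(env, "nf_env"), is.numeric(schedule), n_iter >= 1L)
  variant <- match.arg(variant)
  orientation <- match.arg(orientation)
  sigma_dir <- match.arg(sigma_dir)
  n_iter <- as.integer(n_iter)
  if (length(schedule) == 1L) schedule <- rep(schedule, n_iter)
  if (length(schedule) < n_iter)
    stop("'schedule' is shorter than 'n_iter'")
  eng <- .nf_engine(env, schedule = as.numeric(schedule), n_iter = n_iter,
                    variant = variant, orientation = orientation,
                    sigma_dir = sigma_dir, prior_alpha = prior_alpha,
                    prior_beta = prior_beta, sigma0 = sigma0, keep = "trace")
  .as_trace(eng, n_iter,
            .run_meta(env, n_iter, variant, orientation, sigma_dir,
                      "adaptive"))
}

#' Compare the entropy time courses of two runs
#'
#' Per-iteration relative action entropy of a test run against a reference
#' run (typically adaptive versus fixed threshold), with its decibel
#' transform \eqn{10\log_{10}(H_{test}/H_{ref})}. Reports the iterations at
#' which the test run's entropy strictly exceeds the reference, the
#' crossing (sign-change) iterations, and the final crossover: the last
#' iteration whose ratio exceeds 1 with all later iterations at or below 1.
#'
#' @param test,reference `nf_trace` objects of equal length.
#' @return An object of class `nf_compare`: a data.frame with columns
#'   `iteration`, `h_test`, `h_ref`, `ratio`, `db`, with attributes
#'   `exceed_runs` (matrix of first/last iterations of each contiguous
#'   excess phase), `crossings` and `final_crossover` (`NA` if the test
#'   never exceeds the reference).
#' @export
compare_traces <- function(test, reference) {
  stopifnot(inherits(test, "nf_trace"), inherits(reference, "nf_trace"))
  if (nrow(test) != nrow(reference))
    stop("traces have different lengths")
  ratio <- test$entropy_bits / reference$entropy_bits
  out <- data.frame(iteration = test$iteration,
                    h_test = test$entropy_bits,
                    h_ref = reference$entropy_bits,
                    ratio = ratio,
                    db = 10 * log10(ratio))
  exceed <- which(test$entropy_bits > reference$entropy_bits)
  runs <- if (length(exceed)) {
    grp <- cumsum(c(1L, diff(exceed) != 1L))
    t(vapply(split(exceed, grp), range, integer(2L)))
  } else matrix(integer(0), 0L, 2L)
  dimnames(runs) <- list(NULL, c("from", "to"))
  attr(out, "exceed_runs") <- runs
  attr(out, "crossings") <- sort(unique(c(runs[, 1L], runs[, 2L] + 1L)))
  attr(out, "final_crossover") <-
    if (length(exceed)) max(exceed) else NA_integer_
  class(out) <- c("nf_compare", "data.frame")
  out
}

#' Monte-Carlo ensemble of stochastic training runs
#'
#' Simulates `n_runs` independent stochastic trajectories
#' (action sampling, Bernoulli rewards, unit belief increments, full state
#' steps — see [stochastic_step()]) and summarizes the ensemble per
#' iteration. Fully reproducible from `seed`.
#'
#' @param env an [nf_env].
#' @param schedule per-iteration threshold vector, or a single constant
#'   threshold.
#' @param n_runs number of independent runs (`>= 1`).
#' @param n_iter iterations per run.
#' @param seed integer seed for R's RNG.
#' @inheritParams run_fixed
#' @param keep_runs if `TRUE`, attach the full `n_iter x n_runs` matrix of
#'   per-run trained-action probabilities as attribute `p_runs`.
#' @return An object of class `nf_ensemble`: a data.frame with columns
#'   `iteration`, `p_T_mean`, `p_T_sd`, `sigma_mean`, `sigma_sd`,
#'   `entropy_mean`, `entropy_sd` (entropy of each run's selection
#'   probability, averaged across runs).
#' @examples
#' mc <- monte_carlo(standard_environment("moderate"), 0,
#'                   n_runs = 50, n_iter = 10, seed = 1)
#' mc$p_T_mean[10]
#' @export
monte_carlo <- function(env, schedule, n_runs, n_iter,
                        seed, orientation = .orientations,
                        sigma_dir = .sigma_dirs,
                        prior_alpha = 1, prior_beta = 1, sigma0 = 0,
                        keep_runs = FALSE) {
  stopifnot(inherits(env, "nf_env"), n_runs >= 1L, n_iter >= 1L)
  if (missing(seed) || is.null(seed))
    stop("an explicit 'seed' is required for reproducibility")
  orientation <- match.arg(orientation)
  sigma_dir <- match.arg(sigma_dir)
  n_runs <- as.integer(n_runs); n_iter <- as.integer(n_iter)
  if (length(schedule) == 1L) schedule <- rep(schedule, n_iter)
  if (length(schedule) < n_iter) stop("'schedule' is shorter than 'n_iter'")
  set.seed(as.integer(seed))
  sgn <- .sigma_sign(sigma_dir)

  aT <- aF <- rep(prior_alpha, n_runs)
  bT <- bF <- rep(prior_beta, n_runs)
  sigma <- rep(sigma0, n_runs)
  pm <- matrix(NA_real_, n_iter, n_runs)
  sm <- matrix(NA_real_, n_iter, n_runs)
  for (i in seq_len(n_iter)) {
    p_T <- .action_prob_T(aT, bT, aF, bF, orientation)
    pm[i, ] <- p_T
    sm[i, ] <- sigma
    take_T <- stats::runif(n_runs) < p_T
    q <- .reward_probs(schedule[i], sigma, env)
    q_a <- ifelse(take_T, q$q_T, q$q_F)
    rewarded <- stats::runif(n_runs) < q_a
    aT <- aT + (take_T & rewarded)
    bT <- bT + (take_T & !rewarded)
    aF <- aF + (!take_T & rewarded)
    bF <- bF + (!take_T & !rewarded)
    sigma <- sigma + sgn * ifelse(take_T, 1, -1) * env$step
  }
  hm <- .entropy_bits(pm)
  out <- data.frame(iteration = seq_len(n_iter),
                    p_T_mean = rowMeans(pm),
                    p_T_sd = apply(pm, 1L, stats::sd),
                    sigma_mean = rowMeans(sm),
                    sigma_sd = apply(sm, 1L, stats::sd),
                    entropy_mean = rowMeans(hm),
                    entropy_sd = apply(hm, 1L, stats::sd))
  attr(out, "meta") <- .run_meta(env, n_iter, NA_character_, orientation,
                                 sigma_dir, "monte_carlo", seed = seed)
  attr(out, "n_runs") <- n_runs
  if (keep_runs) attr(out, "p_runs") <- pm
  class(out) <- c("nf_ensemble", "data.frame")
  out
}
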