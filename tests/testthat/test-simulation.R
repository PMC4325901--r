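test_that("chance-level feedback teaches nothing in expectation", {
  tr <- run_fixed(nf_env(D = 0), theta = 2.5, n_iter = 300)
  expect_equal(tr$p_T, rep(0.5, 300), tolerance = 1e-12)
  expect_equal(tr$entropy_bits, rep(1, 300), tolerance = 1e-12)
})

test_that("entropy falls over training at the maximum-accuracy threshold", {
  tr <- run_fixed(standard_environment("expert"), theta = 0, n_iter = 500)
  expect_lt(tr$entropy_bits[500], tr$entropy_bits[10])
  expect_lt(tr$entropy_bits[500], 0.01)
})

test_that("expectation-mode runs are bit-identical across calls", {
  env <- standard_environment("moderate")
  a <- run_fixed(env, 0.3, 200)
  b <- run_fixed(env, 0.3, 200)
  expect_identical(a, b)
})

test_that("trace layout honours the per-iteration contract", {
  env <- standard_environment("illiterate")
  tr <- run_fixed(env, -1, 50)
  expect_equal(nrow(tr), 50)
  expect_equal(tr$iteration, 1:50)
  expect_equal(tr$p_T + tr$p_F, rep(1, 50))
  expect_true(all(tr$entropy_bits >= 0 & tr$entropy_bits <= 1))
  ## row i reports the belief state before update i, starting at the prior
  expect_equal(unlist(tr[1, c("alpha_T", "beta_T", "alpha_F", "beta_F")]),
               c(alpha_T = 1, beta_T = 1, alpha_F = 1, beta_F = 1))
  ## efficiency column is the normalized one-step gain of p_T
  ie <- instructional_efficiency(tr$p_T[-50], tr$p_T[-1])
  expect_equal(tr$efficiency[-50], ie)
})

test_that("sweep columns are independent of grid order", {
  env <- standard_environment("moderate")
  g <- threshold_grid(-3, 3, 0.5)
  sw <- threshold_sweep(env, g, 150)
  set.seed(9)
  perm <- sample(length(g))
  swp <- threshold_sweep(env, as.numeric(g)[perm], 150)
  expect_identical(swp$H[, order(perm)], sw$H)
  expect_identical(swp$IE[, order(perm)], sw$IE)
})

test_that("single-point grids pin both optimal vectors to that threshold", {
  sw <- threshold_sweep(standard_environment("expert"), 1.2, 80)
  expect_equal(sw$theta_entropy, rep(1.2, 80))
  expect_equal(sw$theta_ie[!is.na(sw$IE[, 1])], rep(1.2, sum(!is.na(sw$IE))))
  vec <- optimal_threshold_vectors(sw)
  expect_length(vec$entropy_vector, 80)
})

test_that("degenerate chance environments tie-break the vectors to zero", {
  sw <- threshold_sweep(nf_env(D = 0), threshold_grid(-2, 2, 1), 60)
  expect_equal(sw$theta_entropy, rep(0, 60))
  expect_equal(sw$theta_ie, rep(0, 60))
})

test_that("the entropy-minimizing trace starts at the maximum-accuracy threshold", {
  for (name in c("moderate", "expert")) {
    sw <- threshold_sweep(standard_environment(name),
                          threshold_grid(-5, 5, 0.5), 300)
    expect_equal(sw$theta_entropy[1], 0)
    expect_lte(abs(sw$theta_entropy[2]), 0.5)
  }
})

test_that("a constant schedule reproduces the fixed-threshold run exactly", {
  env <- standard_environment("moderate")
  fx <- run_fixed(env, 0.7, 120)
  ad <- run_adaptive(env, rep(0.7, 120))
  strip <- function(x) {
    x <- as.data.frame(x)
    attr(x, "meta") <- NULL
    x
  }
  expect_identical(strip(ad), strip(fx))
  ad1 <- run_adaptive(env, 0.7, n_iter = 120)  # scalar recycled
  expect_equal(ad1$p_T, fx$p_T)
  expect_error(run_adaptive(env, rep(0, 10), n_iter = 50), "shorter")
})

test_that("trace comparison reports ratios, crossings and the final crossover", {
  env <- standard_environment("moderate")
  tr <- run_fixed(env, 0, 100)
  same <- compare_traces(tr, tr)
  expect_equal(same$ratio, rep(1, 100))
  expect_equal(same$db, rep(0, 100))
  expect_equal(nrow(attr(same, "exceed_runs")), 0)
  expect_true(is.na(attr(same, "final_crossover")))

  other <- run_fixed(env, 1.5, 100)
  cmp <- compare_traces(other, tr)
  expect_equal(cmp$ratio, other$entropy_bits / tr$entropy_bits)
  exceed <- which(other$entropy_bits > tr$entropy_bits)
  expect_equal(attr(cmp, "final_crossover"), max(exceed))
  expect_error(compare_traces(run_fixed(env, 0, 50), tr), "length")
})

test_that("Monte-Carlo ensembles are reproducible and agree with expectation", {
  env <- standard_environment("moderate")
  a <- monte_carlo(env, 0, n_runs = 200, n_iter = 10, seed = 3)
  b <- monte_carlo(env, 0, n_runs = 200, n_iter = 10, seed = 3)
  expect_identical(a, b)
  one <- monte_carlo(env, 0, n_runs = 1, n_iter = 20, seed = 4,
                     keep_runs = TRUE)
  expect_equal(dim(attr(one, "p_runs")), c(20L, 1L))
  expect_error(monte_carlo(env, 0, n_runs = 5, n_iter = 5), "seed")

  ## ensemble mean tracks the expectation recursion (first-order approx.)
  mc <- monte_carlo(env, 0, n_runs = 2000, n_iter = 10, seed = 5)
  tr <- run_fixed(env, 0, 10)
  expect_lt(abs(mc$p_T_mean[10] - tr$p_T[10]), 0.05)
})

test_that("deflection peaks summarize the entropy-minimizing trace", {
  sw <- threshold_sweep(standard_environment("illiterate"),
                        threshold_grid(-4, 4, 0.5), 400)
  pk <- deflection_peaks(sw)
  expect_equal(pk$early_theta, min(sw$theta_entropy[1:100]))
  expect_equal(pk$late_theta, max(sw$theta_entropy))
  expect_lte(pk$early_theta, 0)
  expect_gte(pk$late_theta, 0)
})
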