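test_that("standard environments carry the benchmark parameter sets", {
  ill <- standard_environment("illiterate")
  expect_equal(c(ill$D, ill$delta_sep, ill$step), c(0.4, 1, 0.1))
  exp_env <- standard_environment("expert")
  expect_equal(c(exp_env$D, exp_env$delta_sep, exp_env$step), c(5.9, 1, 0.1))
  expect_equal(standard_environment("moderate")$D, 1.7)
  expect_error(standard_environment("novice"), "illiterate")
})

test_that("environment constructor enforces parameter ranges", {
  expect_error(nf_env(D = -1), ">= 0")
  expect_error(nf_env(D = 1, delta_sep = -0.1), ">= 0")
  expect_error(nf_env(D = 1, step = 0), "> 0")
  expect_s3_class(nf_env(D = 0, delta_sep = 0), "nf_env")  # degenerate ok
})

test_that("reward probabilities follow the logistic curves", {
  env <- standard_environment("moderate")
  expect_equal(reward_probability("trained", theta = 0, sigma = 0, env = env),
               LOGISTIC_17, tolerance = 1e-14)
  ## zero exponent at theta = Delta - sigma for the trained action
  for (sig in c(-2, 0, 1.3))
    expect_equal(reward_probability("trained", env$delta_sep - sig, sig, env),
                 0.5)
  ## D = 0: flat chance curves for either action
  flat <- nf_env(D = 0)
  expect_equal(reward_probability("trained", -3:3, 0, flat), rep(0.5, 7))
  expect_equal(reward_probability("false", -3:3, 0, flat), rep(0.5, 7))
})

test_that("trained action dominates, with equality only when D or Delta is 0", {
  set.seed(41)
  for (i in 1:50) {
    env <- nf_env(D = runif(1, 0.1, 4), delta_sep = runif(1, 0.1, 2))
    th <- runif(1, -3, 3); sig <- runif(1, -2, 2)
    expect_gt(reward_probability("trained", th, sig, env),
              reward_probability("false", th, sig, env))
  }
  eq_env <- nf_env(D = 2, delta_sep = 0)
  expect_equal(reward_probability("trained", 1.5, 0.5, eq_env),
               reward_probability("false", 1.5, 0.5, eq_env))
})

test_that("curves are translation invariant in theta + sigma and mirror-symmetric", {
  env <- standard_environment("expert")
  set.seed(42)
  th <- runif(20, -10, 10); sig <- runif(20, -5, 5); shift <- runif(20, -3, 3)
  for (a in c("trained", "false")) {
    expect_equal(reward_probability(a, th + shift, sig - shift, env),
                 reward_probability(a, th, sig, env))
    ## at sigma = 0: P(r|a_T; theta) = 1 - P(r|a_F; -theta)
  }
  expect_equal(reward_probability("trained", th, 0, env),
               1 - reward_probability("false", -th, 0, env))
})

test_that("balanced accuracy behaves as the classifier operating measure", {
  expect_equal(classification_accuracy(c(-4, 0, 7), 0, nf_env(D = 0)),
               rep(0.5, 3))
  env <- standard_environment("expert")
  expect_equal(classification_accuracy(0, 0, env), LOGISTIC_59,
               tolerance = 1e-14)
  th <- seq(-5, 5, by = 0.5)
  expect_equal(classification_accuracy(th, 0, env),
               classification_accuracy(-th, 0, env))
})

test_that("maximum-accuracy threshold sits at -sigma, ties resolve to zero", {
  grid <- threshold_grid(-10, 10, 0.1)
  for (D in c(0.4, 1.7, 5.9)) {
    env <- nf_env(D = D)
    expect_equal(max_accuracy_threshold(env, sigma = 0, grid = grid), 0)
    expect_equal(max_accuracy_threshold(env, sigma = 2, grid = grid), -2)
    ## agreement with a brute-force scan at an off-grid state
    sig <- 1.37
    brute <- brute_argmax(function(t) classification_accuracy(t, sig, env),
                          grid)
    expect_equal(max_accuracy_threshold(env, sigma = sig, grid = grid), brute)
  }
  expect_equal(max_accuracy_threshold(nf_env(D = 0), grid = grid), 0)
  expect_error(max_accuracy_threshold(nf_env(D = 1), grid = numeric(0)),
               "non-empty")
})

test_that("point-wise KL terms match direct evaluation and vanish when curves agree", {
  flat <- nf_env(D = 0)
  kl0 <- kl_divergence_pointwise(c(-1, 0, 3), 0, flat)
  expect_equal(kl0$gain_bits, rep(0, 3))
  expect_equal(kl0$loss_bits, rep(0, 3))
  ## environment solved so that (p, q) = (0.8, 0.4) at its threshold:
  ## gain term is then 0.8 * log2(2) = 0.8 exactly
  D <- (qlogis(0.8) - qlogis(0.4)) / 2
  th <- 1 - qlogis(0.8) / D
  env <- nf_env(D = D)
  expect_equal(reward_probability("trained", th, 0, env), 0.8)
  expect_equal(reward_probability("false", th, 0, env), 0.4)
  kl <- kl_divergence_pointwise(th, 0, env)
  expect_equal(kl$gain_bits, 0.8, tolerance = 1e-12)
})

test_that("gain information peaks at positive and loss at negative thresholds", {
  grid <- threshold_grid(-10, 10, 0.1)
  prev_height <- 0; prev_width <- Inf
  for (D in c(0.4, 1.7, 5.9)) {
    kl <- kl_divergence_pointwise(grid, 0, nf_env(D = D))
    peak_gain <- grid[which.max(kl$gain_bits)]
    peak_loss <- grid[which.min(kl$loss_bits)]  # most negative
    expect_gt(peak_gain, 0)
    expect_lt(peak_loss, 0)
    ## divergence grows and narrows with D
    height <- max(kl$gain_bits)
    width <- 0.1 * sum(kl$gain_bits > height / 2)
    expect_gt(height, prev_height)
    expect_lt(width, prev_width)
    prev_height <- height; prev_width <- width
  }
})
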