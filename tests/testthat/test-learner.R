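test_that("belief initialization sets shared priors and rejects bad ones", {
  b <- init_belief()
  expect_equal(unlist(b[c("alpha_T", "beta_T", "alpha_F", "beta_F")]),
               c(alpha_T = 1, beta_T = 1, alpha_F = 1, beta_F = 1))
  b2 <- init_belief(2, 2)
  expect_equal(unname(unlist(b2[1:4])), rep(2, 4))
  expect_error(init_belief(0), "positive")
  expect_error(init_belief(1, -1), "positive")
})

test_that("anticipated rewards are the beta posterior means", {
  expect_equal(unname(anticipated_rewards(init_belief())), c(0.5, 0.5))
  expect_equal(unname(anticipated_rewards(belief_with(2, 1, 1, 2))),
               c(2 / 3, 1 / 3))
  expect_equal(anticipated_rewards(belief_with(10, 30, 5, 5))[["r_T"]], 0.25)
})

test_that("belief confidence is the regularized incomplete beta", {
  ## closed forms: I_x(2, 1) = x^2 and I_x(1, 2) = 1 - (1 - x)^2
  xs <- c(0, 1 / 3, 0.5, 0.9, 1)
  expect_equal(belief_confidence(xs, 2, 1), xs^2)
  expect_equal(belief_confidence(xs, 1, 2), 1 - (1 - xs)^2)
  expect_equal(belief_confidence(1, 7.3, 0.2), 1)
  expect_error(belief_confidence(1.2, 1, 1), "\\[0, 1\\]")
  expect_error(belief_confidence(0.5, 0, 1), "positive")
})

test_that("action probabilities normalize and honour the orientation", {
  for (orient in c("confidence", "swapped", "as_printed"))
    expect_equal(unname(action_probabilities(init_belief(), orient)),
                 c(0.5, 0.5))
  b <- belief_with(2, 1, 1, 2)
  ## from the closed forms above: I_{1/3}(2,1) = 1/9, I_{2/3}(1,2) = 8/9
  expect_equal(action_probabilities(b, "confidence")[["p_T"]], 8 / 9)
  expect_equal(action_probabilities(b, "swapped")[["p_T"]], 8 / 9)
  expect_equal(action_probabilities(b, "as_printed")[["p_T"]], 1 / 9)
  set.seed(11)
  for (i in 1:30) {
    b <- belief_with(runif(1, 0.1, 50), runif(1, 0.1, 50),
                     runif(1, 0.1, 50), runif(1, 0.1, 50))
    for (orient in c("confidence", "swapped", "as_printed")) {
      p <- action_probabilities(b, orient)
      expect_identical(sum(p), 1)
      expect_true(all(p >= 0 & p <= 1))
    }
  }
})

test_that("confidence orientation prefers the believed-better action", {
  sure_T <- belief_with(1e6, 1, 1, 1e6)
  expect_gt(action_probabilities(sure_T, "confidence")[["p_T"]], 0.999999)
  expect_lt(action_probabilities(sure_T, "as_printed")[["p_T"]], 1e-6)
})

test_that("expected update adds the expected belief mass and moves the state", {
  env <- standard_environment("moderate")
  up <- expected_update(init_belief(), nf_state(), theta = 0, env = env)
  ## symmetric start: p_T = 0.5, state unmoved, alpha_T grows by 0.5 * q_T
  expect_equal(up$state$sigma, 0)
  expect_equal(up$belief$alpha_T - 1, 0.5 * LOGISTIC_17, tolerance = 1e-14)

  ## increment bookkeeping: selection_weighted spreads one pseudo-observation
  ## across both actions, as_printed gives each action a full one
  for (i in 1:5) {
    b <- belief_with(runif(1, 0.5, 5), runif(1, 0.5, 5),
                     runif(1, 0.5, 5), runif(1, 0.5, 5))
    mass <- function(bb) bb$alpha_T + bb$beta_T + bb$alpha_F + bb$beta_F
    sw <- expected_update(b, nf_state(), 0.7, env,
                          variant = "selection_weighted")
    expect_equal(mass(sw$belief) - mass(b), 1)
    ap <- expected_update(b, nf_state(), 0.7, env, variant = "as_printed")
    expect_equal(ap$belief$alpha_T + ap$belief$beta_T -
                   (b$alpha_T + b$beta_T), 1)
    expect_equal(ap$belief$alpha_F + ap$belief$beta_F -
                   (b$alpha_F + b$beta_F), 1)
  }
})

test_that("no update ever shrinks a belief parameter", {
  env <- standard_environment("illiterate")
  b <- init_belief(); st <- nf_state()
  for (i in 1:200) {
    out <- expected_update(b, st, theta = sin(i), env = env)
    for (f in c("alpha_T", "beta_T", "alpha_F", "beta_F"))
      expect_gte(out$belief[[f]], b[[f]])
    b <- out$belief; st <- out$state
  }
})

test_that("state position stays consistent with the accumulated counts", {
  env <- standard_environment("moderate")
  for (dir in c("toward_trained", "printed_recursion")) {
    b <- init_belief(); st <- nf_state()
    for (i in 1:50) {
      out <- expected_update(b, st, theta = 0.3, env = env, sigma_dir = dir)
      b <- out$belief; st <- out$state
    }
    sign <- if (dir == "printed_recursion") 1 else -1
    expect_equal(st$sigma, sign * (st$n_trained - st$n_false) * env$step,
                 tolerance = 1e-10)
  }
})

test_that("operant conditioning emerges under fixed informative rewards", {
  ## hold reward probabilities at (0.9, 0.1) and iterate the expectation
  ## update by hand: the trained action must come to dominate
  q_T <- 0.9; q_F <- 0.1
  b <- init_belief()
  p_hist <- numeric(200)
  for (i in 1:200) {
    p <- action_probabilities(b, "confidence")
    p_hist[i] <- p[["p_T"]]
    b$alpha_T <- b$alpha_T + p[["p_T"]] * q_T
    b$beta_T <- b$beta_T + p[["p_T"]] * (1 - q_T)
    b$alpha_F <- b$alpha_F + p[["p_F"]] * q_F
    b$beta_F <- b$beta_F + p[["p_F"]] * (1 - q_F)
  }
  expect_true(all(diff(p_hist[-1]) >= -1e-12))
  expect_gt(max(p_hist), 0.95)
})

test_that("stochastic steps are reproducible and respect forced outcomes", {
  env <- standard_environment("moderate")
  walk <- function(seed) {
    set.seed(seed)
    b <- init_belief(); st <- nf_state()
    log <- character(0)
    for (i in 1:30) {
      out <- stochastic_step(b, st, theta = 0, env = env)
      b <- out$belief; st <- out$state
      log <- c(log, paste(out$action, out$rewarded))
    }
    list(log = log, belief = b, state = st)
  }
  expect_identical(walk(99), walk(99))

  ## reward probability ~1 for both actions at a far-negative threshold
  sure <- nf_env(D = 50)
  set.seed(1)
  for (i in 1:20) {
    out <- stochastic_step(init_belief(), nf_state(), theta = -9, env = sure)
    expect_true(out$rewarded)
  }
  ## extreme confidence: the trained action is all but certain
  set.seed(2)
  for (i in 1:20) {
    out <- stochastic_step(belief_with(1e6, 1, 1, 1e6), nf_state(),
                           theta = 0, env = env)
    expect_identical(out$action, "trained")
  }
})
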