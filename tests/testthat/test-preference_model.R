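test_that("the grid matches the task discretisation", {
  spec <- grid_spec()
  expect_length(spec$alpha, 241)
  expect_length(spec$beta, 241)
  expect_equal(range(spec$alpha), c(0, 30))
  expect_equal(range(spec$beta), c(-30, 30))
  expect_true(all(diff(spec$alpha) == 0.125))
  expect_true(all(diff(spec$beta) == 0.25))
})

test_that("option utility weights own payoff and the favourable gap", {
  expect_equal(option_utility(10, 5, alpha = 1, beta = 0), 10)
  expect_equal(option_utility(10, 5, alpha = 1, beta = 1), 15)
  # disadvantageous inequality is not penalised
  expect_equal(option_utility(5, 5, alpha = 2, beta = -3), 10)
  expect_equal(option_utility(5, 10, alpha = 2, beta = -3), 10)
})

test_that("discretised normal beliefs are normalised, floored, symmetric", {
  spec <- coarse_grid()
  b <- discretized_normal_belief(15, 4, 0, 5, spec)
  expect_equal(sum(b$mass), 1, tolerance = 1e-10)
  expect_true(all(b$mass >= 2.22e-16 * (1 - 1e-6)))
  # symmetric beta marginal about zero
  pb <- colSums(b$mass)
  below <- sum(pb[spec$beta < 0]); above <- sum(pb[spec$beta > 0])
  expect_equal(below, above, tolerance = 1e-8)
  # tiny spread concentrates on the nearest grid point
  b2 <- discretized_normal_belief(15.1, 1e-6, -7.4, 1e-6, spec)
  expect_equal(marginal_summary(b2, "alpha")$median, 15)
  expect_equal(marginal_summary(b2, "beta")$median, -7)
  expect_error(discretized_normal_belief(10, -1, 0, 1, spec), "positive")
})

test_that("choice probability agrees with the brute-force grid sum", {
  spec <- tiny_grid()
  pair <- list(r_ppt_1 = 5, r_par_1 = 5, r_ppt_2 = 10, r_par_2 = 5)
  beliefs <- list(
    discretized_normal_belief(10, 5, -5, 8, spec),
    uniform_belief(spec),
    discretized_normal_belief(2, 1, 15, 3, spec))
  for (b in beliefs) {
    expect_equal(choice_probability(pair, b), brute_choice_probability(pair, b),
                 tolerance = 1e-12)
  }
  # mass split over two states averages the two point probabilities
  b <- uniform_belief(spec)
  b$mass[] <- 0
  b$mass[2, 3] <- 0.5
  b$mass[4, 1] <- 0.5
  p1 <- plogis(option_utility(5, 5, spec$alpha[2], spec$beta[3]) -
                 option_utility(10, 5, spec$alpha[2], spec$beta[3]))
  p2 <- plogis(option_utility(5, 5, spec$alpha[4], spec$beta[1]) -
                 option_utility(10, 5, spec$alpha[4], spec$beta[1]))
  expect_equal(choice_probability(pair, b), (p1 + p2) / 2, tolerance = 1e-12)
})

test_that("a point-mass belief with zero utility difference gives 0.5", {
  spec <- coarse_grid()
  b <- discretized_normal_belief(0, 1e-7, 0, 1e-7, spec)
  pair <- list(r_ppt_1 = 5, r_par_1 = 5, r_ppt_2 = 10, r_par_2 = 5)
  # at (alpha, beta) = (0, 0) every option is worth 0
  expect_equal(choice_probability(pair, b), 0.5, tolerance = 1e-9)
  # large positive utility difference saturates towards 1
  b2 <- discretized_normal_belief(20, 1e-7, 10, 1e-7, spec)
  pair2 <- list(r_ppt_1 = 10, r_par_1 = 5, r_ppt_2 = 5, r_par_2 = 5)
  expect_gt(choice_probability(pair2, b2), 1 - 1e-9)
})

test_that("Bayes updates normalise, commute, and match batch updating", {
  spec <- tiny_grid()
  prior <- discretized_normal_belief(10, 6, -5, 8, spec)
  pairA <- list(r_ppt_1 = 5, r_par_1 = 5, r_ppt_2 = 10, r_par_2 = 5)
  pairB <- list(r_ppt_1 = 10, r_par_1 = 10, r_ppt_2 = 10, r_par_2 = 5)
  ab <- bayes_update(bayes_update(prior, pairA, 1), pairB, 2)
  ba <- bayes_update(bayes_update(prior, pairB, 2), pairA, 1)
  expect_equal(sum(ab$mass), 1, tolerance = 1e-10)
  expect_equal(ab$mass, ba$mass, tolerance = 1e-10)
  # flat prior: posterior proportional to the likelihood map
  flat <- uniform_belief(spec)
  post <- bayes_update(flat, pairA, 1)
  lik <- plogis(outer(spec$alpha * (5 - 10),
                      spec$beta * (0 - 5), "+"))
  expect_equal(post$mass, lik / sum(lik), tolerance = 1e-8)
  expect_error(bayes_update(prior, pairA, 3), "1 or 2")
})

test_that("sequential phase-2 filtering equals the batch posterior", {
  spec <- coarse_grid()
  params <- fixture_params_m1()
  rec <- fixture_record(spec = spec)
  fl <- selfother:::model_filter(model_spec("M1"), as.list(params), rec, spec)
  batch <- fl$prior2
  trials <- env_phase(rec$env, 2)
  for (t in seq_len(nrow(trials))) {
    lik <- plogis(outer(spec$alpha * (trials$r_ppt_1[t] - trials$r_ppt_2[t]),
                        spec$beta * (max(trials$r_ppt_1[t] - trials$r_par_1[t], 0) -
                                       max(trials$r_ppt_2[t] - trials$r_par_2[t], 0)),
                        "+"))
    if (rec$phase2_partner[t] == 2) lik <- 1 - lik
    batch$mass <- batch$mass * lik
  }
  batch$mass <- batch$mass / sum(batch$mass)
  expect_equal(fl$posterior$mass, batch$mass, tolerance = 1e-8)
})

test_that("marginal summaries recover construction parameters", {
  spec <- grid_spec()
  b <- discretized_normal_belief(10, 1e-7, -5, 1e-7, spec)
  sa <- marginal_summary(b, "alpha"); sb <- marginal_summary(b, "beta")
  expect_equal(sa$median, 10); expect_equal(sb$median, -5)
  # the noise floor leaves a vanishing residual spread
  expect_lt(sa$sd, 1e-3)
  expect_lt(sb$sd, 1e-3)
  b2 <- discretized_normal_belief(15, 3, -7.5, 3, spec)
  expect_lte(abs(marginal_summary(b2, "beta")$median - -7.5), 0.25)
  expect_lte(abs(marginal_summary(b2, "alpha")$median - 15), 0.125)
})

test_that("KL divergence is zero at identity, positive otherwise, exact on toys", {
  spec <- coarse_grid()
  b <- discretized_normal_belief(12, 4, -3, 6, spec)
  expect_equal(kl_step(b, b, "joint"), 0, tolerance = 1e-12)
  b2 <- discretized_normal_belief(14, 4, -3, 6, spec)
  expect_gt(kl_step(b2, b, "joint"), 0)
  expect_gte(kl_step(b2, b, "alpha"), 0)
  # hand-evaluated two-point toy
  expect_equal(selfother:::kl_discrete(c(0.8, 0.2), c(0.5, 0.5)),
               0.8 * log(1.6) + 0.2 * log(0.4), tolerance = 1e-12)
  spec2 <- grid_spec(alpha_step = 1, beta_step = 1)
  expect_error(kl_step(discretized_normal_belief(1, 1, 0, 1, spec2), b),
               "different grids")
})
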