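test_that("the model lattice has the stated structure and free-parameter counts", {
  counts <- c(M1 = 6, M2 = 6, M3 = 8, M4 = 8, Beta = 3)
  for (nm in names(counts)) {
    m <- model_spec(nm)
    expect_length(m$free_params, counts[[nm]])
  }
  expect_true(model_spec("M1")$self_insertion && model_spec("M1")$contagion)
  expect_true(model_spec("M2")$self_insertion && !model_spec("M2")$contagion)
  expect_true(!model_spec("M3")$self_insertion && model_spec("M3")$contagion)
  expect_true(!model_spec("M4")$self_insertion && !model_spec("M4")$contagion)
  expect_equal(model_spec("Beta")$utility_dims, "relative-only")
})

test_that("phase-2 priors are centred per the insertion flag", {
  spec <- coarse_grid()
  p1 <- build_phase2_prior("M1", fixture_params_m1(), spec)
  expect_lte(abs(marginal_summary(p1, "alpha")$median - 18.41), 0.5)
  expect_lte(abs(marginal_summary(p1, "beta")$median - -7.5), 1)
  p4 <- build_phase2_prior("M4", fixture_params_m4(), spec)
  expect_lte(abs(marginal_summary(p4, "beta")$median - -0.47), 1)
  expect_lte(abs(marginal_summary(p4, "alpha")$median - 10.57), 0.5)
  # M4 prior ignores the self medians entirely
  p4b <- build_phase2_prior("M4", replace(fixture_params_m4(), "beta_m", 20), spec)
  expect_equal(p4$mass, p4b$mass)
  # missing prior central tendencies must error
  expect_error(build_phase2_prior("M4", fixture_params_m1(), spec),
               "prior central tendencies")
  # tiny reference spread approaches a point mass at the self medians
  tight <- replace(fixture_params_m1(), c("alpha_ref", "beta_ref"), c(1e-6, 1e-6))
  pt <- build_phase2_prior("M1", tight, spec)
  expect_gt(max(pt$mass), 0.999)
})

test_that("contagion combines self and partner by precision weighting", {
  post <- list(alpha = list(median = 10, sd = 2), beta = list(median = 5, sd = 2))
  self <- self_preferences(20, -10, 4, 4)
  ref <- c(alpha_ref = 3, beta_ref = 3)
  sh <- contagion_update(self, ref, post)
  # shifted spread is strictly below the self spread (precisions add)
  expect_lt(sh$alpha_sd, self$alpha_sd)
  expect_lt(sh$beta_sd, self$beta_sd)
  # near-certain self barely moves
  sh2 <- contagion_update(self_preferences(20, -10, 1e-4, 1e-4), ref, post)
  expect_equal(sh2$alpha_m, 20, tolerance = 1e-4)
  expect_equal(sh2$beta_m, -10, tolerance = 1e-4)
  # equal precisions land at the midpoint
  sd_match <- sqrt(2 * 3^2 + 2^2)
  sh3 <- contagion_update(self_preferences(20, -10, sd_match, sd_match), ref, post)
  expect_equal(sh3$alpha_m, (20 + 10) / 2, tolerance = 1e-10)
  expect_equal(sh3$beta_m, (-10 + 5) / 2, tolerance = 1e-10)
  # monotone: a more uncertain self is drawn further toward the partner
  shifts <- sapply(c(2, 4, 8, 16), function(s)
    contagion_update(self_preferences(20, -10, 4, s), ref, post)$beta_m)
  expect_true(all(diff(shifts) > 0))
  expect_error(contagion_update(self_preferences(20, -10, 4, 4),
                                c(alpha_ref = 0, beta_ref = 3), post),
               "positive")
})

test_that("the null-preference reference model scores 126 log 0.5", {
  # a grid holding only the indifference state (alpha, beta) = (0, 0) makes
  # every utility difference 0, so every choice and prediction probability
  # is exactly 0.5 across all 126 trials
  null_spec <- grid_spec(alpha_step = 1, beta_step = 1,
                         alpha_range = c(0, 0), beta_range = c(0, 0))
  params <- c(alpha_m = 0, beta_m = 0, alpha_sd = 1, beta_sd = 1,
              alpha_ref = 1, beta_ref = 1,
              prior_alpha_m = 0, prior_beta_m = 0)
  rec <- fixture_record(spec = coarse_grid())
  ll <- subject_loglik("M4", params, rec, null_spec)
  expect_equal(ll, 126 * log(0.5), tolerance = 1e-9)
  expect_lt(abs(ll - -87.33), 0.01)
})

test_that("subject likelihoods match per-trial brute force on a toy record", {
  spec <- tiny_grid()
  env <- fixture_env(seed = 9)
  params <- c(alpha_m = 10, beta_m = -5, alpha_sd = 5, beta_sd = 5,
              alpha_ref = 6, beta_ref = 6)
  partner <- rep(c(1L, 2L), length.out = 54)
  rec <- simulate_subject("M2", params, env, partner, seed = 31, spec = spec)
  ll <- subject_loglik("M2", params, rec, spec)
  # brute force: phase 1/3 static products, phase 2 sequential updates
  bel1 <- discretized_normal_belief(10, 5, -5, 5, spec)
  manual <- 0
  for (t in seq_len(36)) {
    p <- choice_probability(env_phase(env, 1)[t, ], bel1)
    manual <- manual + log(ifelse(rec$phase1_choices[t] == 1, p, 1 - p))
  }
  bel <- build_phase2_prior("M2", params, spec)
  for (t in seq_len(54)) {
    pair <- env_phase(env, 2)[t, ]
    p <- choice_probability(pair, bel)
    manual <- manual + log(ifelse(rec$phase2_predictions[t] == 1, p, 1 - p))
    bel <- bayes_update(bel, pair, rec$phase2_partner[t])
  }
  for (t in seq_len(36)) {
    p <- choice_probability(env_phase(env, 3)[t, ], bel1)
    manual <- manual + log(ifelse(rec$phase3_choices[t] == 1, p, 1 - p))
  }
  expect_equal(ll, manual, tolerance = 1e-6)
  expect_lt(ll, 0)
})

test_that("simulation is reproducible and respects the model lattice", {
  spec <- coarse_grid()
  env <- fixture_env(seed = 13)
  partner <- rep(c(1L, 2L), length.out = 54)
  r1 <- simulate_subject("M1", fixture_params_m1(), env, partner, 77, spec)
  r2 <- simulate_subject("M1", fixture_params_m1(), env, partner, 77, spec)
  expect_identical(r1$phase1_choices, r2$phase1_choices)
  expect_identical(r1$phase2_predictions, r2$phase2_predictions)
  expect_identical(r1$phase3_choices, r2$phase3_choices)
  expect_error(simulate_subject("M1", fixture_params_m1(), env, partner[-1],
                                77, spec),
               "partner decisions")
  # without contagion, phase-3 choice probabilities equal phase-1
  # probabilities for the same option pair
  fl <- selfother:::model_filter(model_spec("M4"), as.list(fixture_params_m4()),
                                 simulate_subject("M4", fixture_params_m4(),
                                                  env, partner, 78, spec),
                                 spec)
  pairs1 <- env_phase(env, 1)[, c("r_ppt_1", "r_par_1", "r_ppt_2", "r_par_2")]
  pairs3 <- env_phase(env, 3)[, c("r_ppt_1", "r_par_1", "r_ppt_2", "r_par_2")]
  key1 <- apply(pairs1, 1, paste, collapse = ",")
  key3 <- apply(pairs3, 1, paste, collapse = ",")
  shared <- intersect(key1, key3)
  for (k in shared[1:3]) {
    expect_equal(fl$p1[match(k, key1)], fl$p3[match(k, key3)], tolerance = 1e-12)
  }
})

test_that("a strongly prosocial simulated subject picks the equal split", {
  spec <- coarse_grid()
  env <- fixture_env(seed = 21)
  params <- c(alpha_m = 1, beta_m = -25, alpha_sd = 0.5, beta_sd = 0.5,
              alpha_ref = 4, beta_ref = 4)
  rec <- simulate_subject("M2", params, env, rep(1L, 54), seed = 5, spec = spec)
  counts <- choice_type_counts(rec)
  pc <- counts[counts$phase == 1 & counts$pair_type == "prosocial-competitive", ]
  expect_gte(pc$count[pc$role == "prosocial"], 11)
})

test_that("the Beta model ignores the alpha dimension", {
  spec <- coarse_grid()
  env <- fixture_env(seed = 33)
  partner <- rep(c(1L, 2L, 2L), length.out = 54)
  params <- c(beta_m = -8, beta_sd = 4, beta_ref = 5)
  rec <- simulate_subject("Beta", params, env, partner, seed = 55, spec = spec)
  ll <- subject_loglik("Beta", params, rec, spec)
  expect_lt(ll, 0)
  # likelihood is computed on a one-point alpha grid fixed at 1
  ws <- selfother:::ws_for(model_spec("Beta"), env, spec)
  expect_equal(ws$spec$alpha, 1)
})
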