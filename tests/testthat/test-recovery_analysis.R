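test_that("accuracy summaries count prediction hits", {
  coh <- generate_cohort(default_group_spec("control-like"), n = 4, seed = 9)
  acc <- accuracy_summary(coh$records)
  expect_length(acc$per_subject, 4)
  expect_length(acc$trialwise, 54)
  expect_true(all(acc$per_subject >= 0 & acc$per_subject <= 1))
  # an all-correct record scores 1
  r <- coh$records[[1]]
  r$phase2_predictions <- r$phase2_partner
  r$phase2_feedback <- rep(TRUE, 54)
  expect_equal(accuracy_summary(list(r))$per_subject, 1)
})

test_that("simulated phase-2 accuracy rises from the first to the last third", {
  coh <- generate_cohort(default_group_spec("control-like"), n = 25, seed = 14)
  acc <- accuracy_summary(coh$records)
  early <- mean(acc$trialwise[1:18])
  late <- mean(acc$trialwise[37:54])
  expect_gt(late, early)
})

test_that("belief trajectories are non-negative with declining surprise", {
  coh <- generate_cohort(default_group_spec("control-like"), n = 10, seed = 15)
  params <- lapply(seq_len(10), function(i)
    unlist(coh$truth[i, model_spec("M1")$free_params]))
  tr <- belief_trajectories(params, coh$records, "M1", spec = coarse_grid())
  expect_equal(nrow(tr), 10 * 54)
  expect_true(all(tr$kl_alpha >= 0 & tr$kl_beta >= 0 & tr$kl_joint >= 0))
  m <- tapply(tr$kl_joint, tr$trial, mean)
  # mean informational surprise declines over phase 2
  expect_gt(mean(m[1:10]), mean(m[45:54]))
  expect_lt(coef(lm(m ~ seq_along(m)))[2], 0)
  # first-trial surprise exceeds last-trial surprise
  expect_gt(m[1], m[54])
})

test_that("a partner matching the prior produces near-zero surprise", {
  spec <- coarse_grid()
  env <- fixture_env(seed = 71)
  params <- fixture_params_m1()
  # partner behaves exactly as the subject's own point preferences
  partner <- deterministic_choices(params[["alpha_m"]], params[["beta_m"]],
                                   env_phase(env, 2))
  rec <- simulate_subject("M1", params, env, partner, seed = 3, spec = spec)
  tr <- belief_trajectories(list(params), list(rec), "M1", spec = spec)
  # matched partner: late-phase updates are tiny
  expect_lt(mean(tr$kl_joint[40:54]), 0.01)
})

test_that("contagion metrics are zero without contagion, monotone with it", {
  coh <- generate_cohort(default_group_spec("bpd-like"), n = 3, seed = 16)
  fits4 <- lapply(seq_len(3), function(i) {
    structure(list(model = "M4",
                   params = unlist(coh$truth[i, model_spec("M4")$free_params])),
              class = "so_subject_fit")
  })
  cm4 <- contagion_metrics(fits4, coh$records, spec = coarse_grid())
  expect_true(all(cm4$delta_alpha_m == 0 & cm4$delta_beta_m == 0))
  expect_false(any(cm4$contagion))
  # under M1 assumptions, doubling self uncertainty increases the shift
  p <- fixture_params_m1()
  coh1 <- generate_cohort(default_group_spec("control-like"), n = 3, seed = 17)
  mk <- function(params) lapply(1:3, function(i)
    structure(list(model = "M1", params = params), class = "so_subject_fit"))
  cm_a <- contagion_metrics(mk(p), coh1$records, spec = coarse_grid())
  p2 <- replace(p, c("alpha_sd", "beta_sd"), c(12, 12))
  cm_b <- contagion_metrics(mk(p2), coh1$records, spec = coarse_grid())
  expect_true(all(cm_b$delta_beta_m > cm_a$delta_beta_m))
  expect_true(all(cm_a$contagion))
})

test_that("contagion shifts under M1 and M3 assumptions agree on synthetic data", {
  coh <- generate_cohort(default_group_spec("control-like"), n = 12, seed = 18)
  p1 <- lapply(seq_len(12), function(i) {
    pr <- unlist(coh$truth[i, model_spec("M1")$free_params])
    structure(list(model = "M1", params = pr), class = "so_subject_fit")
  })
  p3 <- lapply(seq_len(12), function(i) {
    pr <- unlist(coh$truth[i, model_spec("M1")$free_params])
    pr <- c(pr, prior_alpha_m = unname(pr["alpha_m"]),
            prior_beta_m = unname(pr["beta_m"]))
    structure(list(model = "M3", params = pr), class = "so_subject_fit")
  })
  cm1 <- contagion_metrics(p1, coh$records, spec = coarse_grid())
  cm3 <- contagion_metrics(p3, coh$records, spec = coarse_grid())
  expect_gt(cor(cm1$delta_beta_m, cm3$delta_beta_m, method = "spearman"), 0.5)
})

test_that("choice type counts sum to the per-type trial totals", {
  coh <- generate_cohort(default_group_spec("control-like"), n = 2, seed = 19)
  counts <- choice_type_counts(coh$records[[1]])
  per_type <- tapply(counts$count, list(counts$phase, counts$pair_type), sum)
  expect_true(all(per_type == 12))
  # strongly prosocial preferences show up as prosocial choice counts
  spec <- coarse_grid()
  env <- fixture_env(seed = 91)
  rec <- simulate_subject("M2", c(alpha_m = 1, beta_m = -25, alpha_sd = 0.5,
                                  beta_sd = 0.5, alpha_ref = 4, beta_ref = 4),
                          env, rep(1L, 54), seed = 6, spec = spec)
  cc <- choice_type_counts(rec)
  pro <- sum(cc$count[cc$role == "prosocial"])
  expect_gt(pro, 0.8 * sum(cc$count[cc$pair_type != "individualistic-competitive"]))
})
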