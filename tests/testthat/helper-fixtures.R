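# Shared fixtures: a small environment, a coarse grid for fast fitting,
# and a canonical control-like parameter set.

coarse_grid <- function() grid_spec(alpha_step = 0.5, beta_step = 1)

tiny_grid <- function() {
  # 5 x 5 sub-grid for brute-force checks
  structure(list(alpha = seq(0, 20, by = 5), beta = seq(-20, 20, by = 10)),
            class = "so_grid")
}

fixture_env <- function(seed = 101) generate_environment(seed = seed)

fixture_params_m1 <- function() {
  c(alpha_m = 18.41, beta_m = -7.5, alpha_sd = 6, beta_sd = 6,
    alpha_ref = 8, beta_ref = 8)
}

fixture_params_m4 <- function() {
  c(alpha_m = 10.57, beta_m = -6.59, alpha_sd = 4.5, beta_sd = 5,
    alpha_ref = 4, beta_ref = 6.5, prior_alpha_m = 10.57, prior_beta_m = -0.47)
}

fixture_record <- function(model = "M1", params = fixture_params_m1(),
                           seed = 202, spec = coarse_grid()) {
  sim <- simulate_matched_subject(model, params, seed, spec)
  sim$record
}

# Brute-force choice probability: explicit double loop over all grid states.
brute_choice_probability <- function(pair, belief) {
  g <- belief$spec
  p <- 0
  for (i in seq_along(g$alpha)) {
    for (j in seq_along(g$beta)) {
      du <- option_utility(pair$r_ppt_1, pair$r_par_1, g$alpha[i], g$beta[j]) -
        option_utility(pair$r_ppt_2, pair$r_par_2, g$alpha[i], g$beta[j])
      p <- p + plogis(du) * belief$mass[i, j]
    }
  }
  p
}
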