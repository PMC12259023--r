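#' Simulate-and-refit parameter recovery
#'
#' Mirrors the generative-accuracy workflow: take per-subject parameters
#' under a model (by default, the parameters estimated by fitting a
#' synthetic cohort drawn at the group defaults — the analogue of
#' "each participant's individual parameters from the winning model"),
#' simulate a fresh record for every parameter vector (fresh environment,
#' partner matching and behaviour seeds), refit with the same model, and
#' report per-parameter Spearman rank correlations between generating and
#' re-estimated values. Parameters with zero generating variance are
#' reported as `NA`.
#'
#' @param group an `so_group_spec`.
#' @param config a [fit_config()].
#' @param seed integer seed (cohort generation and fresh simulation).
#' @param n cohort size.
#' @param model generating/refitting model (defaults to the dominant model).
#' @param generator_params optional data frame / list of named per-subject
#'   parameter vectors to simulate from, replacing the fit-the-cohort stage.
#' @param cohort optional pre-generated `so_cohort` used for that stage.
#' @param sim_spec grid used for simulation.
#' @return an `so_recovery` list: `rho` (named per-parameter Spearman),
#'   `min_rho`, `generating`, `recovered`, `failed` (refit-excluded
#'   subjects), `model`, `n`.
#' @export
run_parameter_recovery <- function(group = default_group_spec("control-like"),
                                   config = fit_config(), seed = 1L,
                                   n = group$n, model = group$dominant_model,
                                   generator_params = NULL, cohort = NULL,
                                   sim_spec = grid_spec()) {
  model <- as_model(model)
  if (is.null(generator_params)) {
    if (is.null(cohort))
      cohort <- generate_cohort(group, n = n, model = model, seed = seed,
                                spec = sim_spec)
    base_fit <- fit_cohort(model, cohort$records, config)
    generator_params <- base_fit$params
  }
  if (is.data.frame(generator_params))
    generator_params <- lapply(seq_len(nrow(generator_params)),
                               function(i) unlist(generator_params[i, ]))
  n <- length(generator_params)
  if (n < 10) stop("parameter recovery needs n >= 10")
  records <- vector("list", n)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    sim <- tryCatch(
      simulate_matched_subject(model, generator_params[[i]],
                               derive_seed(seed, 1000 + i), sim_spec),
      error = function(e) NULL)
    if (is.null(sim)) { ok[i] <- FALSE; next }
    records[[i]] <- sim$record
  }
  if (any(!ok))
    message("excluded ", sum(!ok), " subject(s) whose simulation failed")
  refit <- fit_cohort(model, records[ok], config)
  gen <- as.data.frame(do.call(rbind, generator_params[ok]))
  rec <- refit$params
  rho <- vapply(model$free_params, function(p) {
    if (length(unique(gen[[p]])) < 2) return(NA_real_)
    cor(gen[[p]], rec[[p]], method = "spearman")
  }, numeric(1))
  structure(list(rho = rho, min_rho = min(rho, na.rm = TRUE),
                 generating = gen, recovered = rec, failed = which(!ok),
                 model = model$name, n = sum(ok)),
            class = "so_recovery")
}

#' @export
print.so_recovery <- function(x, ...) {
  cat(sprintf("parameter recovery (%s, n = %d): min Spearman rho = %.3f\n",
              x$model, x$n, x$min_rho))
  print(round(x$rho, 3))
  invisible(x)
}

#' Simulate a mixed-model cohort and recover the model lattice
#'
#' Builds a cohort with a stated number of subjects per generating model
#' (all drawn from the same group's parameter distributions), runs
#' [hierarchical_compare()] over the lattice, and reports frequencies,
#' protected exceedance probabilities, and the Spearman association between
#' generative membership and recovered responsibility per model.
#'
#' @param group an `so_group_spec` providing the parameter distributions.
#' @param mixture named integer vector: subjects per generating model, e.g.
#'   `c(M1 = 35, M2 = 5, M3 = 5, M4 = 5)`.
#' @param models models entered into the comparison.
#' @param config a [fit_config()].
#' @param seed integer seed.
#' @param sim_spec grid used for simulation.
#' @return an `so_model_recovery` list: `comparison` (an `so_comparison`),
#'   `winner`, `responsibility_assoc`, `truth`.
#' @export
run_model_recovery <- function(group = default_group_spec("control-like"),
                               mixture = c(M1 = 35, M2 = 5, M3 = 5, M4 = 5),
                               models = c("M1", "M2", "M3", "M4"),
                               config = fit_config(), seed = 1L,
                               sim_spec = grid_spec()) {
  stopifnot(all(mixture >= 0), sum(mixture) >= 2)
  parts <- list()
  for (j in seq_along(mixture)) {
    if (mixture[j] == 0) next
    parts[[length(parts) + 1]] <-
      generate_cohort(group, n = mixture[j], model = names(mixture)[j],
                      seed = derive_seed(seed, 100 + j), spec = sim_spec)
  }
  cohort <- do.call(bind_cohorts, parts)
  cmp <- hierarchical_compare(models, cohort$records, config)
  assoc <- vapply(cmp$models, function(m) {
    member <- as.numeric(cohort$truth$model == m)
    if (length(unique(member)) < 2) return(NA_real_)
    cor(member, cmp$responsibility[, m], method = "spearman")
  }, numeric(1))
  structure(list(comparison = cmp,
                 winner = cmp$models[which.max(cmp$pxp)],
                 responsibility_assoc = assoc,
                 truth = cohort$truth),
            class = "so_model_recovery")
}

#' @export
print.so_model_recovery <- function(x, ...) {
  cat("model recovery: winner by protected exceedance =", x$winner, "\n")
  print(x$comparison)
  invisible(x)
}

#' Trial-wise belief-update trajectories in phase 2
#'
#' Replays phase 2 for each subject under the given model and parameters and
#' returns the per-trial Kullback-Leibler divergence between consecutive
#' beliefs (alpha marginal, beta marginal, joint; the first trial is
#' measured against the prior) plus running prediction accuracy.
#'
#' @param params_list per-subject named parameter vectors (model space),
#'   e.g. a row-split of [fit_cohort()]'s `params` or the cohort truth.
#' @param cohort list of `so_subject` records.
#' @param model model name or `so_model`.
#' @param spec grid specification for the replay.
#' @return data frame: `subject`, `trial`, `kl_alpha`, `kl_beta`,
#'   `kl_joint`, `correct`, `running_accuracy`.
#' @export
belief_trajectories <- function(params_list, cohort, model,
                                spec = grid_spec()) {
  model <- as_model(model)
  out <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    data <- cohort[[i]]
    fl <- model_filter(model, params_list[[i]], data, spec, keep_path = TRUE)
    g <- fl$ws$spec
    prev <- fl$prior2$mass
    T2 <- ncol(fl$path)
    ka <- kb <- kj <- numeric(T2)
    for (t in seq_len(T2)) {
      cur <- matrix(fl$path[, t], length(g$alpha))
      ka[t] <- kl_discrete(rowSums(cur), rowSums(prev))
      kb[t] <- kl_discrete(colSums(cur), colSums(prev))
      kj[t] <- kl_discrete(cur, prev)
      prev <- cur
    }
    correct <- as.integer(data$phase2_feedback)
    out[[i]] <- data.frame(subject = i, trial = seq_len(T2),
                           kl_alpha = ka, kl_beta = kb, kl_joint = kj,
                           correct = correct,
                           running_accuracy = cumsum(correct) / seq_len(T2))
  }
  do.call(rbind, out)
}

#' Per-subject contagion metrics
#'
#' For contagion-bearing fits (M1, M3, Beta), replays phase 2 and reports
#' the absolute shift in central tendency and the change in spread between
#' the phase-1 and phase-3 beliefs, per dimension. For M2/M4 fits all
#' metrics are zero by construction and flagged.
#'
#' @param fits list of `so_subject_fit` (one model across subjects).
#' @param cohort list of `so_subject` records.
#' @param spec grid specification.
#' @return data frame: `subject`, `delta_alpha_m`, `delta_beta_m`,
#'   `dsd_alpha`, `dsd_beta`, `contagion` (logical flag).
#' @export
contagion_metrics <- function(fits, cohort, spec = grid_spec()) {
  out <- vector("list", length(fits))
  for (i in seq_along(fits)) {
    model <- as_model(fits[[i]]$model)
    params <- as.list(fits[[i]]$params)
    if (!model$contagion) {
      out[[i]] <- data.frame(subject = i, delta_alpha_m = 0, delta_beta_m = 0,
                             dsd_alpha = 0, dsd_beta = 0, contagion = FALSE)
      next
    }
    fl <- model_filter(model, params, cohort[[i]], spec)
    post <- list(alpha = marginal_moments(fl$posterior, "alpha"),
                 beta = marginal_moments(fl$posterior, "beta"))
    if (model$utility_dims == "relative-only") {
      sh <- contagion_update(list(alpha_m = 1, beta_m = params$beta_m,
                                  alpha_sd = 1, beta_sd = params$beta_sd),
                             list(alpha_ref = 1, beta_ref = params$beta_ref),
                             post)
      out[[i]] <- data.frame(subject = i, delta_alpha_m = 0,
                             delta_beta_m = abs(sh$beta_m - params$beta_m),
                             dsd_alpha = 0,
                             dsd_beta = sh$beta_sd - params$beta_sd,
                             contagion = TRUE)
      next
    }
    sh <- contagion_update(params, params, post)
    out[[i]] <- data.frame(subject = i,
                           delta_alpha_m = abs(sh$alpha_m - params$alpha_m),
                           delta_beta_m = abs(sh$beta_m - params$beta_m),
                           dsd_alpha = sh$alpha_sd - params$alpha_sd,
                           dsd_beta = sh$beta_sd - params$beta_sd,
                           contagion = TRUE)
  }
  do.call(rbind, out)
}

#' Phase-2 prediction accuracy summaries
#'
#' @param cohort list of `so_subject` records.
#' @return list with `per_subject` (fraction of correct predictions) and
#'   `trialwise` (mean accuracy across subjects per trial).
#' @export
accuracy_summary <- function(cohort) {
  acc <- vapply(cohort, function(s) mean(s$phase2_feedback), numeric(1))
  fb <- do.call(rbind, lapply(cohort, function(s) as.integer(s$phase2_feedback)))
  list(per_subject = acc, trialwise = colMeans(fb))
}

#' Choice-type counts per phase
#'
#' Counts, within each pair type of phases 1 and 3, how often the subject
#' chose the option in each orientation role (e.g. prosocial choices on
#' prosocial-individualistic pairs).
#'
#' @param record an `so_subject`.
#' @return data frame: `phase`, `pair_type`, `role`, `count`.
#' @export
choice_type_counts <- function(record) {
  env <- record$env
  out <- list()
  for (ph in c(1, 3)) {
    trials <- env_phase(env, ph)
    choices <- if (ph == 1) record$phase1_choices else record$phase3_choices
    roles <- vapply(seq_len(nrow(trials)), function(i) {
      classify_options(trials[i, ])$roles[choices[i]]
    }, character(1))
    tab <- table(pair_type = trials$pair_type, role = roles)
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(df)[3] <- "count"
    df$phase <- ph
    out[[length(out) + 1]] <- df[, c("phase", "pair_type", "role", "count")]
  }
  do.call(rbind, out)
}
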