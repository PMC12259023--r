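#' Default synthetic group specifications
#'
#' Two cohort archetypes seeded by the study-scale group central tendencies:
#' a control-like group dominated by the full insertion-plus-contagion model
#' (M1) with mean preferences alpha_m = 18.41, beta_m = -7.50, and a
#' bpd-like group dominated by the disintegrated model (M4) with mean
#' alpha_m = 10.57, beta_m = -6.59 and near-neutral partner-prior relative
#' preferences (mean -0.47). Between-subject dispersions are not part of the
#' printed group summaries; the defaults (alpha_m sd 6, beta_m sd 4 for
#' control-like; 60% of those for bpd-like, whose members are more certain)
#' are configuration, not estimates. Spread-type parameters are drawn
#' log-normally around the listed medians with log-sd `spread_sdlog`.
#'
#' @param label `"control-like"` or `"bpd-like"`.
#' @return an `so_group_spec` list: `label`, `dominant_model`, `n`, `means`
#'   (named parameter medians/means), `between_sd` (for central
#'   tendencies), `spread_sdlog`.
#' @export
default_group_spec <- function(label = c("control-like", "bpd-like")) {
  label <- match.arg(label)
  spec <- if (label == "control-like") {
    list(label = label, dominant_model = "M1", n = 50,
         means = c(alpha_m = 18.41, beta_m = -7.50,
                   alpha_sd = 6, beta_sd = 6,
                   alpha_ref = 8, beta_ref = 8,
                   # free partner priors, used when simulating M3/M4 members
                   # of a control-like cohort: neutral, detached from self
                   prior_alpha_m = 10, prior_beta_m = 0),
         between_sd = c(alpha_m = 6, beta_m = 4,
                        prior_alpha_m = 4, prior_beta_m = 3),
         spread_sdlog = 0.4)
  } else {
    list(label = label, dominant_model = "M4", n = 50,
         means = c(alpha_m = 10.57, beta_m = -6.59,
                   alpha_sd = 4.5, beta_sd = 5,
                   alpha_ref = 4, beta_ref = 6.5,
                   prior_alpha_m = 10.57, prior_beta_m = -0.47),
         between_sd = c(alpha_m = 3.6, beta_m = 2.4,
                        prior_alpha_m = 3.6, prior_beta_m = 2.4),
         spread_sdlog = 0.4)
  }
  structure(spec, class = "so_group_spec")
}

# One subject's generating parameters for `model` under a group spec.
draw_subject_params <- function(group, model, seed) {
  model <- as_model(model)
  m <- group$means; bsd <- group$between_sd
  with_seed(seed, {
    p <- c(
      alpha_m = clip(rnorm(1, m[["alpha_m"]], bsd[["alpha_m"]]), 0, 30),
      beta_m = clip(rnorm(1, m[["beta_m"]], bsd[["beta_m"]]), -30, 30),
      alpha_sd = rlnorm(1, log(m[["alpha_sd"]]), group$spread_sdlog),
      beta_sd = rlnorm(1, log(m[["beta_sd"]]), group$spread_sdlog),
      alpha_ref = rlnorm(1, log(m[["alpha_ref"]]), group$spread_sdlog),
      beta_ref = rlnorm(1, log(m[["beta_ref"]]), group$spread_sdlog),
      prior_alpha_m = clip(rnorm(1, m[["prior_alpha_m"]], bsd[["prior_alpha_m"]]), 0, 30),
      prior_beta_m = clip(rnorm(1, m[["prior_beta_m"]], bsd[["prior_beta_m"]]), -30, 30)
    )
    p[model$free_params]
  })
}

#' Simulate one subject end-to-end, including partner matching
#'
#' Generates an environment, simulates phase-1 choices, infers the phase-1
#' point estimate, matches a partner at the target dissimilarity, then
#' simulates the full three-phase record.
#'
#' @param model model name or `so_model`.
#' @param params named generating parameters (model space).
#' @param seed integer seed (environment, behaviour and matching streams
#'   are derived from it).
#' @param spec grid specification.
#' @param target_dissimilarity partner-matching target.
#' @return list with `record` (`so_subject`), `est` (phase-1 point
#'   estimate), `partner` (`so_partner`).
#' @export
simulate_matched_subject <- function(model, params, seed, spec = grid_spec(),
                                     target_dissimilarity = 0.5) {
  model <- as_model(model)
  env <- generate_environment(seed = derive_seed(seed, 1))
  s_beh <- derive_seed(seed, 2)
  c1 <- simulate_phase1(model, params, env, s_beh, spec)
  est <- point_estimate_phase1(c1, env, spec)
  partner <- match_partner(est, env_phase(env, 2), target_dissimilarity,
                           seed = derive_seed(seed, 3), spec = spec)
  rec <- simulate_subject(model, params, env, partner$decisions, s_beh, spec)
  stopifnot(identical(rec$phase1_choices, c1))
  list(record = rec, est = est, partner = partner)
}

#' Generate a synthetic cohort
#'
#' For each subject: draw generating parameters from the group
#' distributions, then run [simulate_matched_subject()] (fresh environment,
#' phase-1 simulation, point estimation, partner matching, full three-phase
#' simulation). Ground-truth parameters, partner profiles and achieved
#' similarities are returned alongside the behavioural records so every
#' downstream stage is testable without external data.
#'
#' @param group an `so_group_spec` (see [default_group_spec()]).
#' @param n cohort size (defaults to the group spec's `n`).
#' @param model generating model (defaults to the group's dominant model).
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @param spec grid specification used for simulation and matching.
#' @param target_dissimilarity partner-matching target.
#' @return an `so_cohort`: list with `records` (list of `so_subject`),
#'   `truth` (data frame of generating parameters, model, partner
#'   parameters, `achieved_similarity`), `group`, `seed`.
#' @export
generate_cohort <- function(group = default_group_spec("control-like"),
                            n = group$n, model = group$dominant_model,
                            seed = 1L, spec = grid_spec(),
                            target_dissimilarity = 0.5) {
  model <- as_model(model)
  records <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    params <- draw_subject_params(group, model, derive_seed(seed, 4 * i))
    sim <- simulate_matched_subject(model, params, derive_seed(seed, 4 * i + 1),
                                    spec, target_dissimilarity)
    records[[i]] <- sim$record
    truth[[i]] <- data.frame(subject = i, model = model$name, t(params),
                             est_alpha = sim$est[["alpha"]],
                             est_beta = sim$est[["beta"]],
                             partner_alpha = sim$partner$alpha,
                             partner_beta = sim$partner$beta,
                             achieved_similarity = sim$partner$achieved_similarity,
                             matched = sim$partner$matched)
  }
  truth <- do.call(rbind, lapply(truth, function(d) {
    for (nm in setdiff(c("prior_alpha_m", "prior_beta_m"), names(d))) d[[nm]] <- NA_real_
    d
  }))
  structure(list(records = records, truth = truth, group = group, seed = seed),
            class = "so_cohort")
}

#' @export
print.so_cohort <- function(x, ...) {
  cat(sprintf("synthetic %s cohort: n = %d, generating model(s) %s, mean partner similarity %.3f\n",
              x$group$label, length(x$records),
              paste(unique(x$truth$model), collapse = "/"),
              mean(x$truth$achieved_similarity)))
  invisible(x)
}

#' Concatenate cohorts (e.g. model mixtures)
#' @param ... `so_cohort` objects.
#' @export
bind_cohorts <- function(...) {
  parts <- list(...)
  records <- do.call(c, lapply(parts, `[[`, "records"))
  truth <- do.call(rbind, lapply(parts, `[[`, "truth"))
  truth$subject <- seq_len(nrow(truth))
  structure(list(records = records, truth = truth,
                 group = parts[[1]]$group, seed = parts[[1]]$seed),
            class = "so_cohort")
}
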