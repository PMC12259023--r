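#' Model lattice specification
#'
#' Four models cross self-insertion (own preference medians seed the prior
#' over the partner) with social contagion (the partner posterior shifts own
#' preferences for phase 3):
#' \itemize{
#'   \item M1: insertion + contagion (6 free parameters)
#'   \item M2: insertion only (6)
#'   \item M3: contagion only; free prior central tendencies over the
#'     partner (8)
#'   \item M4: neither; free prior central tendencies (8)
#'   \item Beta: as M1 but on the relative-reward dimension only, with the
#'     absolute-reward weight fixed at \eqn{\alpha = 1} (3)
#' }
#'
#' @param name one of `"M1"`, `"M2"`, `"M3"`, `"M4"`, `"Beta"`.
#' @return an `so_model` with fields `name`, `self_insertion`, `contagion`,
#'   `utility_dims`, `free_params`.
#' @export
model_spec <- function(name = c("M1", "M2", "M3", "M4", "Beta")) {
  name <- match.arg(name)
  common <- c("alpha_m", "beta_m", "alpha_sd", "beta_sd", "alpha_ref", "beta_ref")
  def <- switch(name,
    M1 = list(self_insertion = TRUE, contagion = TRUE, utility_dims = "both",
              free_params = common),
    M2 = list(self_insertion = TRUE, contagion = FALSE, utility_dims = "both",
              free_params = common),
    M3 = list(self_insertion = FALSE, contagion = TRUE, utility_dims = "both",
              free_params = c(common, "prior_alpha_m", "prior_beta_m")),
    M4 = list(self_insertion = FALSE, contagion = FALSE, utility_dims = "both",
              free_params = c(common, "prior_alpha_m", "prior_beta_m")),
    Beta = list(self_insertion = TRUE, contagion = TRUE,
                utility_dims = "relative-only",
                free_params = c("beta_m", "beta_sd", "beta_ref")))
  structure(c(list(name = name), def), class = "so_model")
}

as_model <- function(model) {
  if (inherits(model, "so_model")) model else model_spec(model)
}

# Grid actually used by a model: the Beta variant collapses alpha to {1}.
model_grid <- function(model, spec) {
  if (model$utility_dims == "relative-only" && length(spec$alpha) != 1L)
    grid_spec(beta_step = spec$beta[2] - spec$beta[1],
              beta_range = range(spec$beta), alpha_fixed = 1)
  else spec
}

# ---- trial-likelihood workspace -------------------------------------------
#
# All trial probabilities over the grid depend only on the two
# utility-difference coefficients (A, B) of the option pair, so per
# environment we precompute p(option 1 | state) once per unique (A, B) and
# index trials into those columns. This is what makes repeated likelihood
# evaluation inside the optimiser cheap.
make_workspace <- function(env, spec) {
  AB <- t(vapply(seq_len(nrow(env)), function(i) du_coef(env[i, ]), numeric(2)))
  key <- paste(AB[, 1], AB[, 2])
  uk <- unique(key)
  uidx <- match(key, uk)
  uAB <- AB[match(uk, key), , drop = FALSE]
  alpha_vec <- rep(spec$alpha, times = length(spec$beta))
  beta_vec <- rep(spec$beta, each = length(spec$alpha))
  P <- vapply(seq_len(nrow(uAB)), function(u)
    plogis(uAB[u, 1] * alpha_vec + uAB[u, 2] * beta_vec),
    numeric(length(alpha_vec)))
  P <- matrix(P, nrow = length(alpha_vec)) # guard single-state grids
  list(P = P, idx = uidx, phase = env$phase, env = env, spec = spec,
       na = length(spec$alpha), nb = length(spec$beta))
}

ws_for <- function(model, env, spec, ws = NULL) {
  g <- model_grid(as_model(model), spec)
  if (!is.null(ws) && same_grid(ws$spec, g)) return(ws)
  make_workspace(env, g)
}

belief_vec <- function(belief) as.vector(belief$mass)

vec_belief <- function(v, spec) new_belief(matrix(v, length(spec$alpha)), spec)

# Static-phase choice probabilities for option 1 on the given trials.
static_probs <- function(ws, rows, belief) {
  pu <- as.vector(crossprod(ws$P, belief_vec(belief)))
  pu[ws$idx[rows]]
}

bernoulli_ll <- function(p1, choice, floor = .so_floor) {
  p <- ifelse(choice == 1, p1, 1 - p1)
  sum(log(clip(p, floor, 1 - floor)))
}

#' Self preference summary
#'
#' Central tendencies and spreads of a subject's own preference distribution
#' (the phase-1 generative belief).
#' @param alpha_m,beta_m central tendencies (grid units).
#' @param alpha_sd,beta_sd positive spreads.
#' @export
self_preferences <- function(alpha_m, beta_m, alpha_sd, beta_sd) {
  if (alpha_sd <= 0 || beta_sd <= 0) stop("spreads must be positive")
  structure(list(alpha_m = alpha_m, beta_m = beta_m,
                 alpha_sd = alpha_sd, beta_sd = beta_sd),
            class = "so_self")
}

#' Phase-2 prior belief over the partner
#'
#' Under self-insertion (M1, M2, Beta) the prior is centred on the
#' subject's own central tendencies; under M3/M4 it is centred on free prior
#' central tendencies. In all models the prior spreads are the reference
#' spreads `alpha_ref`, `beta_ref`, allowing the partner to be believed
#' different from the self. The Beta variant fixes the alpha dimension at 1.
#'
#' @param model an `so_model` or model name.
#' @param params named parameter list/vector in model space (see
#'   [model_spec()] for the names).
#' @param spec grid specification.
#' @param floor noise floor.
#' @return an `so_belief` on [model_grid()].
#' @export
build_phase2_prior <- function(model, params, spec = grid_spec(), floor = .so_floor) {
  model <- as_model(model)
  params <- as.list(params)
  g <- model_grid(model, spec)
  if (model$utility_dims == "relative-only") {
    return(discretized_normal_belief(1, 1, params$beta_m, params$beta_ref, g, floor))
  }
  if (model$self_insertion) {
    m <- c(params$alpha_m, params$beta_m)
  } else {
    if (is.null(params$prior_alpha_m) || is.null(params$prior_beta_m))
      stop(model$name, " requires prior central tendencies over the partner")
    m <- c(params$prior_alpha_m, params$prior_beta_m)
  }
  discretized_normal_belief(m[1], params$alpha_ref, m[2], params$beta_ref, g, floor)
}

#' Precision-weighted contagion shift for phase 3
#'
#' Combines self preferences with the posterior belief about the partner,
#' per dimension, by precision weighting. With self precision
#' \eqn{\sigma_{ppt}^{-2}} and an effective other precision
#' \eqn{(2\,ref^2 + \sigma_{par}^2)^{-1}}, the shifted variance is
#' \eqn{\acute v = (\sigma_{ppt}^{-2} + (2 ref^2 + \sigma_{par}^2)^{-1})^{-1}}
#' and the shifted median is the precision-weighted combination
#' \eqn{\acute m = \acute v\,[\sigma_{ppt}^{-2} m_{ppt} +
#' (2 ref^2 + \sigma_{par}^2)^{-1} m_{par}]}. Certain selves therefore move
#' little; uncertain selves are drawn toward precisely-represented partners.
#'
#' @param self an [self_preferences()] (or list with the same fields).
#' @param ref list/vector with `alpha_ref`, `beta_ref` (phase-2 prior spreads).
#' @param posterior list with `alpha` and `beta` entries summarising the
#'   final partner posterior per dimension: each needs an `sd` and a centre
#'   (`mean`, preferred for smoothness, or the discrete `median` from
#'   [marginal_summary()]).
#' @return list with shifted `alpha_m`, `beta_m`, `alpha_sd`, `beta_sd`.
#' @export
contagion_update <- function(self, ref, posterior) {
  ref <- as.list(ref)
  centre <- function(x) if (!is.null(x$mean)) x$mean else x$median
  shift_dim <- function(m_self, sd_self, ref_sd, m_par, sd_par) {
    if (sd_self <= 0 || ref_sd <= 0) stop("spreads must be positive")
    prec_self <- sd_self^-2
    prec_other <- 1 / (2 * ref_sd^2 + sd_par^2)
    v <- 1 / (prec_self + prec_other)
    list(m = v * (prec_self * m_self + prec_other * m_par), sd = sqrt(v))
  }
  a <- shift_dim(self$alpha_m, self$alpha_sd, ref$alpha_ref,
                 centre(posterior$alpha), posterior$alpha$sd)
  b <- shift_dim(self$beta_m, self$beta_sd, ref$beta_ref,
                 centre(posterior$beta), posterior$beta$sd)
  list(alpha_m = a$m, beta_m = b$m, alpha_sd = a$sd, beta_sd = b$sd)
}

# Phase-1 generative belief for a parameter set under a model.
self_belief <- function(model, params, spec, floor = .so_floor) {
  model <- as_model(model)
  params <- as.list(params)
  g <- model_grid(model, spec)
  if (model$utility_dims == "relative-only")
    discretized_normal_belief(1, 1, params$beta_m, params$beta_sd, g, floor)
  else
    discretized_normal_belief(params$alpha_m, params$alpha_sd,
                              params$beta_m, params$beta_sd, g, floor)
}

# Phase-3 belief: contagion-shifted for M1/M3/Beta, the phase-1 belief
# otherwise. `posterior` is the final phase-2 partner belief.
phase3_belief <- function(model, params, posterior, spec, floor = .so_floor) {
  model <- as_model(model)
  params <- as.list(params)
  if (!model$contagion) return(self_belief(model, params, spec, floor))
  g <- model_grid(model, spec)
  post <- list(alpha = marginal_moments(posterior, "alpha"),
               beta = marginal_moments(posterior, "beta"))
  if (model$utility_dims == "relative-only") {
    sh <- contagion_update(list(alpha_m = 1, beta_m = params$beta_m,
                                alpha_sd = 1, beta_sd = params$beta_sd),
                           list(alpha_ref = 1, beta_ref = params$beta_ref), post)
    return(discretized_normal_belief(1, 1, sh$beta_m, sh$beta_sd, g, floor))
  }
  sh <- contagion_update(params, params, post)
  discretized_normal_belief(sh$alpha_m, sh$alpha_sd, sh$beta_m, sh$beta_sd, g, floor)
}

# ---- full three-phase likelihood ------------------------------------------

# Runs all three phases for one subject under a model and parameter set.
# Returns the total log-likelihood plus per-phase pieces and the objects
# downstream analyses need (partner posterior, shifted belief, predictive
# probabilities, optionally the full phase-2 belief path).
model_filter <- function(model, params, data, spec = grid_spec(), ws = NULL,
                         floor = .so_floor, keep_path = FALSE) {
  model <- as_model(model)
  env <- data$env
  ws <- ws_for(model, env, spec, ws)
  g <- ws$spec
  rows1 <- which(ws$phase == 1)
  rows2 <- which(ws$phase == 2)
  rows3 <- which(ws$phase == 3)
  if (length(data$phase1_choices) != length(rows1) ||
      length(data$phase2_partner) != length(rows2) ||
      length(data$phase2_predictions) != length(rows2) ||
      length(data$phase3_choices) != length(rows3))
    stop("subject record lengths do not match the environment")

  bel1 <- self_belief(model, params, g, floor)
  p1 <- static_probs(ws, rows1, bel1)
  ll1 <- bernoulli_ll(p1, data$phase1_choices, floor)

  prior2 <- build_phase2_prior(model, params, g, floor)
  f2 <- phase2_filter_cpp(ws$P, ws$idx[rows2], as.integer(data$phase2_partner),
                          belief_vec(prior2), floor, keep_path)
  pred_p <- clip(f2$pred_p, floor, 1 - floor)
  ll2 <- bernoulli_ll(pred_p, data$phase2_predictions, floor)
  posterior <- vec_belief(f2$posterior, g)

  bel3 <- phase3_belief(model, params, posterior, g, floor)
  p3 <- static_probs(ws, rows3, bel3)
  ll3 <- bernoulli_ll(p3, data$phase3_choices, floor)

  list(loglik = ll1 + ll2 + ll3, ll_phase = c(ll1, ll2, ll3),
       p1 = p1, pred_p = f2$pred_p, p3 = p3,
       prior2 = prior2, posterior = posterior, belief3 = bel3,
       path = if (keep_path) f2$path else NULL, ws = ws)
}

#' Subject log-likelihood under a model
#'
#' Sums, in nats: phase-1 choice log-likelihoods under the self belief;
#' phase-2 prediction log-likelihoods, where by probability matching the
#' prediction probability equals the model's current partner-choice
#' probability (the belief is then updated on the partner's actual decision,
#' feedback being veridical); and phase-3 choice log-likelihoods under the
#' contagion-shifted belief (M1, M3, Beta) or the phase-1 belief (M2, M4).
#' All per-trial probabilities are clipped away from 0 and 1 by the noise
#' floor.
#'
#' @param model model name or `so_model`.
#' @param params named parameter vector/list in model space.
#' @param data an `so_subject` record (see [simulate_subject()]).
#' @param spec grid specification.
#' @param floor noise floor.
#' @return total log-likelihood (numeric scalar, \eqn{\le 0}).
#' @export
subject_loglik <- function(model, params, data, spec = grid_spec(),
                           floor = .so_floor) {
  model_filter(model, params, data, spec, floor = floor)$loglik
}

new_subject <- function(env, c1, pred2, d2, c3, seed = NA_integer_) {
  structure(list(env = env,
                 phase1_choices = as.integer(c1),
                 phase2_predictions = as.integer(pred2),
                 phase2_partner = as.integer(d2),
                 phase2_feedback = as.integer(pred2) == as.integer(d2),
                 phase3_choices = as.integer(c3),
                 seed = seed),
            class = "so_subject")
}

#' @export
print.so_subject <- function(x, ...) {
  cat(sprintf("subject record: %d + %d + %d trials, phase-2 accuracy %.2f\n",
              length(x$phase1_choices), length(x$phase2_predictions),
              length(x$phase3_choices), mean(x$phase2_feedback)))
  invisible(x)
}

#' Simulate one subject's three-phase behaviour
#'
#' Phase-1 and phase-3 choices are Bernoulli draws from the
#' random-preference choice probabilities; phase-2 predictions are drawn
#' from the probability-matched partner-choice probability, after which the
#' belief is updated on the partner's actual decision.
#'
#' @param model model name or `so_model`.
#' @param params named parameter vector/list in model space.
#' @param env an `so_env`.
#' @param partner_decisions integer vector (1/2) of the partner's phase-2
#'   decisions, one per phase-2 trial.
#' @param seed integer seed; identical seeds reproduce the record.
#' @param spec grid specification used for simulation.
#' @return an `so_subject`.
#' @export
simulate_subject <- function(model, params, env, partner_decisions, seed,
                             spec = grid_spec()) {
  model <- as_model(model)
  ws <- ws_for(model, env, spec)
  g <- ws$spec
  n1 <- sum(ws$phase == 1); n2 <- sum(ws$phase == 2); n3 <- sum(ws$phase == 3)
  if (length(partner_decisions) != n2)
    stop("expected ", n2, " partner decisions, got ", length(partner_decisions))
  u <- with_seed(seed, runif(n1 + n2 + n3))
  u1 <- u[seq_len(n1)]; u2 <- u[n1 + seq_len(n2)]; u3 <- u[n1 + n2 + seq_len(n3)]

  bel1 <- self_belief(model, params, g)
  p1 <- static_probs(ws, which(ws$phase == 1), bel1)
  c1 <- ifelse(u1 < p1, 1L, 2L)

  prior2 <- build_phase2_prior(model, params, g)
  f2 <- phase2_filter_cpp(ws$P, ws$idx[ws$phase == 2], as.integer(partner_decisions),
                          belief_vec(prior2), .so_floor, FALSE)
  pred2 <- ifelse(u2 < f2$pred_p, 1L, 2L)
  posterior <- vec_belief(f2$posterior, g)

  bel3 <- phase3_belief(model, params, posterior, g)
  p3 <- static_probs(ws, which(ws$phase == 3), bel3)
  c3 <- ifelse(u3 < p3, 1L, 2L)

  new_subject(env, c1, pred2, partner_decisions, c3, seed = seed)
}

# Phase-1 choices only, drawn from the same random stream as
# simulate_subject() so that a later full simulation reproduces them.
simulate_phase1 <- function(model, params, env, seed, spec = grid_spec()) {
  model <- as_model(model)
  ws <- ws_for(model, env, spec)
  n1 <- sum(ws$phase == 1)
  u1 <- with_seed(seed, runif(n1))
  bel1 <- self_belief(model, params, ws$spec)
  p1 <- static_probs(ws, which(ws$phase == 1), bel1)
  ifelse(u1 < p1, 1L, 2L)
}
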