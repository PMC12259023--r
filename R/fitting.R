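#' Fitting configuration
#'
#' Latent parameters are fitted unbounded with independent Gaussian priors
#' (mean 0, variance 6.5 by default, matching the broad priors used for
#' hierarchical estimation). Central tendencies map onto the grid ranges
#' through scaled logistics and spread-type parameters through exp, so the
#' broad latent prior is spread over the whole preference grid instead of
#' penalising parameter magnitude.
#'
#' @param prior_mean,prior_var initial latent prior mean and variance.
#' @param floor noise floor for distributions and probabilities.
#' @param max_iter maximum hierarchical iterations.
#' @param tol convergence tolerance on model frequencies.
#' @param maxit_cold,maxit_warm optimiser iteration caps for first and
#'   warm-started fits.
#' @param spec grid specification used during fitting.
#' @param seed integer seed.
#' @export
fit_config <- function(prior_mean = 0, prior_var = 6.5, floor = .so_floor,
                       max_iter = 5L, tol = 0.01,
                       maxit_cold = 80L, maxit_warm = 30L,
                       spec = grid_spec(), seed = 1L) {
  stopifnot(prior_var > 0, tol > 0)
  structure(list(prior_mean = prior_mean, prior_var = prior_var, floor = floor,
                 max_iter = max_iter, tol = tol,
                 maxit_cold = maxit_cold, maxit_warm = maxit_warm,
                 spec = spec, seed = seed),
            class = "so_fit_config")
}

is_spread_param <- function(names) grepl("_sd$|_ref$", names)
is_alpha_centre <- function(names) names %in% c("alpha_m", "prior_alpha_m")
is_beta_centre <- function(names) names %in% c("beta_m", "prior_beta_m")

# Latent parameters are unbounded; central tendencies map onto the grid
# ranges through scaled logistics (so the N(0, 6.5) latent prior spreads
# broadly over the grid rather than pulling magnitudes to zero), spreads
# through exp so they stay positive.
latent_to_model <- function(model, latent) {
  nm <- as_model(model)$free_params
  out <- latent
  out[is_spread_param(nm)] <- exp(latent[is_spread_param(nm)])
  out[is_alpha_centre(nm)] <- 30 * plogis(latent[is_alpha_centre(nm)])
  out[is_beta_centre(nm)] <- 60 * plogis(latent[is_beta_centre(nm)]) - 30
  setNames(out, nm)
}

model_to_latent <- function(model, params) {
  nm <- as_model(model)$free_params
  p <- unlist(params)[nm]
  eps <- 1e-4
  p[is_spread_param(nm)] <- log(pmax(p[is_spread_param(nm)], 1e-8))
  p[is_alpha_centre(nm)] <-
    qlogis(clip(p[is_alpha_centre(nm)] / 30, eps, 1 - eps))
  p[is_beta_centre(nm)] <-
    qlogis(clip((p[is_beta_centre(nm)] + 30) / 60, eps, 1 - eps))
  setNames(p, nm)
}

neg_log_posterior <- function(latent, model, data, ws, prior_mean, prior_var,
                              floor) {
  params <- latent_to_model(model, latent)
  ll <- tryCatch(
    model_filter(model, params, data, ws$spec, ws = ws, floor = floor)$loglik,
    error = function(e) -Inf)
  lp <- sum(dnorm(latent, prior_mean, sqrt(prior_var), log = TRUE))
  if (!is.finite(ll)) return(1e10)
  -(ll + lp)
}

# Heuristic starting point: grid point estimates of the phase-1 medians
# (and, for free-prior models, of the partner medians from phase-2
# decisions), moderate spreads.
heuristic_start <- function(model, data, ws) {
  model <- as_model(model)
  spec <- ws$spec
  est <- tryCatch({
    rows <- which(ws$phase == 1)
    f <- phase2_filter_cpp(ws$P, ws$idx[rows], as.integer(data$phase1_choices),
                           rep(1 / nrow(ws$P), nrow(ws$P)), .so_floor, FALSE)
    s <- which.max(f$posterior)
    c(spec$alpha[(s - 1) %% ws$na + 1], spec$beta[(s - 1) %/% ws$na + 1])
  }, error = function(e) c(10, 0))
  start <- c(alpha_m = est[1], beta_m = est[2],
             alpha_sd = 5, beta_sd = 5, alpha_ref = 5, beta_ref = 5)
  if (!model$self_insertion) {
    par_est <- tryCatch({
      rows <- which(ws$phase == 2)
      f <- phase2_filter_cpp(ws$P, ws$idx[rows], as.integer(data$phase2_partner),
                             rep(1 / nrow(ws$P), nrow(ws$P)), .so_floor, FALSE)
      s <- which.max(f$posterior)
      c(spec$alpha[(s - 1) %% ws$na + 1], spec$beta[(s - 1) %/% ws$na + 1])
    }, error = function(e) c(10, 0))
    start <- c(start, prior_alpha_m = par_est[1], prior_beta_m = par_est[2])
  }
  model_to_latent(model, start)
}

#' MAP fit of one subject under one model
#'
#' Maximises the subject log-likelihood plus independent Gaussian log-priors
#' over the latent parameters (quasi-Newton, multiple starts), and computes
#' the Laplace approximation to the log marginal likelihood:
#' log posterior at the mode + (k/2) log 2*pi - (1/2) log det H, with H the
#' Hessian of the negative log posterior. Non-positive-definite Hessians are
#' regularised with diagonal jitter and flagged.
#'
#' @param model model name or `so_model`.
#' @param data an `so_subject`.
#' @param config a [fit_config()]; `prior_mean`/`prior_var` may be scalars
#'   or per-parameter vectors (as updated by the hierarchical loop).
#' @param init optional latent start (warm start); otherwise heuristic and
#'   prior-mean starts are tried.
#' @param hessian compute the Laplace evidence (default TRUE).
#' @param ws optional precomputed workspace for this subject's environment.
#' @return an `so_subject_fit` with latent and model-space estimates,
#'   log-likelihood, log posterior, `evidence`, and flags.
#' @export
map_fit <- function(model, data, config = fit_config(), init = NULL,
                    hessian = TRUE, ws = NULL) {
  model <- as_model(model)
  ws <- ws_for(model, data$env, config$spec, ws)
  k <- length(model$free_params)
  pm <- rep(config$prior_mean, length.out = k)
  pv <- rep(config$prior_var, length.out = k)
  fn <- function(latent) neg_log_posterior(latent, model, data, ws, pm, pv,
                                           config$floor)
  starts <- if (is.null(init)) {
    # heuristic start, kept away from the flat logistic tails where the
    # latent gradient vanishes; the prior mean is the fallback
    list(clip(heuristic_start(model, data, ws), -2.5, 2.5), pm)
  } else {
    list(init)
  }
  maxit <- if (is.null(init)) config$maxit_cold else config$maxit_warm
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      optim(s0, fn, method = "BFGS",
            control = list(maxit = maxit, reltol = 1e-7)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0) break # first converged start wins
  }
  if (is.null(best)) stop("non-finite likelihood at all starts for ", model$name)
  latent <- setNames(best$par, model$free_params)
  params <- latent_to_model(model, latent)
  ll <- model_filter(model, params, data, ws$spec, ws = ws,
                     floor = config$floor)$loglik
  logpost <- -best$value
  evidence <- NA_real_
  hess_ok <- NA
  post_var <- pv # prior variance as fallback for a failed Hessian
  if (hessian) {
    H <- tryCatch(optimHess(best$par, fn), error = function(e) NULL)
    hess_ok <- FALSE
    if (!is.null(H)) {
      H <- (H + t(H)) / 2
      ch <- tryCatch(chol(H), error = function(e) NULL)
      if (is.null(ch)) {
        H <- H + diag(abs(diag(H)) * 1e-6 + 1e-6, k)
        ch <- tryCatch(chol(H), error = function(e) NULL)
      } else {
        hess_ok <- TRUE
      }
      if (!is.null(ch)) {
        evidence <- logpost + 0.5 * k * log(2 * pi) - sum(log(diag(ch)))
        post_var <- diag(chol2inv(ch))
      }
    }
    if (!is.finite(evidence)) evidence <- logpost - 0.5 * k * log(2 * pi * 100)
  }
  structure(list(model = model$name, latent = latent, params = params,
                 loglik = ll, logpost = logpost, evidence = evidence,
                 post_var = setNames(pmin(post_var, pv), model$free_params),
                 converged = best$convergence == 0, hessian_ok = hess_ok),
            class = "so_subject_fit")
}

#' @export
print.so_subject_fit <- function(x, ...) {
  cat(sprintf("%s fit: loglik %.2f, evidence %.2f%s\n", x$model, x$loglik,
              x$evidence, if (x$converged) "" else " [not converged]"))
  print(round(x$params, 3))
  invisible(x)
}

#' Empirical-Bayes fit of a cohort under a single model
#'
#' Fits every subject by MAP under a shared latent prior, re-estimates the
#' group prior (mean and variance of the latent estimates, variance floored
#' at 0.01), and refits warm-started for `passes - 1` further rounds. This
#' is the single-model analogue of [hierarchical_compare()] and is used for
#' parameter recovery.
#'
#' @param model model name or `so_model`.
#' @param cohort list of `so_subject` records.
#' @param config a [fit_config()].
#' @param passes number of fitting passes (>= 1).
#' @return list with `fits` (per subject), `params` (data frame of
#'   model-space estimates), `prior_mean`, `prior_var` (latent).
#' @export
fit_cohort <- function(model, cohort, config = fit_config(), passes = 2L) {
  model <- as_model(model)
  k <- length(model$free_params)
  pm <- rep(config$prior_mean, length.out = k)
  pv <- rep(config$prior_var, length.out = k)
  fits <- vector("list", length(cohort))
  for (pass in seq_len(passes)) {
    cfg <- config; cfg$prior_mean <- pm; cfg$prior_var <- pv
    for (i in seq_along(cohort)) {
      init <- if (pass > 1) fits[[i]]$latent else NULL
      fits[[i]] <- map_fit(model, cohort[[i]], cfg, init = init)
    }
    th <- do.call(rbind, lapply(fits, `[[`, "latent"))
    wv <- do.call(rbind, lapply(fits, `[[`, "post_var"))
    pm <- colMeans(th)
    # group variance = dispersion of the modes plus mean within-subject
    # posterior variance, so weakly identified parameters keep a broad prior
    pv <- pmax(apply(th, 2, var) + colMeans(wv), 0.01)
  }
  params <- as.data.frame(do.call(rbind, lapply(fits, `[[`, "params")))
  list(fits = fits, params = params, prior_mean = pm, prior_var = pv)
}

# Expected log Dirichlet frequencies.
e_log_dir <- function(alpha) digamma(alpha) - digamma(sum(alpha))

# Exceedance probabilities of a Dirichlet by Monte Carlo.
dirichlet_exceedance <- function(alpha, nsamp = 1e5, seed = 1L) {
  with_seed(seed, {
    m <- length(alpha)
    g <- matrix(rgamma(nsamp * m, shape = rep(alpha, each = nsamp)), nsamp, m)
    tabulate(max.col(g), m) / nsamp
  })
}

# Variational free energy of the random-effects (Dirichlet-multinomial)
# model given log evidences L (subjects x models), used for the Bayes
# omnibus risk.
bms_free_energy <- function(L, r, alpha, alpha0) {
  elog <- e_log_dir(alpha)
  f <- sum(r * L) + sum(r %*% elog) - sum(r[r > 0] * log(r[r > 0]))
  f <- f + lgamma(sum(alpha0)) - sum(lgamma(alpha0)) -
    (lgamma(sum(alpha)) - sum(lgamma(alpha))) +
    sum((alpha0 - alpha) * elog)
  f
}

#' Hierarchical random-effects model comparison
#'
#' Iterates: (1) per subject x model MAP fits with Laplace evidence under
#' the current group priors; (2) model responsibilities proportional to the
#' exponentiated evidence plus the expected log model frequency; (3) a
#' Dirichlet update of model frequencies from the responsibility counts;
#' (4) responsibility-weighted updates of each model's group latent prior
#' mean and variance (variance floored at 0.01). After convergence of the
#' frequencies, exceedance probabilities are drawn from the Dirichlet
#' counts and protected against the null of uniform frequencies via the
#' Bayes omnibus risk: pxp = xp * (1 - BOR) + BOR / M.
#'
#' @param models character vector or list of models (>= 1).
#' @param cohort list of `so_subject` records (>= 2).
#' @param config a [fit_config()].
#' @param verbose print per-iteration frequencies.
#' @return an `so_comparison`: responsibilities, `frequency`, `alpha`,
#'   `xp`, `bor`, `pxp`, per-model subject parameter tables, evidence
#'   matrix, group priors, convergence info.
#' @export
hierarchical_compare <- function(models = c("M1", "M2", "M3", "M4"), cohort,
                                 config = fit_config(), verbose = FALSE) {
  models <- lapply(models, as_model)
  mnames <- vapply(models, `[[`, "", "name")
  M <- length(models)
  n <- length(cohort)
  if (n < 2) stop("hierarchical comparison needs at least 2 subjects")
  pm <- lapply(models, function(m) rep(config$prior_mean,
                                       length.out = length(m$free_params)))
  pv <- lapply(models, function(m) rep(config$prior_var,
                                       length.out = length(m$free_params)))
  alpha0 <- rep(1, M)
  alpha <- alpha0
  latents <- matrix(list(), n, M)
  postvars <- matrix(list(), n, M)
  L <- matrix(NA_real_, n, M, dimnames = list(NULL, mnames))
  freq <- rep(1 / M, M)
  converged <- FALSE
  iter <- 0L
  freq_trace <- NULL
  while (iter < config$max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      ws <- NULL
      for (m in seq_len(M)) {
        cfg <- config
        cfg$prior_mean <- pm[[m]]; cfg$prior_var <- pv[[m]]
        ws_m <- ws_for(models[[m]], cohort[[i]]$env, config$spec, ws)
        if (models[[m]]$utility_dims == "both") ws <- ws_m
        fit <- map_fit(models[[m]], cohort[[i]], cfg,
                       init = if (iter > 1) latents[[i, m]] else NULL,
                       ws = ws_m)
        latents[[i, m]] <- fit$latent
        postvars[[i, m]] <- fit$post_var
        L[i, m] <- fit$evidence
      }
    }
    # responsibilities
    elog <- e_log_dir(alpha)
    lw <- sweep(L, 2, elog, "+")
    lw <- lw - apply(lw, 1, max)
    r <- exp(lw); r <- r / rowSums(r)
    alpha <- alpha0 + colSums(r)
    new_freq <- alpha / sum(alpha)
    # group prior updates (responsibility-weighted; variance includes the
    # mean within-subject posterior variance to avoid hierarchical collapse)
    for (m in seq_len(M)) {
      th <- do.call(rbind, latents[, m])
      wv <- do.call(rbind, postvars[, m])
      w <- r[, m]
      if (sum(w) > 1e-3) {
        mu <- colSums(th * w) / sum(w)
        v <- colSums(sweep(th, 2, mu)^2 * w) / sum(w)
        pm[[m]] <- mu
        pv[[m]] <- pmax(v + colSums(wv * w) / sum(w), 0.01)
      }
    }
    if (verbose)
      message("iter ", iter, ": ", paste(sprintf("%s=%.3f", mnames, new_freq),
                                         collapse = " "))
    freq_trace <- rbind(freq_trace, new_freq)
    if (max(abs(new_freq - freq)) < config$tol) {
      freq <- new_freq
      converged <- TRUE
      break
    }
    freq <- new_freq
  }
  xp <- dirichlet_exceedance(alpha, seed = derive_seed(config$seed, 17))
  f1 <- bms_free_energy(L, r, alpha, alpha0)
  f0 <- sum(apply(L, 1, function(x) max(x) + log(mean(exp(x - max(x))))))
  bor <- 1 / (1 + exp(f1 - f0))
  pxp <- xp * (1 - bor) + bor / M
  subject_params <- lapply(seq_len(M), function(m)
    as.data.frame(do.call(rbind, lapply(seq_len(n), function(i)
      latent_to_model(models[[m]], latents[[i, m]])))))
  names(subject_params) <- mnames
  structure(list(models = mnames, responsibility = r,
                 frequency = setNames(freq, mnames),
                 alpha = setNames(alpha, mnames),
                 xp = setNames(xp, mnames), bor = bor,
                 pxp = setNames(pxp, mnames),
                 evidence = L, subject_params = subject_params,
                 prior_mean = setNames(pm, mnames),
                 prior_var = setNames(pv, mnames),
                 iterations = iter, converged = converged,
                 freq_trace = freq_trace),
            class = "so_comparison")
}

#' @export
print.so_comparison <- function(x, ...) {
  cat("hierarchical model comparison over", paste(x$models, collapse = ", "),
      sprintf("(%d subjects, %d iteration%s%s)\n", nrow(x$responsibility),
              x$iterations, if (x$iterations > 1) "s" else "",
              if (x$converged) "" else ", not converged"))
  tab <- rbind(frequency = x$frequency, xp = x$xp, pxp = x$pxp)
  print(round(tab, 3))
  cat(sprintf("Bayes omnibus risk: %.3g\n", x$bor))
  invisible(x)
}

#' Bootstrap mean-difference interval between two groups
#'
#' Percentile bootstrap of the difference in means (group 1 minus group 2);
#' descriptive plumbing for group contrasts on fitted parameters.
#'
#' @param x,y numeric vectors.
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @param seed integer seed.
#' @export
bootstrap_group_diff <- function(x, y, n_boot = 2000, conf = 0.95, seed = 1L) {
  d <- with_seed(seed, replicate(n_boot, mean(sample(x, replace = TRUE)) -
                                   mean(sample(y, replace = TRUE))))
  q <- quantile(d, c((1 - conf) / 2, 1 - (1 - conf) / 2))
  list(diff = mean(x) - mean(y), lower = q[[1]], upper = q[[2]])
}
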