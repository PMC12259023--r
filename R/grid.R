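#' Discretised preference grid
#'
#' The two social value orientation dimensions are discretised on a fixed
#' rectangular grid: \eqn{\alpha} (absolute-reward weight) from 0 to 30 and
#' \eqn{\beta} (relative-reward weight, prosocial negative / competitive
#' positive) from -30 to 30. The default steps (0.125 and 0.25) give 241
#' points per dimension. Coarser steps can be requested for faster fitting;
#' a single fixed alpha value (used by the one-dimensional relative-reward
#' model) is requested with `alpha_fixed`.
#'
#' @param alpha_step,beta_step grid increments.
#' @param alpha_range,beta_range inclusive bounds per dimension.
#' @param alpha_fixed if non-NULL, collapse the alpha dimension to this
#'   single value.
#' @return an object of class `so_grid` with `alpha` and `beta` value vectors.
#' @export
grid_spec <- function(alpha_step = 0.125, beta_step = 0.25,
                      alpha_range = c(0, 30), beta_range = c(-30, 30),
                      alpha_fixed = NULL) {
  stopifnot(alpha_step > 0, beta_step > 0)
  alpha <- if (is.null(alpha_fixed)) {
    seq(alpha_range[1], alpha_range[2], by = alpha_step)
  } else {
    as.numeric(alpha_fixed)
  }
  beta <- seq(beta_range[1], beta_range[2], by = beta_step)
  structure(list(alpha = alpha, beta = beta), class = "so_grid")
}

#' @export
print.so_grid <- function(x, ...) {
  cat(sprintf("preference grid: %d alpha points [%g, %g] x %d beta points [%g, %g]\n",
              length(x$alpha), min(x$alpha), max(x$alpha),
              length(x$beta), min(x$beta), max(x$beta)))
  invisible(x)
}

same_grid <- function(a, b) {
  length(a$alpha) == length(b$alpha) && length(a$beta) == length(b$beta) &&
    all(a$alpha == b$alpha) && all(a$beta == b$beta)
}

new_belief <- function(mass, spec) {
  structure(list(mass = mass, spec = spec), class = "so_belief")
}

#' @export
print.so_belief <- function(x, ...) {
  s <- marginal_summary(x, "alpha")
  b <- marginal_summary(x, "beta")
  cat(sprintf("belief over %dx%d grid: alpha median %.3g (sd %.3g), beta median %.3g (sd %.3g)\n",
              length(x$spec$alpha), length(x$spec$beta),
              s$median, s$sd, b$median, b$sd))
  invisible(x)
}

check_belief <- function(belief) {
  stopifnot(inherits(belief, "so_belief"))
  if (abs(sum(belief$mass) - 1) > 1e-8)
    stop("belief is not normalised (mass sums to ", sum(belief$mass), ")")
  invisible(belief)
}

# Normalise, add the noise floor, renormalise; matrix in, matrix out.
# Normalising first keeps the floor on the probability scale, so no entry
# of the result sits (meaningfully) below the floor.
floor_normalise <- function(mass, floor = .so_floor) {
  mass <- mass / sum(mass) + floor
  mass / sum(mass)
}

#' Discretised product-normal belief
#'
#' Builds a belief over the grid as the product of independent normal
#' densities in alpha and beta evaluated at the grid points, floored and
#' normalised. Central tendencies are clipped to the grid bounds first.
#'
#' @param m_alpha,sd_alpha,m_beta,sd_beta per-dimension central tendency and
#'   spread (grid units); spreads must be positive.
#' @param spec a [grid_spec()].
#' @param floor noise floor added before normalisation.
#' @return an `so_belief`.
#' @export
discretized_normal_belief <- function(m_alpha, sd_alpha, m_beta, sd_beta,
                                      spec = grid_spec(), floor = .so_floor) {
  if (sd_alpha <= 0 || sd_beta <= 0) stop("spreads must be positive")
  m_alpha <- clip(m_alpha, min(spec$alpha), max(spec$alpha))
  m_beta <- clip(m_beta, min(spec$beta), max(spec$beta))
  fa <- dnorm(spec$alpha, m_alpha, sd_alpha)
  fb <- dnorm(spec$beta, m_beta, sd_beta)
  if (length(spec$alpha) == 1L) fa <- 1 # degenerate alpha dimension
  mass <- outer(fa, fb)
  s <- sum(mass)
  if (s == 0) { # spread far below grid resolution: point mass at nearest node
    ia <- which.min(abs(spec$alpha - m_alpha))
    ib <- which.min(abs(spec$beta - m_beta))
    mass[ia, ib] <- 1
  }
  new_belief(floor_normalise(mass, floor), spec)
}

#' Uniform belief over the grid
#' @param spec a [grid_spec()].
#' @export
uniform_belief <- function(spec = grid_spec()) {
  n <- length(spec$alpha) * length(spec$beta)
  new_belief(matrix(1 / n, length(spec$alpha), length(spec$beta)), spec)
}

#' Constricted Fehr-Schmidt option utility
#'
#' \deqn{U = \alpha r_{ppt} + \beta \max(r_{ppt} - r_{par}, 0)}
#' The advantageous-inequality term only is retained: agents weight their own
#' payoff and the positive part of the payoff gap in their favour.
#'
#' @param r_ppt,r_par points for self and other.
#' @param alpha,beta preference weights.
#' @export
option_utility <- function(r_ppt, r_par, alpha, beta) {
  alpha * r_ppt + beta * pmax(r_ppt - r_par, 0)
}

# Utility-difference coefficients for a pair: dU(alpha, beta) = A*alpha + B*beta.
du_coef <- function(pair) {
  c(A = pair$r_ppt_1 - pair$r_ppt_2,
    B = max(pair$r_ppt_1 - pair$r_par_1, 0) - max(pair$r_ppt_2 - pair$r_par_2, 0))
}

du_grid <- function(pair, spec) {
  k <- du_coef(pair)
  outer(k[["A"]] * spec$alpha, k[["B"]] * spec$beta, "+")
}

#' Random-preference choice probability
#'
#' Probability that option 1 is chosen, marginalised over the belief:
#' the unit-slope logistic of the utility difference at each grid state,
#' weighted by the state's probability mass.
#'
#' @param pair an option pair (list or one-row data frame with fields
#'   `r_ppt_1`, `r_par_1`, `r_ppt_2`, `r_par_2`).
#' @param belief an `so_belief` (normalised).
#' @return probability in `[0, 1]`.
#' @export
choice_probability <- function(pair, belief) {
  check_belief(belief)
  sum(plogis(du_grid(pair, belief$spec)) * belief$mass)
}

#' Bayesian belief update on one observed decision
#'
#' Multiplies the prior by the per-state likelihood of the observed decision
#' (option 1 or 2), adds the noise floor, and renormalises.
#'
#' @param belief prior `so_belief` (normalised).
#' @param pair the option pair shown on the trial.
#' @param observed decision, 1 or 2.
#' @param floor noise floor.
#' @export
bayes_update <- function(belief, pair, observed, floor = .so_floor) {
  check_belief(belief)
  if (!observed %in% c(1, 2)) stop("observed decision must be 1 or 2")
  p1 <- plogis(du_grid(pair, belief$spec))
  lik <- if (observed == 1) p1 else 1 - p1
  new_belief(floor_normalise(belief$mass * lik, floor), belief$spec)
}

#' Marginal median and standard deviation of a belief dimension
#'
#' The median of the discrete marginal is the first grid value whose
#' cumulative mass reaches 0.5; the sd is that of the marginal mass function.
#'
#' @param belief an `so_belief`.
#' @param dimension `"alpha"` or `"beta"`.
#' @return list with `median` and `sd` (grid units).
#' @export
marginal_summary <- function(belief, dimension = c("alpha", "beta")) {
  dimension <- match.arg(dimension)
  check_belief(belief)
  if (dimension == "alpha") {
    p <- rowSums(belief$mass); g <- belief$spec$alpha
  } else {
    p <- colSums(belief$mass); g <- belief$spec$beta
  }
  p <- p / sum(p)
  med <- g[which(cumsum(p) >= 0.5)[1]]
  mu <- sum(p * g)
  list(median = med, sd = sqrt(max(sum(p * g^2) - mu^2, 0)))
}

#' Kullback-Leibler divergence between consecutive beliefs
#'
#' \deqn{D_{KL}(P^t \| P^{t-1}) = \sum_s P^t(s) \log P^t(s)/P^{t-1}(s)}
#' in nats, over the joint grid or a single-dimension marginal. Used as the
#' per-trial informational-surprise statistic for belief updating.
#'
#' @param current,previous `so_belief` objects on the same grid.
#' @param scope `"joint"`, `"alpha"` or `"beta"` (marginal).
#' @export
kl_step <- function(current, previous, scope = c("joint", "alpha", "beta")) {
  scope <- match.arg(scope)
  check_belief(current); check_belief(previous)
  if (!same_grid(current$spec, previous$spec)) stop("beliefs are on different grids")
  if (scope == "joint") {
    p <- current$mass; q <- previous$mass
  } else if (scope == "alpha") {
    p <- rowSums(current$mass); q <- rowSums(previous$mass)
  } else {
    p <- colSums(current$mass); q <- colSums(previous$mass)
  }
  kl_discrete(p, q)
}

# Smooth marginal moments (mean and sd). The reporting convention for
# central tendency is the discrete median (marginal_summary), but the
# contagion combination inside the likelihood uses the mean: the median of
# a discrete marginal is a step function of the parameters and would make
# the log-likelihood discontinuous, breaking quasi-Newton fitting and the
# Laplace evidence. For the near-symmetric posteriors involved the two
# differ by at most about one grid step.
marginal_moments <- function(belief, dimension) {
  if (dimension == "alpha") {
    p <- rowSums(belief$mass); g <- belief$spec$alpha
  } else {
    p <- colSums(belief$mass); g <- belief$spec$beta
  }
  p <- p / sum(p)
  mu <- sum(p * g)
  list(mean = mu, sd = sqrt(max(sum(p * g^2) - mu^2, 0)))
}

kl_discrete <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  keep <- p > 0
  # non-negative by Gibbs' inequality; clamp float round-off at identity
  max(sum(p[keep] * log(p[keep] / q[keep])), 0)
}

#' Export a belief as a dense CSV matrix (diagnostics)
#'
#' Rows are alpha grid values, columns beta grid values.
#' @param belief an `so_belief`.
#' @param path output file.
#' @export
write_belief_csv <- function(belief, path) {
  m <- belief$mass
  rownames(m) <- belief$spec$alpha
  colnames(m) <- belief$spec$beta
  write.csv(m, path)
  invisible(path)
}
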