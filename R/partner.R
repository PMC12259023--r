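#' Grid point estimate of phase-1 preferences
#'
#' Flat prior over the grid updated on every phase-1 choice; returns the
#' grid point of maximal posterior mass (ties broken to the first maximal
#' point in column-major grid order).
#'
#' @param choices integer vector (1/2), one per phase-1 trial.
#' @param env an `so_env`.
#' @param spec grid specification.
#' @return named vector `c(alpha, beta)`.
#' @export
point_estimate_phase1 <- function(choices, env, spec = grid_spec()) {
  ws <- make_workspace(env, spec)
  rows <- which(ws$phase == 1)
  if (length(choices) != length(rows) || anyNA(choices))
    stop("expected ", length(rows), " complete phase-1 choices")
  f <- phase2_filter_cpp(ws$P, ws$idx[rows], as.integer(choices),
                         belief_vec(uniform_belief(spec)), .so_floor, FALSE)
  s <- which.max(f$posterior)
  na <- length(spec$alpha)
  c(alpha = spec$alpha[(s - 1) %% na + 1], beta = spec$beta[(s - 1) %/% na + 1])
}

#' Deterministic choices of a fixed preference point
#'
#' Option with the larger Fehr-Schmidt utility per trial; ties go to
#' option 1.
#'
#' @param alpha,beta preference weights.
#' @param trials data frame of option pairs (e.g. one phase of an `so_env`).
#' @return integer vector of 1/2.
#' @export
deterministic_choices <- function(alpha, beta, trials) {
  du <- vapply(seq_len(nrow(trials)), function(i) {
    k <- du_coef(trials[i, ])
    alpha * k[["A"]] + beta * k[["B"]]
  }, numeric(1))
  ifelse(du >= 0, 1L, 2L)
}

#' Match a phase-2 partner at a target choice dissimilarity
#'
#' Reimplementation of the server-side matching rule: candidate preference
#' points on a coarse sub-grid (every 8th grid node per dimension) are
#' scanned in seeded random order; each candidate's deterministic phase-2
#' choices are compared with the participant's (from their phase-1 point
#' estimate), and among candidates whose choices differ on at least
#' `target_dissimilarity` of trials the one closest to the target from
#' above is selected. If no candidate reaches the target, the most
#' dissimilar candidate is returned with `matched = FALSE`.
#'
#' @param participant_estimate named vector `c(alpha, beta)` from
#'   [point_estimate_phase1()].
#' @param env2_trials data frame of phase-2 option pairs.
#' @param target_dissimilarity target fraction of differing choices,
#'   in (0, 1).
#' @param seed integer seed for the scan order.
#' @param spec grid specification defining the candidate sub-grid.
#' @return an `so_partner`: list with `alpha`, `beta`,
#'   `achieved_similarity`, `decisions` (the partner's deterministic
#'   phase-2 choices) and `matched`.
#' @export
match_partner <- function(participant_estimate, env2_trials,
                          target_dissimilarity = 0.5, seed = 1L,
                          spec = grid_spec()) {
  if (target_dissimilarity <= 0 || target_dissimilarity >= 1)
    stop("target_dissimilarity must be in (0, 1)")
  ppt <- deterministic_choices(participant_estimate[["alpha"]],
                               participant_estimate[["beta"]], env2_trials)
  cand <- expand.grid(alpha = spec$alpha[seq(1, length(spec$alpha), by = 8)],
                      beta = spec$beta[seq(1, length(spec$beta), by = 8)])
  ord <- with_seed(seed, sample.int(nrow(cand)))
  cand <- cand[ord, , drop = FALSE]
  # choices of every candidate at once: sign of alpha*A + beta*B per trial
  AB <- t(vapply(seq_len(nrow(env2_trials)),
                 function(i) du_coef(env2_trials[i, ]), numeric(2)))
  du <- outer(cand$alpha, AB[, 1]) + outer(cand$beta, AB[, 2])
  choices <- ifelse(du >= 0, 1L, 2L)
  dissim <- rowMeans(choices != matrix(ppt, nrow(cand), length(ppt), byrow = TRUE))
  ok <- which(dissim >= target_dissimilarity)
  if (length(ok)) {
    pick <- ok[which.min(dissim[ok])]
    matched <- TRUE
  } else {
    pick <- which.max(dissim)
    matched <- FALSE
    warning("no candidate reached the target dissimilarity; returning the most dissimilar")
  }
  structure(list(alpha = cand$alpha[pick], beta = cand$beta[pick],
                 achieved_similarity = 1 - dissim[pick],
                 decisions = as.integer(choices[pick, ]),
                 matched = matched),
            class = "so_partner")
}

#' @export
print.so_partner <- function(x, ...) {
  cat(sprintf("matched partner (alpha = %g, beta = %g), achieved similarity %.3f%s\n",
              x$alpha, x$beta, x$achieved_similarity,
              if (x$matched) "" else " [target not reached]"))
  invisible(x)
}
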