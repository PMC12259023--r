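#' Option-pair template library
#'
#' Small library of two-option point splits, four per pair type, built from
#' the canonical exemplars of each contrast (equal split vs higher self;
#' equal split vs advantageous gap; two unequal splits differing in gap)
#' and integer-scaled variants with values in 1-15.
#'
#' @return data frame with columns `r_ppt_1`, `r_par_1`, `r_ppt_2`,
#'   `r_par_2`, `pair_type`.
#' @export
default_pair_templates <- function() {
  tpl <- rbind(
    # prosocial vs individualistic: shared other payoff, one equal split
    c(5, 5, 10, 5), c(3, 3, 6, 3), c(4, 4, 8, 4), c(7, 7, 14, 7),
    # prosocial vs competitive: shared self payoff, other payoff differs
    c(10, 10, 10, 5), c(6, 6, 6, 3), c(8, 8, 8, 4), c(14, 14, 14, 7),
    # individualistic vs competitive: higher self with smaller gap vs
    # lower self with larger gap
    c(10, 5, 8, 1), c(12, 6, 10, 2), c(5, 3, 4, 1), c(14, 7, 11, 2)
  )
  out <- data.frame(r_ppt_1 = tpl[, 1], r_par_1 = tpl[, 2],
                    r_ppt_2 = tpl[, 3], r_par_2 = tpl[, 4])
  out$pair_type <- vapply(seq_len(nrow(out)), function(i) classify_pair(out[i, ]),
                          character(1))
  out
}

#' Classify an option pair by social value orientation contrast
#'
#' Classification rule: if the two options share the self payoff, the option
#' with the higher other payoff is prosocial and the lower is competitive
#' ("prosocial-competitive" pair). If they share the other payoff, the
#' equal-split option is prosocial and the higher-self option is
#' individualistic ("prosocial-individualistic"). Otherwise, when one option
#' has both the higher self payoff and the smaller self-other gap, it is
#' individualistic and the other competitive ("individualistic-competitive").
#' Pairs fitting none of these templates raise an error.
#'
#' @param pair list or one-row data frame with `r_ppt_1`, `r_par_1`,
#'   `r_ppt_2`, `r_par_2`.
#' @return the pair type string.
#' @seealso [classify_options()] for the per-option roles.
#' @export
classify_pair <- function(pair) {
  classify_options(pair)$pair_type
}

#' Per-option roles and pair type
#'
#' @param pair as in [classify_pair()].
#' @return list with `pair_type` and `roles` (length-2 character vector
#'   naming the orientation of option 1 and option 2).
#' @export
classify_options <- function(pair) {
  v <- c(pair$r_ppt_1, pair$r_par_1, pair$r_ppt_2, pair$r_par_2)
  if (any(v < 0) || any(v != round(v))) stop("point values must be non-negative integers")
  if (pair$r_ppt_1 == pair$r_ppt_2 && pair$r_par_1 == pair$r_par_2)
    stop("the two options are identical: (", pair$r_ppt_1, ",", pair$r_par_1, ")")
  gap1 <- pair$r_ppt_1 - pair$r_par_1
  gap2 <- pair$r_ppt_2 - pair$r_par_2
  if (pair$r_ppt_1 == pair$r_ppt_2) {
    roles <- if (pair$r_par_1 > pair$r_par_2) c("prosocial", "competitive")
             else c("competitive", "prosocial")
    return(list(pair_type = "prosocial-competitive", roles = roles))
  }
  if (pair$r_par_1 == pair$r_par_2) {
    eq1 <- pair$r_ppt_1 == pair$r_par_1
    eq2 <- pair$r_ppt_2 == pair$r_par_2
    if (eq1 && !eq2 && pair$r_ppt_2 > pair$r_ppt_1)
      return(list(pair_type = "prosocial-individualistic",
                  roles = c("prosocial", "individualistic")))
    if (eq2 && !eq1 && pair$r_ppt_1 > pair$r_ppt_2)
      return(list(pair_type = "prosocial-individualistic",
                  roles = c("individualistic", "prosocial")))
  } else {
    if (pair$r_ppt_1 > pair$r_ppt_2 && gap1 < gap2)
      return(list(pair_type = "individualistic-competitive",
                  roles = c("individualistic", "competitive")))
    if (pair$r_ppt_2 > pair$r_ppt_1 && gap2 < gap1)
      return(list(pair_type = "individualistic-competitive",
                  roles = c("competitive", "individualistic")))
  }
  stop("unclassifiable option pair: (", pair$r_ppt_1, ",", pair$r_par_1,
       ") vs (", pair$r_ppt_2, ",", pair$r_par_2, ")")
}

pair_types <- c("prosocial-individualistic", "prosocial-competitive",
                "individualistic-competitive")

#' Generate a three-phase task environment
#'
#' Phases 1 and 3 each hold `n_per_type_p13` option pairs of each of the
#' three pair types (default 12, i.e. 36 trials); phase 2 holds
#' `n_per_type_p2` of each (default 18, i.e. 54 trials) drawn from the same
#' template values. Within a phase, templates of each type are cycled to the
#' required count, trial order is a seeded uniform shuffle, and option
#' positions (1 vs 2) are independently flipped per trial under the seed.
#'
#' @param n_per_type_p13 pairs of each type in phases 1 and 3.
#' @param n_per_type_p2 pairs of each type in phase 2.
#' @param templates template table as from [default_pair_templates()]; must
#'   include all three pair types.
#' @param seed integer; identical seeds give identical environments.
#' @return an `so_env`: data frame with columns `phase`, `trial`,
#'   `r_ppt_1`, `r_par_1`, `r_ppt_2`, `r_par_2`, `pair_type`.
#' @export
generate_environment <- function(n_per_type_p13 = 12, n_per_type_p2 = 18,
                                 templates = default_pair_templates(),
                                 seed = 1L) {
  stopifnot(n_per_type_p13 >= 1, n_per_type_p2 >= 1)
  missing_types <- setdiff(pair_types, unique(templates$pair_type))
  if (length(missing_types))
    stop("templates missing pair type(s): ", paste(missing_types, collapse = ", "))
  build_phase <- function(n_per_type, phase_seed) {
    with_seed(phase_seed, {
      rows <- do.call(rbind, lapply(pair_types, function(tt) {
        idx <- which(templates$pair_type == tt)
        idx <- rep(idx, length.out = n_per_type)
        templates[idx, , drop = FALSE]
      }))
      rows <- rows[sample.int(nrow(rows)), , drop = FALSE]
      flip <- runif(nrow(rows)) < 0.5
      out <- rows
      out[flip, c("r_ppt_1", "r_par_1", "r_ppt_2", "r_par_2")] <-
        rows[flip, c("r_ppt_2", "r_par_2", "r_ppt_1", "r_par_1")]
      rownames(out) <- NULL
      out
    })
  }
  ph <- list(build_phase(n_per_type_p13, derive_seed(seed, 1)),
             build_phase(n_per_type_p2, derive_seed(seed, 2)),
             build_phase(n_per_type_p13, derive_seed(seed, 3)))
  env <- do.call(rbind, lapply(1:3, function(k) {
    cbind(phase = k, trial = seq_len(nrow(ph[[k]])), ph[[k]])
  }))
  rownames(env) <- NULL
  structure(env, class = c("so_env", "data.frame"), seed = seed)
}

#' Rows of an environment belonging to one phase
#' @param env an `so_env`.
#' @param phase 1, 2 or 3.
#' @export
env_phase <- function(env, phase) {
  env[env$phase == phase, , drop = FALSE]
}

#' Write / read an environment as CSV
#' @param env an `so_env`.
#' @param path file path.
#' @export
write_env_csv <- function(env, path) {
  write.csv(as.data.frame(env), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_env_csv
#' @export
read_env_csv <- function(path) {
  env <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("phase", "trial", "r_ppt_1", "r_par_1", "r_ppt_2", "r_par_2", "pair_type")
  miss <- setdiff(need, names(env))
  if (length(miss)) stop("environment CSV missing column(s): ", paste(miss, collapse = ", "))
  structure(env, class = c("so_env", "data.frame"))
}
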