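#' Write subject records as long CSV
#'
#' One row per trial: `subject`, `phase`, `trial`, the four option values,
#' `pair_type`, `response` (choice or prediction, coded 1/2),
#' `partner_decision` and `feedback` (phase 2 only, otherwise NA).
#'
#' @param records list of `so_subject` (or a single record).
#' @param path output file.
#' @export
write_subject_csv <- function(records, path) {
  if (inherits(records, "so_subject")) records <- list(records)
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    env <- as.data.frame(r$env)
    env$subject <- i
    env$response <- NA_integer_
    env$partner_decision <- NA_integer_
    env$feedback <- NA_integer_
    env$response[env$phase == 1] <- r$phase1_choices
    env$response[env$phase == 2] <- r$phase2_predictions
    env$response[env$phase == 3] <- r$phase3_choices
    env$partner_decision[env$phase == 2] <- r$phase2_partner
    env$feedback[env$phase == 2] <- as.integer(r$phase2_feedback)
    env[, c("subject", "phase", "trial", "r_ppt_1", "r_par_1", "r_ppt_2",
            "r_par_2", "pair_type", "response", "partner_decision", "feedback")]
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read subject records from long CSV
#'
#' Validates the schema written by [write_subject_csv()]: required columns,
#' responses coded 1/2, per-phase trial counts consistent across subjects,
#' and feedback equal to the prediction-decision match.
#'
#' @param path input file.
#' @return list of `so_subject`.
#' @export
read_subject_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "phase", "trial", "r_ppt_1", "r_par_1", "r_ppt_2",
            "r_par_2", "pair_type", "response", "partner_decision")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("subject CSV missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!d$response %in% c(1, 2))
  if (length(bad))
    stop("row ", bad[1], ": response coded ", d$response[bad[1]],
         "; responses must be coded 1 (option 1) or 2 (option 2)")
  bad2 <- which(d$phase == 2 & !d$partner_decision %in% c(1, 2))
  if (length(bad2))
    stop("row ", bad2[1], ": phase-2 partner decision must be coded 1 or 2")
  lapply(split(d, d$subject), function(s) {
    s <- s[order(s$phase, s$trial), ]
    env <- structure(s[, c("phase", "trial", "r_ppt_1", "r_par_1", "r_ppt_2",
                           "r_par_2", "pair_type")],
                     class = c("so_env", "data.frame"))
    n2 <- sum(s$phase == 2)
    if (n2 != 54)
      stop("subject ", s$subject[1], ": expected 54 phase-2 rows, found ", n2)
    for (ph in c(1, 3)) {
      if (sum(s$phase == ph) != 36)
        stop("subject ", s$subject[1], ": expected 36 phase-", ph,
             " rows, found ", sum(s$phase == ph))
    }
    new_subject(env,
                c1 = s$response[s$phase == 1],
                pred2 = s$response[s$phase == 2],
                d2 = s$partner_decision[s$phase == 2],
                c3 = s$response[s$phase == 3])
  })
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Accepts
#' a YAML file path or a named list; unnamed fields fall back to defaults.
#' All stage seeds are derived from the single `seed`.
#'
#' @param config named list or path to a YAML file.
#' @return an `so_run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configuration requires the yaml package")
    config <- yaml::yaml.load_file(config)
  }
  defaults <- list(seed = 1L, n_per_group = 10L,
                   models = c("M1", "M2", "M3", "M4"),
                   groups = c("control-like", "bpd-like"),
                   alpha_step = 0.125, beta_step = 0.25,
                   fit_alpha_step = 0.5, fit_beta_step = 1,
                   max_iter = 4L, out_dir = NULL, verbose = FALSE)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown configuration field(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  bad <- setdiff(cfg$models, c("M1", "M2", "M3", "M4", "Beta"))
  if (length(bad)) stop("unknown model name(s): ", paste(bad, collapse = ", "))
  bad_g <- setdiff(cfg$groups, c("control-like", "bpd-like"))
  if (length(bad_g)) stop("unknown group label(s): ", paste(bad_g, collapse = ", "))
  stopifnot(cfg$n_per_group >= 2)
  structure(cfg, class = "so_run_config")
}

#' Run the full synthetic pipeline
#'
#' simulate -> match (inside cohort generation) -> hierarchical fit and
#' model comparison per group -> parameter recovery of each group's
#' dominant model -> summary report. Deterministic given the configuration
#' seed. If `out_dir` is set, per-group cohort CSVs, ground-truth and
#' summary JSON are written there.
#'
#' @param config an [run_config()], list, or YAML path.
#' @return list with per-group `comparison`, `recovery`, `accuracy`, and a
#'   `summary` list (also serialised to JSON when `out_dir` is set).
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "so_run_config")) config <- run_config(config)
  sim_spec <- grid_spec(config$alpha_step, config$beta_step)
  fit_spec <- grid_spec(config$fit_alpha_step, config$fit_beta_step)
  results <- list()
  for (g in config$groups) {
    group <- default_group_spec(g)
    fitcfg <- fit_config(spec = fit_spec, max_iter = config$max_iter,
                         seed = derive_seed(config$seed, match(g, config$groups)))
    cohort <- generate_cohort(group, n = config$n_per_group,
                              seed = derive_seed(config$seed, 10 + match(g, config$groups)),
                              spec = sim_spec)
    cmp <- hierarchical_compare(config$models, cohort$records, fitcfg,
                                verbose = config$verbose)
    rec <- run_parameter_recovery(group, fitcfg,
                                  seed = derive_seed(config$seed, 20 + match(g, config$groups)),
                                  n = config$n_per_group, cohort = cohort)
    acc <- accuracy_summary(cohort$records)
    results[[g]] <- list(cohort = cohort, comparison = cmp, recovery = rec,
                         accuracy = acc)
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      slug <- gsub("-like$", "", g)
      write_subject_csv(cohort$records,
                        file.path(config$out_dir, paste0(slug, "_trials.csv")))
      write.csv(cohort$truth,
                file.path(config$out_dir, paste0(slug, "_truth.csv")),
                row.names = FALSE)
    }
  }
  summary <- lapply(results, function(r) list(
    frequency = as.list(r$comparison$frequency),
    pxp = as.list(r$comparison$pxp),
    winner = r$comparison$models[which.max(r$comparison$pxp)],
    recovery_rho = as.list(r$recovery$rho),
    mean_accuracy = mean(r$accuracy$per_subject),
    mean_similarity = mean(r$cohort$truth$achieved_similarity)))
  if (!is.null(config$out_dir)) {
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  c(results, list(summary = summary))
}
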