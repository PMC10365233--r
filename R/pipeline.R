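# End-to-end orchestration: synth -> activations -> fit (LOSO) -> suggest
# -> evaluate, with all artifacts written to an output directory. Runs are
# deterministic given the same configuration and seed; every JSON artifact
# embeds the configuration hash and seed.

#' Build a pipeline run configuration
#'
#' @param out_dir Output directory for artifacts.
#' @param synthetic A [synthetic_params()] describing the cohort to
#'   generate, or `NULL` to load inputs from `paths`.
#' @param paths Named list with `reviews` and `activations` CSV paths (used
#'   when `synthetic` is NULL).
#' @param strategies Suggestion strategies to run.
#' @param reg_grid Inverse regularization grid for the stimulation models.
#' @param n_permutations Permutations per evaluation test.
#' @param seed Master RNG seed (also seeds the synthetic cohort unless its
#'   params carry their own).
#' @param write_bundles Write TCK bundles when generating synthetically.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir, synthetic = synthetic_params(), paths = NULL,
                       strategies = c("initial", "combined", "window"),
                       reg_grid = 10^seq(-2, 3), n_permutations = 100000,
                       seed = 42, write_bundles = FALSE) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  if (!is.null(synthetic)) synthetic$seed <- seed
  structure(list(out_dir = out_dir, synthetic = synthetic, paths = paths,
                 strategies = strategies, reg_grid = reg_grid,
                 n_permutations = n_permutations, seed = seed,
                 write_bundles = write_bundles),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; `synthetic` holds
#' [synthetic_params()] arguments.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- if (!is.null(y$synthetic)) do.call(synthetic_params, y$synthetic)
  args <- y[setdiff(names(y), "synthetic")]
  do.call(run_config, c(args, list(synthetic = syn)))
}

run_stamp <- function(config) {
  list(config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
       seed = config$seed)
}

write_stamped_csv <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", stamp$config_hash,
                     stamp$seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full tract-guided programming pipeline
#'
#' Generates (or loads) the cohort, fits the HDP and CST stimulation models
#' under nested leave-one-subject-out cross-validation, produces per-lead
#' suggestions for each strategy, and evaluates them against the monopolar
#' reviews with balanced accuracy, permutation tests and threshold errors.
#' Artifacts (activation table, model cards, CV report, suggestion and
#' threshold CSVs, evaluation JSON) are written under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param verbose Log per-stage progress.
#' @return List with `cv` (per pathway), `suggestions` (per strategy),
#'   `evaluation` data frame, `threshold_errors` and the stamp, invisibly
#'   written to disk as well.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stamp <- run_stamp(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  if (!is.null(config$synthetic)) {
    pipeline_log(verbose, "synth: generating cohort (seed %d)", config$seed)
    cohort <- generate_cohort(config$synthetic, keep_bundles = config$write_bundles)
    if (config$write_bundles)
      write_cohort(cohort, file.path(config$out_dir, "cohort"),
                   write_bundles = TRUE)
    reviews <- cohort$reviews
    activations <- cohort$activations
  } else {
    if (is.null(config$paths$reviews) || is.null(config$paths$activations))
      stop("stage synth: config$paths must provide 'reviews' and 'activations'")
    reviews <- read_reviews(config$paths$reviews)
    activations <- utils::read.csv(config$paths$activations,
                                   comment.char = "#")
    cohort <- NULL
  }
  pipeline_log(verbose, "activations: %d rows for %d leads",
               nrow(activations), length(unique(activations$lead_id)))
  write_stamped_csv(activations, file.path(config$out_dir, "activations.csv"),
                    stamp)

  cv <- list()
  samples <- list()
  for (pw in c("HDP", "CST")) {
    samples[[pw]] <- build_training_samples(reviews, activations, pw)
    pipeline_log(verbose, "fit %s: %d samples (%d positive)", pw,
                 nrow(samples[[pw]]), sum(samples[[pw]]$label == "effect"))
    cv[[pw]] <- loso_cv(samples[[pw]], config$reg_grid)
  }
  cards <- lapply(cv, function(x) {
    pooled <- structure(
      list(pathway = x$folds[[1]]$model$pathway, beta0 = x$pooled_beta0,
           beta1 = x$pooled_beta1, boundary = x$pooled_boundary,
           reg_strength = NA_real_, class_cutoff = 0.5),
      class = "stim_model")
    c(model_card(pooled),
      list(mean_test_accuracy = x$mean_accuracy, ci95 = x$ci95,
           n_folds = x$n_folds))
  })
  write_report(c(stamp, list(models = cards)),
               file.path(config$out_dir, "model_cards.json"))
  cv_report <- do.call(rbind, lapply(names(cv), function(pw)
    data.frame(pathway = pw,
               subject_id = vapply(cv[[pw]]$folds, `[[`, "", "subject_id"),
               accuracy = vapply(cv[[pw]]$folds, `[[`, 0, "accuracy"),
               boundary = vapply(cv[[pw]]$folds,
                                 function(f) f$model$boundary, 0))))
  write_stamped_csv(cv_report, file.path(config$out_dir, "cv_report.csv"),
                    stamp)

  suggestions <- list()
  for (strategy in config$strategies) {
    pipeline_log(verbose, "suggest: strategy %s", strategy)
    suggestions[[strategy]] <- suggest_cohort(activations, cv$HDP, cv$CST,
                                              strategy)
    write_stamped_csv(suggestions[[strategy]]$labels,
                      file.path(config$out_dir,
                                sprintf("suggestions_%s.csv", strategy)),
                      stamp)
  }
  write_stamped_csv(suggestions[[1]]$thresholds,
                    file.path(config$out_dir, "suggested_thresholds.csv"),
                    stamp)

  pipeline_log(verbose, "evaluate: %d permutations", config$n_permutations)
  evaluation <- evaluate_suggestions(
    lapply(suggestions, `[[`, "labels"), reviews,
    n_perm = config$n_permutations, seed = config$seed)
  th <- suggestions[[1]]$thresholds
  errors <- list(
    effect = threshold_errors(
      data.frame(lead_id = th$lead_id, config_id = th$config_id,
                 value = th$effect_threshold_mA,
                 censored = th$effect_censored),
      data.frame(lead_id = reviews$lead_id, config_id = reviews$config_id,
                 value = reviews$effect_threshold_mA,
                 censored = reviews$effect_censored | !reviews$tested)),
    side_effect = threshold_errors(
      data.frame(lead_id = th$lead_id, config_id = th$config_id,
                 value = th$side_effect_threshold_mA,
                 censored = th$side_effect_censored),
      data.frame(lead_id = reviews$lead_id, config_id = reviews$config_id,
                 value = reviews$side_effect_threshold_mA,
                 censored = reviews$side_effect_censored | !reviews$tested)))
  write_report(c(stamp, list(
    evaluation = evaluation,
    threshold_errors = lapply(errors, function(e)
      e[c("median_abs", "median_signed", "n_excluded")]))),
    file.path(config$out_dir, "evaluation.json"))
  write_stamped_csv(rbind(
    cbind(pathway = "HDP", errors$effect$pairs),
    cbind(pathway = "CST", errors$side_effect$pairs)),
    file.path(config$out_dir, "threshold_errors.csv"), stamp)

  invisible(list(cohort = cohort, cv = cv, suggestions = suggestions,
                 evaluation = evaluation, threshold_errors = errors,
                 stamp = stamp))
}
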