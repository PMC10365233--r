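# Programming suggestions from fitted stimulation models: per-configuration
# effect / side-effect thresholds, and best/worst level and contact under
# three strategies (initial, combined, therapeutic window).
#
# Censoring substitute: a censored side-effect threshold enters window
# arithmetic as 8.5 mA (one grid step past the sweep end). Tie-breaking for
# "best" is deterministic: (1) larger therapeutic window, (2) lower effect
# threshold, (3) more distal configuration; for "worst": (1) smaller window,
# (2) more distal configuration.

CENSOR_SUBSTITUTE_MA <- 8.5

suggestion_grid <- function() seq(1, 8, by = 0.5)

#' Suggest a stimulation threshold from a model and an activation profile
#'
#' The smallest grid amplitude whose activation the model classifies as
#' "effect"; censored if no grid amplitude is classified as effect.
#'
#' @param model A `stim_model`.
#' @param profile Data frame with `amplitude_mA` and `activation` covering
#'   the 1-8 mA grid.
#' @return List with `threshold` (mA, NA if censored) and `censored`.
#' @export
suggest_threshold <- function(model, profile) {
  prof <- profile[profile$amplitude_mA >= 1 - 1e-9, ]
  prof <- prof[order(prof$amplitude_mA), ]
  lab <- predict_class(model, prof$activation)$label
  hit <- which(lab == "effect")
  if (!length(hit)) list(threshold = NA_real_, censored = TRUE)
  else list(threshold = prof$amplitude_mA[hit[1]], censored = FALSE)
}

#' Per-configuration suggested thresholds for one lead
#'
#' Applies the HDP model to suggest effect thresholds and the CST model to
#' suggest side-effect thresholds for every configuration in the activation
#' table, and computes therapeutic windows (censored side-effect thresholds
#' substitute 8.5 mA; a censored effect threshold leaves the window NA).
#'
#' @param models Named list with `HDP` and `CST` `stim_model`s.
#' @param activations Activation table rows for one lead.
#' @return Data frame with one row per configuration: `config_id`, `level`,
#'   `effect_threshold_mA`, `effect_censored`, `side_effect_threshold_mA`,
#'   `side_effect_censored`, `therapeutic_window_mA`.
#' @export
lead_config_thresholds <- function(models, activations) {
  stopifnot(length(unique(activations$lead_id)) == 1L)
  configs <- intersect(review_configs(), unique(activations$config_id))
  rows <- lapply(configs, function(cfg) {
    sub <- activations[activations$config_id == cfg, ]
    eff <- suggest_threshold(models$HDP,
                             sub[sub$pathway == "HDP", ])
    se <- suggest_threshold(models$CST,
                            sub[sub$pathway == "CST", ])
    se_sub <- if (se$censored) CENSOR_SUBSTITUTE_MA else se$threshold
    data.frame(config_id = cfg, level = config_level(cfg),
               effect_threshold_mA = eff$threshold,
               effect_censored = eff$censored,
               side_effect_threshold_mA = se$threshold,
               side_effect_censored = se$censored,
               therapeutic_window_mA = if (eff$censored) NA_real_
                                       else se_sub - eff$threshold)
  })
  out <- do.call(rbind, rows)
  out$lead_id <- activations$lead_id[1]
  out
}

# Window with censoring substitutes on both sides, for tie-breaking.
window_sub <- function(th) {
  eff <- ifelse(th$effect_censored, CENSOR_SUBSTITUTE_MA, th$effect_threshold_mA)
  se <- ifelse(th$side_effect_censored, CENSOR_SUBSTITUTE_MA,
               th$side_effect_threshold_mA)
  se - eff
}

# Distal-first ordering over configurations: level, then contact position.
config_rank_index <- function(config_id) {
  idx <- c(C1 = 11, C2 = 21, C3 = 22, C4 = 23, C5 = 31, C6 = 32, C7 = 33,
           C8 = 41, L2 = 20, L3 = 30)
  unname(idx[config_id])
}

# Pick the winning row index by a primary key with deterministic tie-breaks;
# rows with primary = Inf (all censored) yield "none".
pick_config <- function(th, primary, tie1, tie2) {
  if (!nrow(th) || all(!is.finite(primary))) return(NA_integer_)
  ord <- order(primary, tie1, tie2)
  ord[1]
}

candidate_rows <- function(th, granularity = c("level", "contact")) {
  granularity <- match.arg(granularity)
  ids <- if (granularity == "level") unname(level_configs()) else contact_configs()
  th[match(ids, th$config_id), , drop = FALSE]
}

config_label <- function(config_id, granularity) {
  if (is.na(config_id)) return("none")
  if (granularity == "level")
    names(level_configs())[match(config_id, level_configs())]
  else config_id
}

best_of <- function(th, granularity) {
  cand <- candidate_rows(th, granularity)
  eff <- ifelse(cand$effect_censored | is.na(cand$effect_threshold_mA),
                Inf, cand$effect_threshold_mA)
  i <- pick_config(cand, eff, -window_sub(cand), config_rank_index(cand$config_id))
  config_label(if (is.na(i)) NA_character_ else cand$config_id[i], granularity)
}

worst_of <- function(th, granularity) {
  cand <- candidate_rows(th, granularity)
  se <- ifelse(cand$side_effect_censored | is.na(cand$side_effect_threshold_mA),
               Inf, cand$side_effect_threshold_mA)
  i <- pick_config(cand, se, window_sub(cand), config_rank_index(cand$config_id))
  config_label(if (is.na(i)) NA_character_ else cand$config_id[i], granularity)
}

#' Initial suggestion: best from the HDP model, worst from the CST model
#'
#' Best level/contact = lowest suggested effect threshold; worst = lowest
#' suggested side-effect threshold. Censored thresholds rank last; all
#' censored yields "none".
#'
#' @param th Per-configuration thresholds (see [lead_config_thresholds()]).
#' @param which "best", "worst" or both.
#' @return Named list of labels, e.g. `best_level`, `best_contact`.
#' @export
suggest_initial <- function(th, which = c("best", "worst")) {
  out <- list()
  if ("best" %in% which) {
    out$best_level <- best_of(th, "level")
    out$best_contact <- best_of(th, "contact")
  }
  if ("worst" %in% which) {
    out$worst_level <- worst_of(th, "level")
    out$worst_contact <- worst_of(th, "contact")
  }
  out
}

combined_keep <- function(th) {
  se_sub <- ifelse(th$side_effect_censored, CENSOR_SUBSTITUTE_MA,
                   th$side_effect_threshold_mA)
  keep <- !th$effect_censored &
    (th$side_effect_censored |
       th$effect_threshold_mA <= th$side_effect_threshold_mA + 1.0 + 1e-9)
  keep & !is.na(se_sub)
}

#' Combined suggestion using both stimulation models
#'
#' Configurations where the suggested effect threshold exceeds the suggested
#' side-effect threshold by more than 1 mA are excluded (side effects before
#' full effect); a censored side-effect threshold keeps the configuration, a
#' censored effect threshold excludes it. Among the kept configurations the
#' best level/contact has the lowest suggested effect threshold.
#'
#' @param th Per-configuration thresholds (see [lead_config_thresholds()]).
#' @return List with `best_level`, `best_contact` and `excluded_configs`.
#' @export
suggest_combined <- function(th) {
  keep <- combined_keep(th)
  th_kept <- th[keep, , drop = FALSE]
  out <- list(best_level = best_of(th_kept, "level"),
              best_contact = best_of(th_kept, "contact"))
  out$excluded_configs <- th$config_id[!keep]
  out
}

#' Therapeutic-window suggestion
#'
#' Best level/contact = largest therapeutic window (suggested side-effect
#' threshold minus suggested effect threshold; censored side-effect
#' thresholds substitute 8.5 mA). Configurations with a censored effect
#' threshold are excluded. Ties prefer the lower effect threshold, then the
#' more distal configuration.
#'
#' @param th Per-configuration thresholds (see [lead_config_thresholds()]).
#' @return List with `best_level` and `best_contact`.
#' @export
suggest_window <- function(th) {
  pick <- function(granularity) {
    cand <- candidate_rows(th, granularity)
    w <- ifelse(cand$effect_censored, -Inf, window_sub(cand))
    eff <- ifelse(cand$effect_censored, Inf, cand$effect_threshold_mA)
    ok <- is.finite(w)
    if (!any(ok)) return(config_label(NA_character_, granularity))
    i <- pick_config(cand, -w, eff, config_rank_index(cand$config_id))
    config_label(cand$config_id[i], granularity)
  }
  list(best_level = pick("level"), best_contact = pick("contact"))
}

#' Per-lead suggestions for a cohort under LOSO cross-validation
#'
#' For every lead, thresholds and labels are produced with the stimulation
#' models of the fold that held out the lead's subject, so no suggestion
#' uses a model trained on its own subject.
#'
#' @param activations Activation table for the cohort.
#' @param cv_hdp,cv_cst `loso_cv` results for the HDP and CST models.
#' @param strategy "initial", "combined" or "window".
#' @return List with `labels` (one row per lead) and `thresholds` (one row
#'   per lead x configuration).
#' @export
suggest_cohort <- function(activations, cv_hdp, cv_cst,
                           strategy = c("initial", "combined", "window")) {
  strategy <- match.arg(strategy)
  leads <- unique(activations[c("subject_id", "lead_id")])
  labels <- list()
  ths <- list()
  for (i in seq_len(nrow(leads))) {
    s <- leads$subject_id[i]
    models <- list(HDP = cv_hdp$folds[[s]]$model, CST = cv_cst$folds[[s]]$model)
    if (is.null(models$HDP) || is.null(models$CST)) next
    acts <- activations[activations$lead_id == leads$lead_id[i], ]
    th <- lead_config_thresholds(models, acts)
    lab <- switch(strategy,
                  initial = suggest_initial(th),
                  combined = suggest_combined(th),
                  window = suggest_window(th))
    labels[[i]] <- data.frame(
      subject_id = s, lead_id = leads$lead_id[i], strategy = strategy,
      best_level = lab$best_level %||% NA_character_,
      best_contact = lab$best_contact %||% NA_character_,
      worst_level = lab$worst_level %||% NA_character_,
      worst_contact = lab$worst_contact %||% NA_character_,
      excluded_configs = paste(lab$excluded_configs %||% character(0),
                               collapse = ";"))
    ths[[i]] <- th
  }
  list(labels = do.call(rbind, labels), thresholds = do.call(rbind, ths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
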