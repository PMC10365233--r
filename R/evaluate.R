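# Scoring suggestions against clinical labels: balanced accuracy, a
# right-tailed permutation test, threshold errors and contact distances.

#' Balanced accuracy from confusion counts
#'
#' The arithmetic mean of sensitivity (TP / (TP + FN)) and specificity
#' (TN / (TN + FP)).
#'
#' @param counts Named list or vector with `tp`, `fn`, `tn`, `fp`.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(counts) {
  counts <- as.list(counts)
  tp <- counts$tp; fn <- counts$fn; tn <- counts$tn; fp <- counts$fp
  if (any(c(tp, fn, tn, fp) < 0)) stop("confusion counts must be non-negative")
  if (tp + fn == 0 || tn + fp == 0)
    stop("balanced accuracy is undefined when a class is empty")
  0.5 * (tp / (tp + fn) + tn / (tn + fp))
}

confusion_counts <- function(suggested, clinical) {
  stopifnot(length(suggested) == length(clinical))
  list(tp = sum(suggested == 1 & clinical == 1),
       fn = sum(suggested == 0 & clinical == 1),
       tn = sum(suggested == 0 & clinical == 0),
       fp = sum(suggested == 1 & clinical == 0))
}

#' Clinical best/worst labels from a monopolar review
#'
#' The clinical best level/contact of a lead is the candidate with the
#' lowest observed effect threshold; the worst, the candidate with the
#' lowest side-effect threshold. Censored and untested candidates rank
#' last; ties follow the same deterministic rules as the suggestions.
#'
#' @param reviews Review data frame.
#' @param granularity "level" (candidates C1, L2, L3, C8, labeled L1-L4) or
#'   "contact" (C1-C8).
#' @param which "best" or "worst".
#' @return Data frame with `lead_id` and `label` (NA when no candidate has
#'   an observed threshold).
#' @export
clinical_labels <- function(reviews, granularity = c("level", "contact"),
                            which = c("best", "worst")) {
  granularity <- match.arg(granularity)
  which <- match.arg(which)
  leads <- unique(reviews$lead_id)
  thr_col <- if (which == "best") "effect_threshold_mA" else "side_effect_threshold_mA"
  cens_col <- if (which == "best") "effect_censored" else "side_effect_censored"
  out <- lapply(leads, function(ld) {
    rv <- reviews[reviews$lead_id == ld & reviews$tested, ]
    th <- data.frame(config_id = rv$config_id,
                     effect_threshold_mA = rv$effect_threshold_mA,
                     effect_censored = rv$effect_censored,
                     side_effect_threshold_mA = rv$side_effect_threshold_mA,
                     side_effect_censored = rv$side_effect_censored)
    lab <- if (which == "best") best_of(th, granularity)
           else worst_of(th, granularity)
    data.frame(lead_id = ld, label = if (identical(lab, "none")) NA_character_
                                     else lab)
  })
  do.call(rbind, out)
}

#' Paired binary label vectors for suggestion scoring
#'
#' Expands per-lead best/worst labels into paired binary vectors with one
#' entry per candidate (4 levels or 8 contacts) per lead, concatenated
#' across leads. Leads without a clinical label are dropped with a warning.
#'
#' @param suggestions Suggestion labels (one row per lead, see
#'   [suggest_cohort()]).
#' @param clinical Clinical labels (see [clinical_labels()]).
#' @param granularity "level" or "contact".
#' @param which "best" or "worst".
#' @return List with binary vectors `suggested` and `clinical`, the
#'   candidate block size `n_per_lead` and the `lead_id`s used.
#' @export
label_vectors <- function(suggestions, clinical,
                          granularity = c("level", "contact"),
                          which = c("best", "worst")) {
  granularity <- match.arg(granularity)
  which <- match.arg(which)
  cands <- if (granularity == "level") paste0("L", 1:4) else contact_configs()
  col <- paste0(which, "_", granularity)
  merged <- merge(suggestions[c("lead_id", col)], clinical, by = "lead_id")
  drop <- is.na(merged$label)
  if (any(drop))
    warning(sprintf("%d lead(s) without clinical %s %s label dropped",
                    sum(drop), which, granularity))
  merged <- merged[!drop, ]
  merged[[col]][is.na(merged[[col]])] <- "none"
  sugg <- as.vector(vapply(merged[[col]], function(x) as.numeric(cands == x),
                           numeric(length(cands))))
  clin <- as.vector(vapply(merged$label, function(x) as.numeric(cands == x),
                           numeric(length(cands))))
  list(suggested = sugg, clinical = clin, n_per_lead = length(cands),
       lead_id = merged$lead_id)
}

#' Right-tailed permutation test on the balanced accuracy
#'
#' The suggestion vector is permuted uniformly at random and the balanced
#' accuracy against the fixed clinical vector recomputed. Under a uniform
#' shuffle of a binary vector the number of true positives is
#' hypergeometric, which is drawn directly; this is distributionally
#' identical to explicit shuffling. The default p-value uses the add-one
#' correction p = (1 + #{stat >= observed}) / (1 + n); `add_one = FALSE`
#' gives the plain fraction.
#'
#' @param suggested,clinical Paired binary vectors.
#' @param n_perm Number of permutations (default 100000).
#' @param seed Optional RNG seed for reproducibility.
#' @param blocks Optional block labels (e.g. lead ids) for within-block
#'   shuffling; default shuffles the full concatenated vector.
#' @param add_one Use the add-one correction (default TRUE).
#' @return Object of class `permutation_result` with `observed_statistic`,
#'   `n_permutations`, `p_value` and `seed`.
#' @export
permutation_test <- function(suggested, clinical, n_perm = 100000,
                             seed = NULL, blocks = NULL, add_one = TRUE) {
  stopifnot(length(suggested) == length(clinical))
  if (!is.null(seed)) set.seed(seed)
  n <- length(clinical)
  P <- sum(clinical == 1)
  N <- n - P
  if (P == 0 || N == 0) stop("both classes must be present in the clinical vector")
  obs <- balanced_accuracy(confusion_counts(suggested, clinical))
  stat_from_tp <- function(tp, k) {
    fp <- k - tp
    0.5 * (tp / P + (N - fp) / N)
  }
  if (is.null(blocks)) {
    k <- sum(suggested == 1)
    tp <- stats::rhyper(n_perm, m = P, n = N, k = k)
    stat <- stat_from_tp(tp, k)
  } else {
    stopifnot(length(blocks) == n)
    tp_tot <- fp_tot <- numeric(n_perm)
    for (b in unique(blocks)) {
      i <- blocks == b
      kb <- sum(suggested[i] == 1)
      pb <- sum(clinical[i] == 1)
      tpb <- stats::rhyper(n_perm, m = pb, n = sum(i) - pb, k = kb)
      tp_tot <- tp_tot + tpb
      fp_tot <- fp_tot + (kb - tpb)
    }
    stat <- 0.5 * (tp_tot / P + (N - fp_tot) / N)
  }
  n_ge <- sum(stat >= obs - 1e-12)
  p <- if (add_one) (1 + n_ge) / (1 + n_perm) else n_ge / n_perm
  structure(list(observed_statistic = obs, n_permutations = n_perm,
                 p_value = p, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> balanced accuracy %.3f; p = %.4g (%d permutations)\n",
              x$observed_statistic, x$p_value, x$n_permutations))
  invisible(x)
}

#' Threshold suggestion errors against clinical thresholds
#'
#' Pairs suggested with clinical thresholds per lead and configuration;
#' pairs where either side is censored or missing are excluded (their count
#' is reported). Signed error = suggested - clinical.
#'
#' @param suggested Data frame with `lead_id`, `config_id`, `value`,
#'   `censored`.
#' @param clinical Same columns for the clinical thresholds.
#' @return List with `absolute`, `signed`, `median_abs`, `median_signed`,
#'   `n_excluded` and a `pairs` data frame (lead, config, both values).
#' @export
threshold_errors <- function(suggested, clinical) {
  m <- merge(suggested, clinical, by = c("lead_id", "config_id"),
             suffixes = c("_sugg", "_clin"))
  valid <- !m$censored_sugg & !m$censored_clin &
    !is.na(m$value_sugg) & !is.na(m$value_clin)
  n_excluded <- sum(!valid)
  m <- m[valid, ]
  if (!nrow(m)) stop("no valid threshold pairs (all censored or missing)")
  signed <- m$value_sugg - m$value_clin
  list(absolute = abs(signed), signed = signed,
       median_abs = stats::median(abs(signed)),
       median_signed = stats::median(signed),
       n_excluded = n_excluded,
       pairs = data.frame(lead_id = m$lead_id, config_id = m$config_id,
                          suggested_mA = m$value_sugg,
                          clinical_mA = m$value_clin,
                          signed_error_mA = signed))
}

#' Distance between a suggested and a clinical best contact
#'
#' @param suggested_contact,clinical_contact Contact tokens (C1-C8) on the
#'   same lead.
#' @param lead The lead's [lead_model()].
#' @return List with `same_level` and `euclidean_mm` (centroid distance).
#' @export
contact_distance <- function(suggested_contact, clinical_contact, lead) {
  frames <- contact_frames(lead)
  a <- frames[frames$config_id == suggested_contact, ]
  b <- frames[frames$config_id == clinical_contact, ]
  if (!nrow(a) || !nrow(b)) stop("contacts must be C1-C8")
  d <- c(a$cx - b$cx, a$cy - b$cy, a$cz - b$cz)
  list(same_level = a$level == b$level, euclidean_mm = sqrt(sum(d * d)))
}

#' Evaluate cohort suggestions against the monopolar reviews
#'
#' Builds label vectors for each requested strategy, direction and
#' granularity, computes sensitivity, specificity, balanced accuracy and a
#' right-tailed permutation p-value.
#'
#' @param suggestions_by_strategy Named list of suggestion label data frames
#'   (one per strategy).
#' @param reviews Review data frame.
#' @param n_perm Permutations per test.
#' @param seed RNG seed for the permutation tests.
#' @return Data frame with one row per strategy x which x granularity.
#' @export
evaluate_suggestions <- function(suggestions_by_strategy, reviews,
                                 n_perm = 100000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (strategy in names(suggestions_by_strategy)) {
    sugg <- suggestions_by_strategy[[strategy]]
    whichs <- if (strategy == "initial") c("best", "worst") else "best"
    for (wh in whichs) {
      for (gr in c("level", "contact")) {
        clin <- clinical_labels(reviews, gr, wh)
        lv <- label_vectors(sugg, clin, gr, wh)
        cc <- confusion_counts(lv$suggested, lv$clinical)
        pt <- permutation_test(lv$suggested, lv$clinical, n_perm = n_perm)
        rows[[length(rows) + 1L]] <- data.frame(
          strategy = strategy, which = wh, granularity = gr,
          sensitivity = cc$tp / (cc$tp + cc$fn),
          specificity = cc$tn / (cc$tn + cc$fp),
          balanced_accuracy = pt$observed_statistic,
          p_value = pt$p_value,
          n_leads = length(lv$lead_id))
      }
    }
  }
  do.call(rbind, rows)
}
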