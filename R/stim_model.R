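# Logistic stimulation models: probability of (side) effect as a function of
# the pathway activation fraction. One model per pathway: HDP activation vs
# therapeutic effect, CST activation vs capsular side effect. Fits are
# L2-penalized maximum likelihood (ridge on the slope only, unpenalized
# intercept); the inverse regularization strength is selected by
# subject-grouped inner cross-validation maximizing balanced accuracy.

#' Build training samples from monopolar reviews and activation tables
#'
#' For every tested configuration of every lead: one negative sample
#' ("no_effect") with the activation at 0.5 mA, and, if the relevant
#' threshold (effect for HDP, side effect for CST) is observed (uncensored),
#' one positive sample ("effect") with the activation at that threshold.
#' Censored thresholds contribute no positive sample.
#'
#' @param reviews Review data frame (see [read_reviews()]).
#' @param activations Activation table (see [activation_table()]).
#' @param pathway "HDP" or "CST".
#' @return Data frame of samples: `subject_id`, `lead_id`, `config_id`,
#'   `amplitude_mA`, `pathway`, `activation`, `label`.
#' @export
build_training_samples <- function(reviews, activations, pathway = c("HDP", "CST")) {
  pathway <- match.arg(pathway)
  acts <- activations[activations$pathway == pathway, ]
  akey <- paste(acts$lead_id, acts$config_id, acts$amplitude_mA)
  lookup <- function(lead_id, config_id, amp) {
    i <- match(paste(lead_id, config_id, amp), akey)
    if (is.na(i))
      stop(sprintf("no %s activation at %.1f mA for lead %s config %s",
                   pathway, amp, lead_id, config_id))
    acts$activation[i]
  }
  thr_col <- if (pathway == "HDP") "effect_threshold_mA" else "side_effect_threshold_mA"
  cens_col <- if (pathway == "HDP") "effect_censored" else "side_effect_censored"
  rows <- list()
  for (i in which(reviews$tested)) {
    r <- reviews[i, ]
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = r$subject_id, lead_id = r$lead_id, config_id = r$config_id,
      amplitude_mA = 0.5, pathway = pathway,
      activation = lookup(r$lead_id, r$config_id, 0.5), label = "no_effect")
    thr <- r[[thr_col]]
    if (!r[[cens_col]] && !is.na(thr)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = r$subject_id, lead_id = r$lead_id, config_id = r$config_id,
        amplitude_mA = thr, pathway = pathway,
        activation = lookup(r$lead_id, r$config_id, thr), label = "effect")
    }
  }
  if (!length(rows)) stop("no tested configurations in reviews")
  do.call(rbind, rows)
}

# Ridge-penalized logistic regression with a single predictor. Minimizes
# -loglik + beta1^2 / (2 C) by damped Newton iteration; the intercept is not
# penalized (sklearn convention for the inverse regularization C).
ridge_logistic <- function(a, y, C) {
  lambda <- 1 / C
  b <- c(0, 0)
  X <- cbind(1, a)
  obj <- function(b) {
    eta <- X %*% b
    -sum(y * eta - log1p(exp(eta))) + lambda / 2 * b[2]^2
  }
  f <- obj(b)
  for (it in 1:200) {
    eta <- as.vector(X %*% b)
    p <- stats::plogis(eta)
    g <- crossprod(X, p - y) + c(0, lambda * b[2])
    w <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(X, X * w) + diag(c(0, lambda))
    delta <- tryCatch(solve(H, g), error = function(e) g / max(diag(H)))
    step <- 1
    repeat {
      b_new <- b - step * as.vector(delta)
      f_new <- obj(b_new)
      if (is.finite(f_new) && f_new <= f + 1e-12) break
      step <- step / 2
      if (step < 1e-10) { b_new <- b; f_new <- f; break }
    }
    converged <- max(abs(b_new - b)) < 1e-10
    b <- b_new
    f <- f_new
    if (converged) break
  }
  b
}

samples_xy <- function(samples) {
  stopifnot(all(samples$label %in% c("effect", "no_effect")))
  list(a = samples$activation, y = as.numeric(samples$label == "effect"))
}

inner_groups <- function(subject_id, n_groups) {
  subj <- sort(unique(subject_id))
  fold_of <- rep_len(seq_len(min(n_groups, length(subj))), length(subj))
  fold_of[match(subject_id, subj)]
}

#' Fit a logistic stimulation model
#'
#' L2-penalized logistic regression of the binary effect label on the
#' activation fraction. The inverse regularization strength is chosen from
#' `reg_grid` by subject-grouped inner cross-validation maximizing the
#' balanced accuracy of pooled out-of-fold predictions; ties prefer the
#' smaller (more regularized) value.
#'
#' @param samples Training samples (see [build_training_samples()]); both
#'   labels must be present.
#' @param reg_grid Candidate inverse regularization strengths.
#' @param inner_folds Number of subject groups for the inner CV.
#' @param pathway Pathway label stored on the model.
#' @param class_cutoff Probability cutoff for classification.
#' @return Object of class `stim_model` with `beta0`, `beta1`,
#'   `reg_strength`, `boundary` (activation at probability 0.5) and
#'   `class_cutoff`.
#' @export
fit_stim_model <- function(samples, reg_grid = 10^seq(-2, 3), inner_folds = 5,
                           pathway = samples$pathway[1], class_cutoff = 0.5) {
  xy <- samples_xy(samples)
  if (length(unique(xy$y)) < 2L)
    stop("training samples contain a single class; cannot fit a stimulation model")
  n_subj <- length(unique(samples$subject_id))
  reg <- if (length(reg_grid) == 1L || n_subj < 2L) {
    reg_grid[1]
  } else {
    grp <- inner_groups(samples$subject_id, inner_folds)
    scores <- vapply(reg_grid, function(C) {
      pred <- rep(NA_real_, length(xy$y))
      for (g in unique(grp)) {
        tr <- grp != g
        if (length(unique(xy$y[tr])) < 2L) next
        b <- ridge_logistic(xy$a[tr], xy$y[tr], C)
        pred[!tr] <- stats::plogis(b[1] + b[2] * xy$a[!tr])
      }
      ok <- !is.na(pred)
      yy <- xy$y[ok]
      yhat <- as.numeric(pred[ok] >= class_cutoff)
      tp <- sum(yhat == 1 & yy == 1); fn <- sum(yhat == 0 & yy == 1)
      tn <- sum(yhat == 0 & yy == 0); fp <- sum(yhat == 1 & yy == 0)
      if (tp + fn == 0 || tn + fp == 0) return(NA_real_)
      0.5 * (tp / (tp + fn) + tn / (tn + fp))
    }, 0)
    if (all(is.na(scores))) reg_grid[1] else reg_grid[which.max(scores)]
  }
  b <- ridge_logistic(xy$a, xy$y, reg)
  structure(
    list(pathway = pathway, beta0 = b[1], beta1 = b[2], reg_strength = reg,
         class_cutoff = class_cutoff, boundary = -b[1] / b[2],
         n_samples = length(xy$y)),
    class = "stim_model")
}

#' @export
print.stim_model <- function(x, ...) {
  cat(sprintf("<stim_model> %s: p(effect) = logistic(%.3f + %.3f a); boundary a50 = %.4f (C = %g)\n",
              x$pathway, x$beta0, x$beta1, x$boundary, x$reg_strength))
  invisible(x)
}

#' Predict effect probability and label
#'
#' @param model A `stim_model`.
#' @param activation Activation fraction(s) in `[0, 1]`.
#' @return Data frame with `activation`, `probability` and `label`
#'   ("effect" when probability >= cutoff; ties classify as effect).
#' @export
predict_class <- function(model, activation) {
  p <- stats::plogis(model$beta0 + model$beta1 * activation)
  data.frame(activation = activation, probability = p,
             label = ifelse(p >= model$class_cutoff, "effect", "no_effect"))
}

#' Activation at a given effect probability
#'
#' Inverse of the logistic curve: the activation fraction at which the model
#' assigns probability `p`.
#'
#' @param model A `stim_model`.
#' @param p Probability in (0, 1).
#' @return Activation fraction.
#' @export
activation_at_probability <- function(model, p) {
  stopifnot(all(p > 0), all(p < 1))
  if (model$beta1 == 0) stop("slope is 0; inverse activation is undefined")
  (stats::qlogis(p) - model$beta0) / model$beta1
}

#' Nested leave-one-subject-out cross-validation
#'
#' One outer fold per subject: the model is fit on all other subjects (with
#' inner subject-grouped selection of the regularization strength) and
#' evaluated on the held-out subject's samples. Folds whose training set
#' contains a single class are skipped with a warning.
#'
#' @param samples Training samples for one pathway.
#' @param reg_grid Candidate inverse regularization strengths.
#' @param inner_folds Number of subject groups for the inner CV.
#' @param class_cutoff Probability cutoff for classification.
#' @return Object of class `loso_cv`: per-fold models, predictions and
#'   accuracies, the mean accuracy with a normal-approximation 95% CI across
#'   folds, and `pooled_boundary`, the mean of the per-fold decision
#'   boundaries -beta0/beta1.
#' @export
loso_cv <- function(samples, reg_grid = 10^seq(-2, 3), inner_folds = 5,
                    class_cutoff = 0.5) {
  subjects <- sort(unique(samples$subject_id))
  if (length(subjects) < 3L) stop("leave-one-subject-out needs >= 3 subjects")
  folds <- list()
  for (s in subjects) {
    train <- samples[samples$subject_id != s, ]
    test <- samples[samples$subject_id == s, ]
    if (length(unique(train$label)) < 2L) {
      warning(sprintf("fold '%s' skipped: single-class training set", s))
      next
    }
    model <- fit_stim_model(train, reg_grid, inner_folds,
                            class_cutoff = class_cutoff)
    pred <- predict_class(model, test$activation)
    pred$subject_id <- test$subject_id
    pred$lead_id <- test$lead_id
    pred$config_id <- test$config_id
    pred$true_label <- test$label
    folds[[s]] <- list(subject_id = s, model = model, predictions = pred,
                       accuracy = mean(pred$label == test$label))
  }
  if (!length(folds)) stop("no usable folds")
  acc <- vapply(folds, `[[`, 0, "accuracy")
  boundaries <- vapply(folds, function(f) f$model$boundary, 0)
  se <- stats::sd(acc) / sqrt(length(acc))
  structure(
    list(folds = folds, mean_accuracy = mean(acc),
         ci95 = mean(acc) + c(-1, 1) * 1.96 * se,
         pooled_boundary = mean(boundaries),
         pooled_beta0 = mean(vapply(folds, function(f) f$model$beta0, 0)),
         pooled_beta1 = mean(vapply(folds, function(f) f$model$beta1, 0)),
         n_folds = length(folds)),
    class = "loso_cv")
}

#' @export
print.loso_cv <- function(x, ...) {
  cat(sprintf("<loso_cv> %d folds; mean accuracy %.3f (95%% CI %.3f-%.3f); pooled boundary %.4f\n",
              x$n_folds, x$mean_accuracy, x$ci95[1], x$ci95[2],
              x$pooled_boundary))
  invisible(x)
}

#' Model card for a fitted stimulation model
#'
#' @param model A `stim_model`.
#' @param probabilities Probabilities at which to report the inverse
#'   activation.
#' @return List suitable for JSON serialization.
#' @export
model_card <- function(model, probabilities = c(0.5, 0.95, 0.99)) {
  list(pathway = model$pathway, beta0 = model$beta0, beta1 = model$beta1,
       odds_ratio = exp(model$beta1),
       reg_strength = model$reg_strength,
       boundary = model$boundary,
       activation_at_probability = stats::setNames(
         as.list(activation_at_probability(model, probabilities)),
         sprintf("p%02.0f", 100 * probabilities)))
}
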