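toy_activations <- function(lead_id, acts_by_amp) {
  do.call(rbind, lapply(names(acts_by_amp), function(cfg)
    data.frame(subject_id = "S01", lead_id = lead_id, config_id = cfg,
               amplitude_mA = acts_by_amp[[cfg]]$amp,
               pathway = rep(c("HDP", "CST"), each = length(acts_by_amp[[cfg]]$amp)),
               activation = rep(acts_by_amp[[cfg]]$act, 2))))
}

test_that("training samples pair 0.5 mA negatives with threshold positives", {
  rv <- data.frame(
    subject_id = "S01", lead_id = "S01_R",
    config_id = c("C1", "C2", "L2", "L3"),
    effect_threshold_mA = c(2, 3, 2.5, 2),
    effect_censored = FALSE,
    side_effect_threshold_mA = c(4, 5, 4.5, 6),
    side_effect_censored = FALSE, tested = TRUE)
  amps <- c(0.5, 2, 2.5, 3, 4, 4.5, 5, 6)
  acts <- toy_activations("S01_R", stats::setNames(
    lapply(1:4, function(i) list(amp = amps, act = seq(0.01, 0.4, length.out = 8))),
    c("C1", "C2", "L2", "L3")))
  for (pw in c("HDP", "CST")) {
    s <- build_training_samples(rv, acts, pw)
    expect_identical(nrow(s), 8L)   # 4 negatives + 4 positives
    expect_identical(sum(s$label == "no_effect"), 4L)
    expect_true(all(s$amplitude_mA[s$label == "no_effect"] == 0.5))
  }
  # censored side-effect threshold: CST gets the negative sample only
  rv$side_effect_censored[2] <- TRUE
  rv$side_effect_threshold_mA[2] <- NA
  s <- build_training_samples(rv, acts, "CST")
  expect_identical(nrow(s), 7L)
  expect_identical(sum(s$lead_id == "S01_R" & s$config_id == "C2"), 1L)
  # missing activation at a recorded threshold is an error naming the config
  rv2 <- rv[1, ]
  rv2$effect_threshold_mA <- 7.5
  expect_error(build_training_samples(rv2, acts, "HDP"), "config C1")
})

test_that("toy activations map onto the stated sample pairs", {
  rv <- data.frame(subject_id = "S01", lead_id = "L", config_id = "C1",
                   effect_threshold_mA = 2, effect_censored = FALSE,
                   side_effect_threshold_mA = NA, side_effect_censored = TRUE,
                   tested = TRUE)
  acts <- data.frame(subject_id = "S01", lead_id = "L", config_id = "C1",
                     amplitude_mA = c(0.5, 2), pathway = "HDP",
                     activation = c(0.01, 0.30))
  s <- build_training_samples(rv, acts, "HDP")
  expect_equal(s$activation, c(0.01, 0.30))
  expect_identical(s$label, c("no_effect", "effect"))
})

test_that("separated data yield a boundary between the classes", {
  s <- data.frame(subject_id = c("A", "A", "B", "B"),
                  lead_id = "L", config_id = "C1", amplitude_mA = 1,
                  pathway = "HDP",
                  activation = c(0.0, 0.05, 0.6, 0.7),
                  label = c("no_effect", "no_effect", "effect", "effect"))
  m <- fit_stim_model(s, reg_grid = 1)
  expect_gt(m$boundary, 0.05)
  expect_lt(m$boundary, 0.6)
  expect_gt(m$beta1, 0)
  # duplicating every sample leaves the boundary unchanged (the ridge term
  # is fixed while the likelihood doubles, so exact invariance needs a weak
  # penalty and overlapping classes with a unique optimum)
  s_mix <- s
  s_mix$activation <- c(0.0, 0.45, 0.35, 0.7)
  m_weak <- fit_stim_model(s_mix, reg_grid = 1e6)
  m2 <- fit_stim_model(rbind(s_mix, s_mix), reg_grid = 1e6)
  expect_equal(m2$boundary, m_weak$boundary, tolerance = 1e-5)
  # single-class input is an error
  expect_error(fit_stim_model(s[s$label == "effect", ], reg_grid = 1),
               "single class")
})

test_that("the fit recovers a known logistic boundary from simulation", {
  set.seed(21)
  n <- 2000
  a <- stats::runif(n)
  y <- stats::rbinom(n, 1, stats::plogis(-6 + 12 * a))
  s <- data.frame(subject_id = sprintf("S%02d", rep(1:10, each = n / 10)),
                  lead_id = "L", config_id = "C1", amplitude_mA = 1,
                  pathway = "HDP", activation = a,
                  label = ifelse(y == 1, "effect", "no_effect"))
  m <- fit_stim_model(s, reg_grid = 1000)   # weak penalty
  expect_equal(m$boundary, 0.5, tolerance = 0.03)
  # and agrees with the unpenalized glm fit
  g <- stats::glm(y ~ a, family = stats::binomial())
  expect_equal(m$boundary, unname(-coef(g)[1] / coef(g)[2]), tolerance = 0.01)
})

test_that("classification and the inverse logistic follow closed forms", {
  m <- structure(list(pathway = "HDP", beta0 = -9.2, beta1 = 18.4,
                      reg_strength = 1, class_cutoff = 0.5,
                      boundary = 0.5), class = "stim_model")
  pred <- predict_class(m, 0.75)
  expect_equal(pred$probability, stats::plogis(4.6), tolerance = 1e-12)
  expect_identical(pred$label, "effect")
  # ties at the boundary classify as effect
  expect_identical(predict_class(m, 0.5)$label, "effect")
  expect_identical(predict_class(m, 0)$label, "no_effect")
  m2 <- structure(list(pathway = "HDP", beta0 = -6, beta1 = 12,
                       reg_strength = 1, class_cutoff = 0.5, boundary = 0.5),
                  class = "stim_model")
  expect_equal(activation_at_probability(m2, 0.99), (4.595 + 6) / 12,
               tolerance = 1e-3)
  expect_equal(activation_at_probability(m2, 0.5), 0.5)
  m2$beta1 <- 0
  expect_error(activation_at_probability(m2, 0.9), "slope")
})

test_that("LOSO folds never leak the held-out subject", {
  co <- small_cohort()
  s <- build_training_samples(co$reviews, co$activations, "HDP")
  cv <- loso_cv(s)
  expect_identical(cv$n_folds, length(unique(s$subject_id)))
  for (f in cv$folds) {
    expect_true(all(f$predictions$subject_id == f$subject_id))
    # refitting without the subject reproduces the fold model
    retrain <- s[s$subject_id != f$subject_id, ]
    m <- fit_stim_model(retrain)
    expect_equal(m$boundary, f$model$boundary)
  }
  expect_true(all(cv$ci95[1] <= cv$mean_accuracy,
                  cv$mean_accuracy <= cv$ci95[2]))
})

test_that("LOSO accuracy tracks the information in the labels", {
  set.seed(23)
  n_per <- 30
  subj <- sprintf("S%02d", rep(1:8, each = n_per))
  a <- stats::runif(8 * n_per)
  # labels independent of activation: accuracy ~ majority class frequency
  y_rand <- stats::rbinom(8 * n_per, 1, 0.7)
  s_rand <- data.frame(subject_id = subj, lead_id = "L", config_id = "C1",
                       amplitude_mA = 1, pathway = "HDP", activation = a,
                       label = ifelse(y_rand == 1, "effect", "no_effect"))
  cv_rand <- suppressWarnings(loso_cv(s_rand, reg_grid = c(0.01, 1)))
  expect_equal(cv_rand$mean_accuracy, 0.7, tolerance = 0.08)
  # noiseless steep ground truth: accuracy > 95%
  y_det <- as.numeric(a > 0.4)
  s_det <- data.frame(subject_id = subj, lead_id = "L", config_id = "C1",
                      amplitude_mA = 1, pathway = "HDP", activation = a,
                      label = ifelse(y_det == 1, "effect", "no_effect"))
  cv_det <- loso_cv(s_det, reg_grid = c(1, 1000))
  expect_gt(cv_det$mean_accuracy, 0.95)
})
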