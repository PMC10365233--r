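test_that("balanced accuracy matches an independently coded formula", {
  expect_equal(balanced_accuracy(list(tp = 7, fn = 3, tn = 8, fp = 2)), 0.75)
  expect_equal(balanced_accuracy(list(tp = 5, fn = 0, tn = 9, fp = 0)), 1.0)
  # an all-positive predictor scores 0.5
  expect_equal(balanced_accuracy(list(tp = 10, fn = 0, tn = 0, fp = 30)), 0.5)
  expect_error(balanced_accuracy(list(tp = 0, fn = 0, tn = 5, fp = 5)),
               "undefined")
  # independent oracle: sensitivity/specificity written out directly
  set.seed(41)
  for (i in 1:200) {
    c4 <- as.list(stats::setNames(sample(0:20, 4, replace = TRUE),
                                  c("tp", "fn", "tn", "fp")))
    if (c4$tp + c4$fn == 0 || c4$tn + c4$fp == 0) next
    sens <- c4$tp / (c4$tp + c4$fn)
    spec <- c4$tn / (c4$tn + c4$fp)
    expect_identical(balanced_accuracy(c4), (sens + spec) / 2)
  }
})

test_that("label vectors expand per-lead labels with one positive per lead", {
  sugg <- data.frame(lead_id = sprintf("L%02d", 1:40),
                     best_level = sample(paste0("L", 1:4), 40, replace = TRUE))
  clin <- data.frame(lead_id = sprintf("L%02d", 1:40),
                     label = sample(paste0("L", 1:4), 40, replace = TRUE))
  lv <- label_vectors(sugg, clin, "level", "best")
  expect_length(lv$suggested, 160)
  expect_identical(sum(lv$clinical), 40)
  expect_identical(sum(lv$suggested), 40)
  # perfect agreement gives balanced accuracy 1
  lv2 <- label_vectors(data.frame(lead_id = clin$lead_id, best_level = clin$label),
                       clin, "level", "best")
  expect_equal(balanced_accuracy(confusion_counts <- tractstim:::confusion_counts(
    lv2$suggested, lv2$clinical)), 1.0)
})

test_that("a 10-lead toy example reproduces the hand-counted accuracy", {
  # 6 of 10 suggestions match the clinical best level
  clin_lab <- paste0("L", rep(1:4, length.out = 10))
  sugg_lab <- clin_lab
  wrong <- c(2, 4, 6, 8)
  sugg_lab[wrong] <- ifelse(clin_lab[wrong] == "L1", "L2", "L1")
  lv <- label_vectors(
    data.frame(lead_id = sprintf("L%02d", 1:10), best_level = sugg_lab),
    data.frame(lead_id = sprintf("L%02d", 1:10), label = clin_lab),
    "level", "best")
  cc <- tractstim:::confusion_counts(lv$suggested, lv$clinical)
  expect_identical(unlist(cc), c(tp = 6L, fn = 4L, tn = 26L, fp = 4L))
  expect_equal(balanced_accuracy(cc), 0.5 * (0.6 + 26 / 30), tolerance = 1e-12)
})

test_that("leads without clinical labels are dropped with a warning", {
  sugg <- data.frame(lead_id = c("A", "B"), best_level = c("L1", "L2"))
  clin <- data.frame(lead_id = c("A", "B"), label = c("L1", NA))
  expect_warning(lv <- label_vectors(sugg, clin, "level", "best"), "dropped")
  expect_length(lv$suggested, 4)
})

test_that("permutation test behaves at the extremes and under seeds", {
  clin <- rep(c(1, 0, 0, 0), 10)
  # perfect suggestion: no shuffle can beat it, only tie at the maximum
  pt <- permutation_test(clin, clin, n_perm = 999, seed = 1)
  expect_equal(pt$observed_statistic, 1.0)
  expect_gte(pt$p_value, 1 / 1000)
  # constant suggested vector is invariant under permutation: p = 1
  pt1 <- permutation_test(rep(1, 40), clin, n_perm = 999, seed = 1)
  expect_equal(pt1$p_value, 1.0)
  # reproducible under seed
  s <- rep(c(0, 1, 0, 0), 10)
  a <- permutation_test(s, clin, n_perm = 500, seed = 9)
  b <- permutation_test(s, clin, n_perm = 500, seed = 9)
  expect_identical(a$p_value, b$p_value)
  # add-one correction keeps p > 0; plain fraction can reach 0
  expect_gt(permutation_test(clin, clin, n_perm = 100, seed = 2)$p_value, 0)
})

test_that("hypergeometric draws match explicit shuffling in distribution", {
  set.seed(43)
  clin <- rep(c(1, 0, 0, 0), 10)
  s <- c(rep(1, 10), rep(0, 30))[sample(40)]
  # explicit shuffle oracle and the exact hypergeometric tail
  n_perm <- 4000
  stats_explicit <- replicate(n_perm, {
    sp <- sample(s)
    balanced_accuracy(tractstim:::confusion_counts(sp, clin))
  })
  pt <- permutation_test(s, clin, n_perm = n_perm, seed = 44)
  obs <- pt$observed_statistic
  p_explicit <- (1 + sum(stats_explicit >= obs - 1e-12)) / (1 + n_perm)
  P <- sum(clin); N <- length(clin) - P; k <- sum(s)
  tp_all <- 0:min(P, k)
  stat_all <- 0.5 * (tp_all / P + (N - (k - tp_all)) / N)
  p_exact <- sum(stats::dhyper(tp_all, P, N, k)[stat_all >= obs - 1e-12])
  mc_sd <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(pt$p_value - p_exact), 4 * mc_sd)
  expect_lt(abs(p_explicit - p_exact), 4 * mc_sd)
})

test_that("threshold errors pair configs and exclude censored pairs", {
  sugg <- data.frame(lead_id = "L", config_id = c("C1", "C2", "C3", "C4"),
                     value = c(3.0, 2.5, 4.0, 5.0),
                     censored = c(FALSE, FALSE, FALSE, TRUE))
  clin <- data.frame(lead_id = "L", config_id = c("C1", "C2", "C3", "C4"),
                     value = c(2.0, 3.0, 4.0, 5.0),
                     censored = FALSE)
  e <- threshold_errors(sugg, clin)
  expect_equal(sort(e$absolute), c(0.0, 0.5, 1.0))
  expect_equal(e$median_abs, 0.5)
  expect_equal(sort(e$signed), c(-0.5, 0.0, 1.0))
  expect_identical(e$n_excluded, 1L)
  # identical thresholds: zero error
  e0 <- threshold_errors(clin, clin)
  expect_equal(e0$median_abs, 0)
  expect_error(threshold_errors(transform(sugg, censored = TRUE), clin),
               "no valid")
})

test_that("contact distances use the lead geometry", {
  lead <- canonical_lead()
  expect_identical(contact_distance("C2", "C3", lead)$same_level, TRUE)
  expect_equal(contact_distance("C2", "C2", lead)$euclidean_mm, 0)
  d25 <- contact_distance("C2", "C5", lead)
  expect_false(d25$same_level)
  # same angular position two levels apart: purely axial 2 mm
  expect_equal(d25$euclidean_mm, 2.0)
  d23 <- contact_distance("C2", "C3", lead)$euclidean_mm
  expect_equal(d23, 0.635 * sqrt(3), tolerance = 1e-9)
})
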