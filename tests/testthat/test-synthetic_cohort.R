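test_that("HDP bundles terminate in the dorsolateral STN and stay short", {
  p <- synthetic_params(n_hdp = 150, seed = 1)
  set.seed(1)
  b <- make_hdp_bundle(p, "S01", "right")
  stn <- tractstim:::stn_geometry(p, "right")
  ends <- t(vapply(b$streamlines, function(s) s[nrow(s), ], numeric(3)))
  expect_true(all(in_stn(ends, stn)))
  # endpoints fall in the dorsolateral sector (45-degree cone)
  d <- sweep(ends, 2, stn$center)
  d <- d / sqrt(rowSums(d * d))
  expect_true(all(d %*% stn$dl >= cos(45 * pi / 180) - 1e-9))
  expect_true(all(streamline_lengths(b) <= 90))
  expect_true(all(b$weights > 0))
  # reproducible under the same RNG state
  set.seed(1)
  b2 <- make_hdp_bundle(p, "S01", "right")
  expect_equal(b$streamlines, b2$streamlines)
})

test_that("CST bundles stay in length bounds and outside the STN", {
  p <- synthetic_params(n_cst = 300, seed = 2)
  set.seed(2)
  b <- make_cst_bundle(p, "S01", "right")
  stn <- tractstim:::stn_geometry(p, "right")
  lens <- streamline_lengths(b)
  expect_true(all(lens >= 80 & lens <= 135))
  pts <- do.call(rbind, b$streamlines)
  expect_false(any(in_stn(pts, stn)))
  # the tube core passes farther from the STN center than the semi-axes
  core_xy <- stn$center[1:2] + c(p$cst_offset_xy[1], p$cst_offset_xy[2])
  expect_gt(sqrt(sum((core_xy - stn$center[1:2])^2)), max(stn$semiaxes))
  # left hemisphere mirrors x
  set.seed(2)
  bl <- make_cst_bundle(p, "S01", "left")
  expect_lt(max(do.call(rbind, bl$streamlines)[, 1]), 0)
})

test_that("leads are placed near the dorsolateral border with bounded tilt", {
  p <- synthetic_params(seed = 3)
  stn <- tractstim:::stn_geometry(p, "right")
  set.seed(3)
  for (i in 1:20) {
    lead <- place_lead(p, "right")
    anchor <- lead$tip + 2.75 * lead$axis
    expect_lt(sqrt(sum((anchor - stn$border)^2)),
              1.2 + 4 * p$placement_sigma_mm)
    tilt <- acos(sum(lead$axis * tractstim:::unit3(p$lead_axis))) * 180 / pi
    expect_lte(tilt, p$tilt_max_deg + 1e-6)
  }
  set.seed(99)
  l1 <- place_lead(p, "left")
  set.seed(99)
  l2 <- place_lead(p, "left")
  expect_equal(l1$tip, l2$tip)
})

test_that("noiseless reviews equal the ground-truth thresholds", {
  p <- synthetic_params(n_subjects = 1, leads_per_subject = 1, n_hdp = 150,
                        n_cst = 400, p_noise = 0, tested_fraction = 1,
                        seed = 4)
  co <- generate_cohort(p, keep_bundles = FALSE)
  rv <- co$reviews
  tt <- co$truth$thresholds
  expect_true(all(rv$tested))
  expect_identical(rv$side_effect_threshold_mA, tt$true_side_effect_threshold_mA)
  expect_identical(rv$side_effect_censored, tt$true_side_effect_censored)
  # effect thresholds match except where the sweep aborted on side effects
  aborted <- rv$effect_censored & !tt$true_effect_censored
  expect_true(all(tt$true_side_effect_threshold_mA[aborted] <
                  tt$true_effect_threshold_mA[aborted] |
                  tt$true_effect_censored[aborted]))
  same <- !aborted
  expect_identical(rv$effect_threshold_mA[same],
                   tt$true_effect_threshold_mA[same])
})

test_that("bundles far from the lead censor every threshold", {
  p <- synthetic_params(n_hdp = 20, n_cst = 20, p_noise = 0,
                        tested_fraction = 1, seed = 5)
  set.seed(5)
  bundles <- list(HDP = make_hdp_bundle(p, "S01", "right"),
                  CST = make_cst_bundle(p, "S01", "right"))
  far <- lapply(bundles, function(b)
    tract_bundle(lapply(b$streamlines, function(s) s + 500),
                 b$weights, b$name, b$hemisphere))
  lead <- place_lead(p, "right")
  sim <- simulate_review(lead, far, true_models(p), p, "S01", "S01_R")
  expect_true(all(sim$records$effect_censored))
  expect_true(all(sim$records$side_effect_censored))
  expect_true(all(sim$activations$activation == 0))
})

test_that("cohorts have the declared structure and stay on the grid", {
  co <- small_cohort()
  p <- co$params
  expect_identical(nrow(co$leads),
                   as.integer(p$n_subjects * p$leads_per_subject))
  expect_identical(length(unique(co$reviews$lead_id)), nrow(co$leads))
  rv <- co$reviews
  grid <- seq(1, 8, 0.5)
  ok_e <- !is.na(rv$effect_threshold_mA)
  expect_true(all(rv$effect_threshold_mA[ok_e] %in% grid))
  ok_s <- !is.na(rv$side_effect_threshold_mA)
  expect_true(all(rv$side_effect_threshold_mA[ok_s] %in% grid))
  # untested rows carry no thresholds
  expect_true(all(is.na(rv$effect_threshold_mA[!rv$tested])))
  # activation profiles are non-decreasing for every lead/config/pathway
  a <- co$activations
  for (key in split(a, paste(a$lead_id, a$config_id, a$pathway))) {
    key <- key[order(key$amplitude_mA), ]
    expect_true(all(diff(key$activation) >= -1e-12))
  }
  # regeneration under the same seed is identical
  co2 <- generate_cohort(p, keep_bundles = FALSE)
  expect_equal(co2$reviews, co$reviews)
  expect_equal(co2$activations$activation, co$activations$activation)
})

test_that("written cohorts round-trip through the file formats", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  rv <- read_reviews(file.path(dir, "reviews.csv"))
  expect_equal(rv, co$reviews, ignore_attr = TRUE)
  poses <- read_lead_poses(file.path(dir, "leads.csv"))
  expect_equal(poses$tip_x, co$leads$tip_x, tolerance = 1e-9)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(truth$models$HDP$boundary, co$params$a50_hdp)
})
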