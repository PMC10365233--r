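# Fully synthetic cohort with the statistical structure the analysis
# assumes: an ellipsoidal STN per hemisphere, an HDP bundle converging from
# a motor-cortex disc onto the dorsolateral STN sector, a CST tube
# descending posterolateral to the STN through the internal-capsule region,
# directional leads targeted at the dorsolateral STN border, and monopolar
# reviews simulated from known ground-truth logistic stimulation models.
#
# All coordinates are world mm in a right-handed space resembling MNI
# (x lateral, y anterior, z superior); the left hemisphere mirrors x.

#' Parameters of the synthetic cohort generator
#'
#' Defaults define the emulated study conditions: 20 subjects with bilateral
#' leads, 500 HDP / 2000 CST streamlines per hemisphere with heavy-tailed
#' log-normal weights, 1 mm lead placement jitter about the dorsolateral STN
#' border with up to 10 degrees of axis tilt, ground-truth activation
#' boundaries of 0.10 (HDP) and 0.01 (CST), one-grid-step threshold noise
#' with probability 0.2, and 60.8% of directional contacts tested.
#'
#' @param n_subjects Number of subjects.
#' @param leads_per_subject 1 (right only) or 2 (bilateral).
#' @param n_hdp,n_cst Streamlines per HDP / CST bundle.
#' @param weight_meanlog,weight_sdlog Log-normal streamline weight
#'   parameters.
#' @param stn_center Right-hemisphere STN ellipsoid center (mm; x mirrored
#'   for the left).
#' @param stn_semiaxes STN ellipsoid semi-axes (mm).
#' @param dorsolateral_dir Dorsolateral pole direction (right hemisphere).
#' @param dorsolateral_half_angle_deg Half-angle of the dorsolateral sector
#'   cone.
#' @param lead_axis Canonical distal-to-proximal lead axis (right
#'   hemisphere).
#' @param placement_sigma_mm Isotropic Gaussian jitter of the lead anchor.
#' @param tilt_max_deg Maximum axis tilt from the canonical trajectory.
#' @param a50_hdp,a50_cst Ground-truth activation boundaries (activation at
#'   50% outcome probability).
#' @param beta1_hdp,beta1_cst Ground-truth logistic slopes.
#' @param p_noise Probability that an observed threshold is jittered by one
#'   0.5 mA grid step.
#' @param tested_fraction Fraction of directional contacts tested.
#' @param hdp_start_center,hdp_start_radius Source disc of HDP streamlines.
#' @param cst_offset_xy Horizontal offset of the CST tube core from the STN
#'   center (x mirrored for the left hemisphere).
#' @param cst_radius_mm CST tube radius.
#' @param cst_z_range Superior/inferior extent of the CST tube.
#' @param vta VTA kernel parameters used when simulating reviews.
#' @param seed RNG seed for [generate_cohort()].
#' @return Object of class `synthetic_params`.
#' @export
synthetic_params <- function(n_subjects = 20, leads_per_subject = 2,
                             n_hdp = 500, n_cst = 2000,
                             weight_meanlog = 0, weight_sdlog = 0.8,
                             stn_center = c(12, -13, -7),
                             stn_semiaxes = c(5, 3, 3),
                             dorsolateral_dir = c(1, 0, 1),
                             dorsolateral_half_angle_deg = 45,
                             lead_axis = c(0.3, 0, 0.95),
                             placement_sigma_mm = 1.0,
                             tilt_max_deg = 10,
                             a50_hdp = 0.10, a50_cst = 0.01,
                             beta1_hdp = 60, beta1_cst = 600,
                             p_noise = 0.2, tested_fraction = 0.608,
                             hdp_start_center = c(30, -18, 55),
                             hdp_start_radius = 8,
                             cst_offset_xy = c(4.5, -4.2),
                             cst_radius_mm = 2.0,
                             cst_z_range = c(45, -45),
                             vta = vta_params(),
                             seed = 42) {
  stopifnot(n_subjects >= 1, leads_per_subject %in% 1:2,
            n_hdp >= 1, n_cst >= 1, weight_sdlog > 0,
            all(stn_semiaxes > 0), placement_sigma_mm > 0,
            a50_hdp > 0, a50_cst > 0, beta1_hdp > 0, beta1_cst > 0,
            p_noise >= 0, p_noise <= 1,
            tested_fraction > 0, tested_fraction <= 1)
  p <- as.list(environment())
  p$dorsolateral_dir <- unit3(dorsolateral_dir)
  p$lead_axis <- unit3(lead_axis)
  structure(p, class = "synthetic_params")
}

#' Ground-truth stimulation models of a parameter set
#'
#' @param params A [synthetic_params()].
#' @return Named list of `stim_model`s (`HDP`, `CST`) with
#'   `beta0 = -beta1 * a50`.
#' @export
true_models <- function(params) {
  mk <- function(pathway, a50, beta1)
    structure(list(pathway = pathway, beta0 = -beta1 * a50, beta1 = beta1,
                   reg_strength = NA_real_, class_cutoff = 0.5,
                   boundary = a50),
              class = "stim_model")
  list(HDP = mk("HDP", params$a50_hdp, params$beta1_hdp),
       CST = mk("CST", params$a50_cst, params$beta1_cst))
}

hemi_sign <- function(hemisphere) if (hemisphere == "left") -1 else 1

mirror_x <- function(v, s) c(s * v[1], v[2], v[3])

# Radius of the ellipsoid along unit direction d.
ellipsoid_radius <- function(d, semiaxes) 1 / sqrt(sum((d / semiaxes)^2))

stn_geometry <- function(params, hemisphere) {
  s <- hemi_sign(hemisphere)
  center <- mirror_x(params$stn_center, s)
  dl <- unit3(mirror_x(params$dorsolateral_dir, s))
  border <- center + dl * ellipsoid_radius(dl, params$stn_semiaxes)
  list(center = center, semiaxes = params$stn_semiaxes, dl = dl,
       border = border, sign = s)
}

#' Is a point inside the synthetic STN ellipsoid?
#'
#' @param points Matrix (n x 3) or length-3 vector.
#' @param stn STN geometry (list with `center`, `semiaxes`).
#' @return Logical vector.
#' @export
in_stn <- function(points, stn) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  q <- sweep(points, 2, stn$center)
  q <- sweep(q, 2, stn$semiaxes, "/")
  rowSums(q * q) <= 1
}

# Uniform unit vectors within a cone of half-angle `half_deg` about `axis`.
cone_dirs <- function(n, axis, half_deg) {
  cos_min <- cos(half_deg * pi / 180)
  u <- stats::runif(n, cos_min, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  sin_t <- sqrt(pmax(0, 1 - u^2))
  basis <- lead_basis(axis)
  t(vapply(seq_len(n), function(i)
    u[i] * axis + sin_t[i] * (cos(phi[i]) * basis$u + sin(phi[i]) * basis$v),
    numeric(3)))
}

# Cubic Bezier curves for all streamlines at once; P0..P3 are n x 3.
bezier_points <- function(P0, P1, P2, P3, m) {
  t <- seq(0, 1, length.out = m)
  basis <- cbind((1 - t)^3, 3 * t * (1 - t)^2, 3 * t^2 * (1 - t), t^3)
  coords <- lapply(1:3, function(k)
    basis %*% rbind(P0[, k], P1[, k], P2[, k], P3[, k]))
  n <- nrow(P0)
  lapply(seq_len(n), function(i)
    cbind(coords[[1]][, i], coords[[2]][, i], coords[[3]][, i]))
}

#' Generate a synthetic hyperdirect-pathway bundle
#'
#' Smooth streamlines descend from a motor-cortex source disc and converge
#' onto the dorsolateral sector of the STN ellipsoid, approaching it from
#' the dorsolateral side. All endpoints lie inside the STN; lengths are at
#' most 90 mm. Weights are log-normal. Uses the current RNG state.
#'
#' @param params A [synthetic_params()].
#' @param subject Subject id (label only).
#' @param hemisphere "right" or "left".
#' @return A [tract_bundle()] named "HDP".
#' @export
make_hdp_bundle <- function(params, subject = "S01",
                            hemisphere = c("right", "left")) {
  hemisphere <- match.arg(hemisphere)
  stn <- stn_geometry(params, hemisphere)
  n <- params$n_hdp
  dirs <- cone_dirs(n, stn$dl, params$dorsolateral_half_angle_deg)
  rad <- stats::runif(n, 0.2, 0.95) *
    apply(dirs, 1, ellipsoid_radius, semiaxes = stn$semiaxes)
  ends <- sweep(dirs * rad, 2, stn$center, "+")
  sc <- mirror_x(params$hdp_start_center, stn$sign)
  ang <- stats::runif(n, 0, 2 * pi)
  rr <- params$hdp_start_radius * sqrt(stats::runif(n))
  starts <- cbind(sc[1] + rr * cos(ang), sc[2] + rr * sin(ang),
                  sc[3] + stats::runif(n, -5, 5))
  approach <- unit3(stn$dl + c(0, 0, 0.8))
  P1 <- starts + matrix(rep(c(0, 0, -18), each = n), n)
  # fan the approach control points so the funnel near the STN border has a
  # realistic few-mm width rather than collapsing onto a single line
  P2 <- ends + matrix(rep(approach * 14, each = n), n) +
    matrix(stats::rnorm(3 * n, 0, 4), n)
  streams <- bezier_points(starts, P1, P2, ends, m = 80)
  # straighten any over-long paths toward the chord (keeps endpoints fixed)
  for (i in seq_len(n)) {
    for (rep_i in 1:5) {
      d <- diff(streams[[i]])
      if (sum(sqrt(rowSums(d * d))) <= 90) break
      chord <- bezier_points(starts[i, , drop = FALSE],
                             starts[i, , drop = FALSE],
                             ends[i, , drop = FALSE],
                             ends[i, , drop = FALSE], m = 80)[[1]]
      streams[[i]] <- (streams[[i]] + chord) / 2
    }
  }
  tract_bundle(streams,
               weights = stats::rlnorm(n, params$weight_meanlog,
                                       params$weight_sdlog),
               name = "HDP", hemisphere = hemisphere)
}

#' Generate a synthetic corticospinal-tract bundle
#'
#' A near-parallel tube of descending streamlines passing posterolateral to
#' the STN through the internal-capsule region, never entering the STN
#' ellipsoid. Lengths lie in [80, 135] mm; weights are log-normal. Uses the
#' current RNG state.
#'
#' @inheritParams make_hdp_bundle
#' @return A [tract_bundle()] named "CST".
#' @export
make_cst_bundle <- function(params, subject = "S01",
                            hemisphere = c("right", "left")) {
  hemisphere <- match.arg(hemisphere)
  stn <- stn_geometry(params, hemisphere)
  n <- params$n_cst
  core_xy <- stn$center[1:2] + c(stn$sign * params$cst_offset_xy[1],
                                 params$cst_offset_xy[2])
  ang <- stats::runif(n, 0, 2 * pi)
  rr <- params$cst_radius_mm * sqrt(stats::runif(n))
  off_x <- rr * cos(ang)
  off_y <- rr * sin(ang)
  tilt_x <- stats::runif(n, -0.005, 0.005)   # rad; keeps the tube off the STN
  tilt_y <- stats::runif(n, -0.005, 0.005)
  z <- seq(params$cst_z_range[1], params$cst_z_range[2], by = -1)
  m <- length(z)
  dz <- z - mean(z)
  streams <- lapply(seq_len(n), function(i)
    cbind(core_xy[1] + off_x[i] + tilt_x[i] * dz,
          core_xy[2] + off_y[i] + tilt_y[i] * dz,
          z))
  tract_bundle(streams,
               weights = stats::rlnorm(n, params$weight_meanlog,
                                       params$weight_sdlog),
               name = "CST", hemisphere = hemisphere)
}

#' Place a synthetic lead at the dorsolateral STN border
#'
#' The level-2 centroid is anchored at the dorsolateral border point with
#' isotropic Gaussian jitter; the axis is tilted from the canonical
#' trajectory by a random angle up to `tilt_max_deg`, and the marker
#' rotation is uniform. Uses the current RNG state.
#'
#' @param params A [synthetic_params()].
#' @param hemisphere "right" or "left".
#' @return A [lead_model()].
#' @export
place_lead <- function(params, hemisphere = c("right", "left")) {
  hemisphere <- match.arg(hemisphere)
  stn <- stn_geometry(params, hemisphere)
  axis0 <- unit3(mirror_x(params$lead_axis, stn$sign))
  theta <- stats::runif(1, 0, params$tilt_max_deg) * pi / 180
  phi <- stats::runif(1, 0, 2 * pi)
  basis <- lead_basis(axis0)
  axis <- unit3(cos(theta) * axis0 +
                sin(theta) * (cos(phi) * basis$u + sin(phi) * basis$v))
  # implantation depth varies by more than the transverse targeting error:
  # the level closest to the dorsolateral border ranges over the array
  depth <- stats::runif(1, -2, 2)
  anchor <- stn$border + 1.2 * stn$dl + depth * axis +
    stats::rnorm(3, 0, params$placement_sigma_mm)
  tip <- anchor - 2.75 * axis   # level-2 centroid sits at the anchor
  lead_model(tip, axis, rotation = stats::runif(1, 0, 2 * pi))
}

noisy_threshold <- function(true_thr, censored, p_noise) {
  if (censored) return(list(value = NA_real_, censored = TRUE))
  v <- true_thr
  if (stats::runif(1) < p_noise)
    v <- v + sample(c(-0.5, 0.5), 1)
  if (v > 8) return(list(value = NA_real_, censored = TRUE))
  list(value = max(v, 1), censored = FALSE)
}

first_crossing <- function(profile, boundary, grid = suggestion_grid()) {
  prof <- profile[profile$amplitude_mA %in% grid, ]
  prof <- prof[order(prof$amplitude_mA), ]
  hit <- which(prof$activation >= boundary)
  if (!length(hit)) list(value = NA_real_, censored = TRUE)
  else list(value = prof$amplitude_mA[hit[1]], censored = FALSE)
}

#' Simulate a monopolar review for one lead
#'
#' For each physical configuration the true effect (side-effect) threshold
#' is the first grid amplitude whose HDP (CST) activation reaches the
#' ground-truth model's 50% boundary. Observed thresholds jitter by one
#' grid step with probability `p_noise` and are censored beyond 8 mA. If
#' side effects occur before full effect the sweep aborts and the effect
#' threshold is censored. Directional contacts are untested with
#' probability `1 - tested_fraction`. Uses the current RNG state.
#'
#' @param lead A [lead_model()].
#' @param bundles Named list with `HDP` and `CST` [tract_bundle()]s of the
#'   lead's hemisphere.
#' @param models Ground-truth `stim_model`s (see [true_models()]).
#' @param params A [synthetic_params()].
#' @param subject_id,lead_id Identifiers for the emitted records.
#' @return List with `records` (review rows), `truth` (noiseless
#'   thresholds) and `activations` (the activation table used).
#' @export
simulate_review <- function(lead, bundles, models, params,
                            subject_id = "S01", lead_id = "S01_R") {
  configs <- review_configs()
  acts <- list()
  records <- list()
  truth <- list()
  for (cfg in configs) {
    prof_hdp <- activation_profile(bundles$HDP, lead, cfg,
                                   amplitude_grid(), params$vta)
    prof_cst <- activation_profile(bundles$CST, lead, cfg,
                                   amplitude_grid(), params$vta)
    acts[[cfg]] <- rbind(
      data.frame(subject_id = subject_id, lead_id = lead_id, config_id = cfg,
                 amplitude_mA = prof_hdp$amplitude_mA, pathway = "HDP",
                 activation = prof_hdp$activation),
      data.frame(subject_id = subject_id, lead_id = lead_id, config_id = cfg,
                 amplitude_mA = prof_cst$amplitude_mA, pathway = "CST",
                 activation = prof_cst$activation))
    true_eff <- first_crossing(prof_hdp, models$HDP$boundary)
    true_se <- first_crossing(prof_cst, models$CST$boundary)
    tested <- if (cfg %in% c("C2", "C3", "C4", "C5", "C6", "C7"))
      stats::runif(1) < params$tested_fraction else TRUE
    obs_eff <- noisy_threshold(true_eff$value, true_eff$censored, params$p_noise)
    obs_se <- noisy_threshold(true_se$value, true_se$censored, params$p_noise)
    # sweep aborts once persistent side effects precede full effect
    if (!obs_se$censored && (obs_eff$censored ||
                             obs_se$value < obs_eff$value))
      obs_eff <- list(value = NA_real_, censored = TRUE)
    if (!tested) {
      obs_eff <- list(value = NA_real_, censored = FALSE)
      obs_se <- list(value = NA_real_, censored = FALSE)
    }
    records[[cfg]] <- data.frame(
      subject_id = subject_id, lead_id = lead_id, config_id = cfg,
      effect_threshold_mA = obs_eff$value, effect_censored = obs_eff$censored,
      side_effect_threshold_mA = obs_se$value,
      side_effect_censored = obs_se$censored, tested = tested)
    truth[[cfg]] <- data.frame(
      subject_id = subject_id, lead_id = lead_id, config_id = cfg,
      true_effect_threshold_mA = true_eff$value,
      true_effect_censored = true_eff$censored,
      true_side_effect_threshold_mA = true_se$value,
      true_side_effect_censored = true_se$censored)
  }
  list(records = do.call(rbind, records),
       truth = do.call(rbind, truth),
       activations = do.call(rbind, acts))
}

#' Generate a full synthetic cohort
#'
#' Deterministic under `params$seed`: bundles, lead poses, monopolar-review
#' records, the activation table and the generating ground truth.
#'
#' @param params A [synthetic_params()].
#' @param keep_bundles Keep the streamline bundles in the returned object
#'   (set `FALSE` to save memory when only the tables are needed).
#' @return Object of class `synthetic_cohort` with elements `params`,
#'   `bundles`, `leads`, `reviews`, `activations`, `truth` (models and
#'   noiseless thresholds).
#' @export
generate_cohort <- function(params = synthetic_params(), keep_bundles = TRUE) {
  set.seed(params$seed)
  models <- true_models(params)
  hemis <- if (params$leads_per_subject == 2) c("right", "left") else "right"
  subjects <- sprintf("S%02d", seq_len(params$n_subjects))
  bundles <- list()
  leads <- list()
  reviews <- list()
  truth <- list()
  acts <- list()
  for (s in subjects) {
    bundles[[s]] <- list()
    for (h in hemis) {
      b <- list(HDP = make_hdp_bundle(params, s, h),
                CST = make_cst_bundle(params, s, h))
      lead <- place_lead(params, h)
      lead_id <- paste0(s, "_", toupper(substr(h, 1, 1)))
      sim <- simulate_review(lead, b, models, params, s, lead_id)
      leads[[lead_id]] <- data.frame(
        subject_id = s, lead_id = lead_id, hemisphere = h,
        tip_x = lead$tip[1], tip_y = lead$tip[2], tip_z = lead$tip[3],
        axis_x = lead$axis[1], axis_y = lead$axis[2], axis_z = lead$axis[3],
        rotation_rad = lead$rotation)
      reviews[[lead_id]] <- sim$records
      truth[[lead_id]] <- sim$truth
      acts[[lead_id]] <- sim$activations
      if (keep_bundles) bundles[[s]][[h]] <- b
    }
  }
  structure(
    list(params = params,
         bundles = if (keep_bundles) bundles,
         leads = do.call(rbind, c(leads, list(make.row.names = FALSE))),
         reviews = do.call(rbind, c(reviews, list(make.row.names = FALSE))),
         activations = do.call(rbind, c(acts, list(make.row.names = FALSE))),
         truth = list(models = models,
                      thresholds = do.call(rbind, c(truth, list(make.row.names = FALSE))))),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d leads, %d review rows (seed %d)\n",
              length(unique(x$leads$subject_id)), nrow(x$leads),
              nrow(x$reviews), x$params$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the review CSV, lead-pose CSV, ground-truth JSON and (optionally)
#' per-bundle TCK + weight files, the inputs the rest of the pipeline
#' consumes.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @param write_bundles Also write TCK bundles and weight files.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_bundles = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_reviews(cohort$reviews, file.path(dir, "reviews.csv"))
  write_lead_poses(cohort$leads, file.path(dir, "leads.csv"))
  utils::write.csv(cohort$activations, file.path(dir, "activations.csv"),
                   row.names = FALSE)
  truth <- list(
    models = lapply(cohort$truth$models, function(m)
      list(pathway = m$pathway, beta0 = m$beta0, beta1 = m$beta1,
           boundary = m$boundary)),
    thresholds = cohort$truth$thresholds)
  write_report(truth, file.path(dir, "ground_truth.json"))
  if (write_bundles && !is.null(cohort$bundles)) {
    for (s in names(cohort$bundles)) {
      for (h in names(cohort$bundles[[s]])) {
        for (pw in names(cohort$bundles[[s]][[h]])) {
          b <- cohort$bundles[[s]][[h]][[pw]]
          stem <- file.path(dir, sprintf("%s_%s_%s", s, h, tolower(pw)))
          write_tck(b, paste0(stem, ".tck"))
          write_weights(b$weights, paste0(stem, "_weights.txt"))
        }
      }
    }
  }
  invisible(dir)
}
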