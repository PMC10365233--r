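# Shared fixtures. Cohorts are cached per session because several test
# files exercise the same study conditions.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, value_fn) {
  if (is.null(.cohort_cache[[key]])) .cohort_cache[[key]] <- value_fn()
  .cohort_cache[[key]]
}

# Default study conditions (noisy), fixed seed.
default_cohort <- function() {
  cached("default", function() generate_cohort(synthetic_params(seed = 42),
                                               keep_bundles = FALSE))
}

# Same conditions without threshold noise.
noiseless_cohort <- function() {
  cached("noiseless", function()
    generate_cohort(synthetic_params(p_noise = 0, seed = 43),
                    keep_bundles = FALSE))
}

# Reduced cohort for module-level tests that only need the structure.
small_cohort <- function() {
  cached("small", function()
    generate_cohort(synthetic_params(n_subjects = 4, n_hdp = 120,
                                     n_cst = 400, seed = 7),
                    keep_bundles = FALSE))
}

cohort_cv <- function(cohort, key) {
  cached(paste0("cv_", key), function() {
    lapply(stats::setNames(c("HDP", "CST"), c("HDP", "CST")), function(pw)
      suppressWarnings(loso_cv(
        build_training_samples(cohort$reviews, cohort$activations, pw))))
  })
}

canonical_lead <- function() lead_model(c(0, 0, 0), c(0, 0, 1), rotation = 0)

# A small random polyline wandering near the origin.
random_streamline <- function(n_pts = 8, scale = 2) {
  start <- stats::rnorm(3, 0, scale)
  steps <- matrix(stats::rnorm(3 * (n_pts - 1), 0, scale / 3), n_pts - 1)
  apply(rbind(start, steps), 2, cumsum)
}

# Dense-resampling vertex oracle for streamline/VTA intersection.
oracle_hits <- function(streamline, vta, step = 0.01) {
  D <- diff(streamline)
  len <- sqrt(rowSums(D * D))
  npts <- pmax(2L, ceiling(len / step) + 1L)
  row <- rep.int(seq_along(len), npts)
  t <- (sequence(npts) - 1) / (npts[row] - 1)
  P <- streamline[row, , drop = FALSE] + D[row, , drop = FALSE] * t
  for (i in seq_len(nrow(P))) if (point_in_vta(P[i, ], vta)) return(TRUE)
  FALSE
}
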