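# Weighted pathway activation inside VTAs. "Inside" means the streamline
# polyline intersects the VTA (segment intersection, not vertex membership).
# For a fixed source geometry (center, optional sector) the hit condition is
# monotone in radius, so each streamline has a critical radius: the smallest
# sphere radius at which it is hit. Activation profiles over the amplitude
# grid are then simple thresholdings of the critical radii, which makes
# nesting/monotonicity structural.

# Squared distance from point `center` to every segment (A[i,], B[i,]).
segment_dist2 <- function(A, B, center) {
  D <- B - A
  W <- sweep(A, 2, center)
  dd <- rowSums(D * D)
  t <- -rowSums(W * D) / pmax(dd, 1e-300)
  t <- pmin(pmax(t, 0), 1)
  Q <- W + D * t
  rowSums(Q * Q)
}

min_by_group <- function(x, g, n_groups) {
  out <- rep(Inf, n_groups)
  if (length(x)) {
    agg <- vapply(split(x, factor(g, levels = seq_len(n_groups))),
                  function(v) if (length(v)) min(v) else Inf, 0)
    out <- unname(agg)
  }
  out
}

# Per-streamline critical radius for a spherical (or sector) source at
# `center`. Sphere sources use the exact point-to-segment distance. Sector
# sources restrict to points within the angular sector; segments that come
# within `r_max` are densified at `step` mm and the minimum distance over
# in-sector sample points is taken. Radii above r_max are reported as Inf.
critical_radii <- function(segs, center, sector = NULL, r_max = Inf,
                           step = 0.05) {
  d2 <- segment_dist2(segs$A, segs$B, center)
  if (is.null(sector)) {
    rc <- sqrt(min_by_group(d2, segs$sid, segs$n_streamlines))
    rc[rc > r_max] <- Inf
    return(rc)
  }
  if (!is.finite(r_max))
    stop("sector critical radii require a finite r_max")
  cand <- which(d2 <= r_max^2)
  if (!length(cand)) return(rep(Inf, segs$n_streamlines))
  A <- segs$A[cand, , drop = FALSE]
  B <- segs$B[cand, , drop = FALSE]
  D <- B - A
  len <- sqrt(rowSums(D * D))
  npts <- pmax(2L, ceiling(len / step) + 1L)
  row <- rep.int(seq_along(cand), npts)
  pos <- sequence(npts)
  t <- (pos - 1) / (npts[row] - 1)
  P <- A[row, , drop = FALSE] + D[row, , drop = FALSE] * t
  W <- sweep(P, 2, center)
  r <- sqrt(rowSums(W * W))
  cos_half <- cos(sector$width_deg / 2 * pi / 180)
  ok <- r <= r_max & (r < 1e-12 |
                      (W %*% sector$axis_out) / pmax(r, 1e-12) >= cos_half - 1e-12)
  sid_pts <- segs$sid[cand][row]
  min_by_group(r[ok], sid_pts[ok], segs$n_streamlines)
}

densify_polyline <- function(points, step) {
  D <- diff(points)
  len <- sqrt(rowSums(D * D))
  npts <- pmax(2L, ceiling(len / step) + 1L)
  row <- rep.int(seq_along(len), npts)
  t <- (sequence(npts) - 1) / (npts[row] - 1)
  points[row, , drop = FALSE] + D[row, , drop = FALSE] * t
}

#' Does a streamline intersect a VTA?
#'
#' Uses segment intersection, not vertex membership: a straight segment
#' whose endpoints straddle the VTA still hits it. Analytic sphere VTAs use
#' the exact point-to-segment distance; sector VTAs additionally require an
#' in-sector point on the clipped segment (sampled at `step` mm). Mask VTAs
#' densify the polyline to at most half the voxel size and vertex-test.
#'
#' @param streamline Streamline matrix (n x 3, mm).
#' @param vta A `vta` object.
#' @param step Sampling step in mm for sector and mask tests.
#' @return Logical.
#' @export
streamline_hits_vta <- function(streamline, vta, step = 0.01) {
  validate_streamline(streamline)
  if (vta$type == "analytic") {
    segs <- bundle_segments(list(streamline))
    rc <- critical_radii(segs, vta$center, vta$sector,
                         r_max = vta$radius, step = step)
    is.finite(rc[1]) && rc[1] <= vta$radius + 1e-12
  } else {
    vox <- min(abs(diag(vta$affine)[1:3]))
    P <- densify_polyline(streamline, step = vox / 2)
    H <- solve(vta$affine, rbind(t(P), 1))[1:3, , drop = FALSE]
    idx <- round(t(H)) + 1L
    dm <- dim(vta$grid)
    ok <- idx[, 1] >= 1L & idx[, 1] <= dm[1] &
          idx[, 2] >= 1L & idx[, 2] <= dm[2] &
          idx[, 3] >= 1L & idx[, 3] <= dm[3]
    if (!any(ok)) return(FALSE)
    any(vta$grid[idx[ok, , drop = FALSE]] > 0.5)
  }
}

#' Weighted activation fraction of a bundle inside a VTA
#'
#' The sum of the weights of the streamlines intersecting the VTA divided by
#' the bundle's total weight.
#'
#' @param bundle A [tract_bundle()].
#' @param vta A `vta` object.
#' @param step Sampling step in mm for sector and mask tests.
#' @return Fraction in `[0, 1]`.
#' @export
activation_fraction <- function(bundle, vta, step = 0.05) {
  if (!inherits(bundle, "tract_bundle")) stop("bundle must be a tract_bundle")
  if (vta$type == "analytic") {
    rc <- critical_radii(bundle$segments, vta$center, vta$sector,
                         r_max = vta$radius, step = step)
    hits <- is.finite(rc) & rc <= vta$radius + 1e-12
  } else {
    hits <- vapply(bundle$streamlines, streamline_hits_vta, TRUE, vta = vta)
  }
  sum(bundle$weights[hits]) / bundle$total_weight
}

#' Activation profile of a bundle over an amplitude grid
#'
#' Activation fraction at each amplitude for one stimulation configuration.
#' Values are non-decreasing in amplitude (VTAs are nested).
#'
#' @param bundle A [tract_bundle()].
#' @param lead A [lead_model()].
#' @param config_id Configuration token (C1-C8, L1-L4).
#' @param amplitudes Amplitude grid in mA (subset of 0.5-8 by 0.5).
#' @param params A [vta_params()].
#' @param step Sampling step in mm for sector sources.
#' @return Data frame with columns `amplitude_mA` and `activation`.
#' @export
activation_profile <- function(bundle, lead, config_id,
                               amplitudes = amplitude_grid(),
                               params = vta_params(), step = 0.05) {
  amplitudes <- sort(unique(amplitudes))
  frame <- config_frame(lead, config_id, params$radial_offset_fraction)
  sector <- if (frame$kind == "segment")
    list(axis_out = frame$outward, width_deg = params$sector_width_deg)
  radii <- vta_radius_point_source(amplitudes, params)
  rc <- critical_radii(bundle$segments, frame$center, sector,
                       r_max = max(radii) + 1e-9, step = step)
  act <- vapply(radii, function(r)
    sum(bundle$weights[rc <= r + 1e-12]) / bundle$total_weight, 0)
  data.frame(amplitude_mA = amplitudes, activation = act)
}

#' Activation table for a set of leads and bundles
#'
#' Computes activation profiles for every lead, configuration and pathway.
#' Activation is computed against the bundle on the lead's hemisphere;
#' cross-hemisphere activation is 0 and is not tabulated.
#'
#' @param bundles Nested list: `bundles[[subject_id]][[hemisphere]]` is a
#'   named list of `tract_bundle`s (e.g. `list(HDP = ..., CST = ...)`).
#' @param leads Lead pose data frame (see [read_lead_poses()]).
#' @param configs Configuration tokens to tabulate.
#' @param amplitudes Amplitude grid in mA.
#' @param params A [vta_params()].
#' @return Data frame with columns `subject_id`, `lead_id`, `config_id`,
#'   `amplitude_mA`, `pathway`, `activation`.
#' @export
activation_table <- function(bundles, leads, configs = review_configs(),
                             amplitudes = amplitude_grid(),
                             params = vta_params()) {
  out <- vector("list", nrow(leads) * length(configs))
  k <- 0L
  for (i in seq_len(nrow(leads))) {
    lead <- lead_model(tip = c(leads$tip_x[i], leads$tip_y[i], leads$tip_z[i]),
                       axis = c(leads$axis_x[i], leads$axis_y[i], leads$axis_z[i]),
                       rotation = leads$rotation_rad[i])
    subj_bundles <- bundles[[leads$subject_id[i]]][[leads$hemisphere[i]]]
    for (cfg in configs) {
      for (pw in names(subj_bundles)) {
        prof <- activation_profile(subj_bundles[[pw]], lead, cfg,
                                   amplitudes, params)
        k <- k + 1L
        out[[k]] <- data.frame(subject_id = leads$subject_id[i],
                               lead_id = leads$lead_id[i],
                               config_id = cfg,
                               amplitude_mA = prof$amplitude_mA,
                               pathway = pw,
                               activation = prof$activation)
      }
    }
  }
  do.call(rbind, out[seq_len(k)])
}
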