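# Simplified volume-of-tissue-activated (VTA) model. The default kernel is
# the homogeneous point source: a current I in a medium of conductivity
# sigma produces a field E(r) = I / (4 pi sigma r^2); thresholding at E_t
# gives a sphere of radius r = sqrt(I / (4 pi sigma E_t)). Directional
# segments clip the sphere to an angular sector about the contact's outward
# direction.

#' Parameters of the simplified VTA kernel
#'
#' @param sigma Tissue conductivity in S/m (grey-matter default 0.33). The
#'   homogeneous kernel uses a single conductivity; `sigma_white` is accepted
#'   for completeness but unused by the point-source kernel.
#' @param e_threshold Activation threshold of the electric field in V/mm
#'   (default 0.2).
#' @param kernel VTA kernel; only `"point_source"` is implemented.
#' @param sector_width_deg Full angular width of a directional segment's VTA
#'   sector in degrees (default 180: the 120-degree contact span plus spread).
#' @param radial_offset_fraction Radial displacement of segment sources as a
#'   fraction of the lead radius.
#' @param sigma_white White-matter conductivity in S/m; stored, unused.
#' @return Object of class `vta_params`.
#' @export
vta_params <- function(sigma = 0.33, e_threshold = 0.2,
                       kernel = "point_source", sector_width_deg = 180,
                       radial_offset_fraction = 1, sigma_white = 0.14) {
  stopifnot(sigma > 0, e_threshold > 0,
            sector_width_deg > 0, sector_width_deg <= 360)
  kernel <- match.arg(kernel, "point_source")
  structure(list(sigma = sigma, e_threshold = e_threshold, kernel = kernel,
                 sector_width_deg = sector_width_deg,
                 radial_offset_fraction = radial_offset_fraction,
                 sigma_white = sigma_white),
            class = "vta_params")
}

#' Point-source VTA radius
#'
#' Radius (mm) at which the ideal point-source field at `amplitude` mA drops
#' to the activation threshold: `r = sqrt(I / (4 pi sigma E_t))` with I in A,
#' sigma in S/m and E_t in V/m. With I in mA and E_t in V/mm the mm radius
#' simplifies to `sqrt(amplitude / (4 pi sigma e_threshold))`.
#'
#' @param amplitude Stimulation amplitude in mA (vectorized, >= 0).
#' @param params A [vta_params()].
#' @return Radius in mm; 0 at 0 mA, monotone increasing in amplitude.
#' @export
vta_radius_point_source <- function(amplitude, params = vta_params()) {
  if (any(amplitude < 0)) stop("amplitude must be >= 0")
  sqrt(amplitude / (4 * pi * params$sigma * params$e_threshold))
}

#' Construct an analytic (sphere or sector) VTA
#'
#' @param center Sphere center in mm.
#' @param radius Radius in mm (>= 0).
#' @param sector Optional list with `axis_out` (unit vector) and
#'   `width_deg` (full sector width in (0, 360]) restricting the sphere to
#'   an angular sector.
#' @return A `vta` object.
#' @export
vta_sphere <- function(center, radius, sector = NULL) {
  stopifnot(radius >= 0)
  structure(list(type = "analytic", center = as.numeric(center),
                 radius = radius, sector = sector),
            class = "vta")
}

#' Construct a voxel-mask VTA
#'
#' @param grid Logical array; `TRUE` (or values > 0.5) voxels are inside.
#' @param affine 4 x 4 matrix mapping 0-based voxel indices to world mm.
#' @return A `vta` object.
#' @export
vta_mask <- function(grid, affine) {
  structure(list(type = "mask", grid = grid, affine = affine), class = "vta")
}

#' @export
print.vta <- function(x, ...) {
  if (x$type == "analytic") {
    cat(sprintf("<vta> sphere r=%.3f mm at (%.2f, %.2f, %.2f)%s\n",
                x$radius, x$center[1], x$center[2], x$center[3],
                if (!is.null(x$sector))
                  sprintf(", sector %.0f deg", x$sector$width_deg) else ""))
  } else {
    cat(sprintf("<vta> mask %s voxels\n", paste(dim(x$grid), collapse = "x")))
  }
  invisible(x)
}

#' VTA for a stimulation setting
#'
#' Ring contacts (C1, C8) and pseudorings (L2, L3; aliases L1 = C1, L4 = C8)
#' produce a sphere at the level centroid. Directional segments (C2-C7)
#' produce a sphere at the radially offset segment centroid clipped to an
#' angular sector of `params$sector_width_deg` about the outward direction.
#' VTAs at the same configuration are nested in amplitude.
#'
#' @param lead A [lead_model()].
#' @param config_id Configuration token (C1-C8, L1-L4).
#' @param amplitude Amplitude in mA on the 0.5 mA grid.
#' @param params A [vta_params()].
#' @return A `vta` object.
#' @export
vta_for_setting <- function(lead, config_id, amplitude, params = vta_params()) {
  frame <- config_frame(lead, config_id, params$radial_offset_fraction)
  r <- vta_radius_point_source(amplitude, params)
  sector <- if (frame$kind == "segment")
    list(axis_out = frame$outward, width_deg = params$sector_width_deg)
  vta_sphere(frame$center, r, sector)
}

#' Test whether a point lies inside a VTA
#'
#' Analytic VTAs use the distance (and, for sectors, angular) test; mask
#' VTAs transform the point through the inverse affine and look up the
#' nearest voxel.
#'
#' @param point 3-D point in mm.
#' @param vta A `vta` object.
#' @return Logical.
#' @export
point_in_vta <- function(point, vta) {
  point <- as.numeric(point)
  stopifnot(length(point) == 3L, all(is.finite(point)))
  if (vta$type == "analytic") {
    d <- point - vta$center
    r <- sqrt(sum(d * d))
    if (r > vta$radius + 1e-12) return(FALSE)
    if (is.null(vta$sector) || r < 1e-12) return(TRUE)
    cos_half <- cos(vta$sector$width_deg / 2 * pi / 180)
    sum(d * vta$sector$axis_out) / r >= cos_half - 1e-12
  } else {
    v <- solve(vta$affine, c(point, 1))[1:3]
    idx <- round(v) + 1L
    if (any(idx < 1L) || any(idx > dim(vta$grid))) return(FALSE)
    isTRUE(vta$grid[idx[1], idx[2], idx[3]] > 0.5)
  }
}

#' Voxelize an analytic VTA onto a regular grid
#'
#' @param vta Analytic `vta`.
#' @param voxel_size Isotropic voxel edge in mm (default 0.2).
#' @param margin Padding around the sphere in mm.
#' @return A mask `vta` whose affine maps 0-based voxel indices to mm.
#' @export
voxelize_vta <- function(vta, voxel_size = 0.2, margin = 0.5) {
  stopifnot(vta$type == "analytic")
  lo <- vta$center - vta$radius - margin
  hi <- vta$center + vta$radius + margin
  n <- pmax(1L, ceiling((hi - lo) / voxel_size)) + 1L
  ax <- lapply(1:3, function(k) lo[k] + voxel_size * (seq_len(n[k]) - 1L))
  coords <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  d <- sweep(coords, 2, vta$center)
  r <- sqrt(rowSums(d * d))
  inside <- r <= vta$radius
  if (!is.null(vta$sector)) {
    cos_half <- cos(vta$sector$width_deg / 2 * pi / 180)
    ang_ok <- (d %*% vta$sector$axis_out) / pmax(r, 1e-12) >= cos_half
    inside <- inside & (ang_ok | r < 1e-12)
  }
  affine <- diag(c(voxel_size, voxel_size, voxel_size, 1))
  affine[1:3, 4] <- lo
  vta_mask(array(inside, dim = n), affine)
}
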