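#' @keywords internal
"_PACKAGE"

#' Validate a single streamline
#'
#' A streamline is a numeric matrix with one 3-D point (x, y, z, in mm) per
#' row. At least two points are required and all coordinates must be finite.
#'
#' @param points Numeric matrix (n x 3).
#' @return The matrix, invisibly, after validation.
#' @export
validate_streamline <- function(points) {
  if (!is.matrix(points) || !is.numeric(points) || ncol(points) != 3L)
    stop("a streamline must be a numeric matrix with 3 columns (x, y, z)")
  if (nrow(points) < 2L)
    stop("a streamline needs at least 2 points")
  if (!all(is.finite(points)))
    stop("streamline coordinates must all be finite")
  invisible(points)
}

#' Construct a tract bundle
#'
#' A tract bundle is the unit on which pathway activation is computed: a set
#' of streamlines with positive per-streamline weights (SIFT2 convention),
#' a pathway name (e.g. "HDP" or "CST") and a hemisphere. The total weight is
#' the sum of the member weights; activation fractions are ratios of summed
#' weights against this total.
#'
#' @param streamlines List of streamline matrices (n x 3, mm).
#' @param weights Positive per-streamline weights; recycled if length 1.
#' @param name Pathway label, e.g. "HDP" or "CST".
#' @param hemisphere "left" or "right".
#' @return An object of class `tract_bundle` with elements `name`,
#'   `hemisphere`, `streamlines`, `weights` and `total_weight`.
#' @export
tract_bundle <- function(streamlines, weights = 1, name = "bundle",
                         hemisphere = c("right", "left")) {
  hemisphere <- match.arg(hemisphere)
  if (!is.list(streamlines) || length(streamlines) == 0L)
    stop("a tract bundle must contain at least one streamline")
  lapply(streamlines, validate_streamline)
  weights <- rep_len(as.numeric(weights), length(streamlines))
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("streamline weights must be finite and > 0")
  b <- structure(
    list(name = name, hemisphere = hemisphere, streamlines = streamlines,
         weights = weights, total_weight = sum(weights)),
    class = "tract_bundle")
  b$segments <- bundle_segments(streamlines)
  b
}

# Flattened segment representation used by all geometry kernels:
# A, B are matrices of segment start/end points; sid maps each segment to its
# streamline index.
bundle_segments <- function(streamlines) {
  npts <- vapply(streamlines, nrow, 0L)
  P <- do.call(rbind, streamlines)
  last <- cumsum(npts)                    # row index of each streamline's end
  seg_start <- setdiff(seq_len(nrow(P)), last)
  list(A = P[seg_start, , drop = FALSE],
       B = P[seg_start + 1L, , drop = FALSE],
       sid = rep.int(seq_along(streamlines), npts - 1L),
       n_streamlines = length(streamlines))
}

#' @export
print.tract_bundle <- function(x, ...) {
  lens <- streamline_lengths(x)
  cat(sprintf("<tract_bundle> %s (%s): %d streamlines, total weight %.3f\n",
              x$name, x$hemisphere, length(x$streamlines), x$total_weight))
  cat(sprintf("  lengths %.1f-%.1f mm (median %.1f)\n",
              min(lens), max(lens), stats::median(lens)))
  invisible(x)
}

#' Streamline arc lengths of a bundle
#'
#' @param bundle A `tract_bundle`.
#' @return Numeric vector of polyline lengths in mm, one per streamline.
#' @export
streamline_lengths <- function(bundle) {
  vapply(bundle$streamlines, function(p) {
    d <- diff(p)
    sum(sqrt(rowSums(d * d)))
  }, 0)
}
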