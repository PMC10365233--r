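# 8-contact directional lead geometry (1-3-3-1 layout): a distal ring
# (contact 1), two levels of three 120-degree segments (contacts 2-4, 5-7)
# and a proximal ring (contact 8). Contact length 1.5 mm, inter-contact gap
# 0.5 mm (2.0 mm level pitch), lead radius 0.635 mm.

unit3 <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Construct a directional lead model from a pose
#'
#' The pose is the lead tip position (base of the distal contact), the unit
#' axis pointing from distal to proximal, and the rotation of the directional
#' marker (the outward direction of the first segment of each level) about
#' the axis.
#'
#' @param tip 3-D position of the lead tip in mm.
#' @param axis Distal-to-proximal direction (normalized internally).
#' @param rotation Marker rotation in radians.
#' @param contact_length,inter_contact_gap,lead_radius Geometry constants in
#'   mm; defaults follow the 1-3-3-1 directional lead.
#' @return Object of class `lead_model`.
#' @export
lead_model <- function(tip, axis, rotation = 0,
                       contact_length = 1.5, inter_contact_gap = 0.5,
                       lead_radius = 0.635) {
  tip <- as.numeric(tip)
  stopifnot(length(tip) == 3L, all(is.finite(tip)), is.finite(rotation))
  structure(
    list(tip = tip, axis = unit3(as.numeric(axis)), rotation = rotation,
         contact_length = contact_length, inter_contact_gap = inter_contact_gap,
         lead_radius = lead_radius),
    class = "lead_model")
}

#' @export
print.lead_model <- function(x, ...) {
  cat(sprintf("<lead_model> tip (%.2f, %.2f, %.2f) axis (%.2f, %.2f, %.2f) rotation %.2f rad\n",
              x$tip[1], x$tip[2], x$tip[3], x$axis[1], x$axis[2], x$axis[3],
              x$rotation))
  invisible(x)
}

# Deterministic orthonormal in-plane basis (u, v) perpendicular to the axis;
# u is the rotation-zero direction.
lead_basis <- function(axis) {
  ref <- c(1, 0, 0)
  u <- ref - sum(ref * axis) * axis
  if (sqrt(sum(u * u)) < 1e-6) {
    ref <- c(0, 1, 0)
    u <- ref - sum(ref * axis) * axis
  }
  u <- unit3(u)
  list(u = u, v = cross3(axis, u))
}

#' Contact frames of a directional lead
#'
#' Returns centroid and (for segments) outward normal of the eight contacts.
#' Level centroids sit at axial offsets 0.75, 2.75, 4.75 and 6.75 mm from the
#' tip; segment centroids are displaced radially by
#' `lead_radius * radial_offset_fraction` along their outward direction.
#' Segment outward directions are at 0, 120 and 240 degrees from the marker
#' rotation.
#'
#' @param lead A [lead_model()].
#' @param radial_offset_fraction Radial displacement of segment centroids as
#'   a fraction of the lead radius.
#' @return Data frame with one row per contact: `contact`, `config_id`,
#'   `level`, `kind`, centroid `cx,cy,cz` and outward `ox,oy,oz` (NA for
#'   rings).
#' @export
contact_frames <- function(lead, radial_offset_fraction = 1) {
  basis <- lead_basis(lead$axis)
  pitch <- lead$contact_length + lead$inter_contact_gap
  level_offset <- lead$contact_length / 2 + pitch * (0:3)
  level_centroid <- t(vapply(level_offset, function(o) lead$tip + o * lead$axis,
                             numeric(3)))
  contact <- 1:8
  level <- c(1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L)
  kind <- ifelse(contact %in% c(1L, 8L), "ring", "segment")
  angle <- rep(NA_real_, 8)
  angle[2:4] <- lead$rotation + c(0, 2, 4) * pi / 3
  angle[5:7] <- lead$rotation + c(0, 2, 4) * pi / 3
  outward <- matrix(NA_real_, 8, 3)
  centroid <- level_centroid[level, , drop = FALSE]
  for (i in which(kind == "segment")) {
    outward[i, ] <- cos(angle[i]) * basis$u + sin(angle[i]) * basis$v
    centroid[i, ] <- centroid[i, ] +
      lead$lead_radius * radial_offset_fraction * outward[i, ]
  }
  data.frame(contact = contact, config_id = paste0("C", contact),
             level = level, kind = kind,
             cx = centroid[, 1], cy = centroid[, 2], cz = centroid[, 3],
             ox = outward[, 1], oy = outward[, 2], oz = outward[, 3])
}

# Resolve a stimulation configuration (C1..C8 contact or L1..L4 level /
# pseudoring) to a source frame: center, kind, and outward direction for
# segments. Pseudorings are ring sources at the level's axial centroid.
config_frame <- function(lead, config_id, radial_offset_fraction = 1) {
  config_id <- normalize_config_id(config_id)
  frames <- contact_frames(lead, radial_offset_fraction)
  if (grepl("^C[1-8]$", config_id)) {
    f <- frames[frames$config_id == config_id, ]
    list(config_id = config_id, kind = f$kind, level = f$level,
         center = c(f$cx, f$cy, f$cz),
         outward = if (f$kind == "segment") c(f$ox, f$oy, f$oz) else NULL)
  } else if (config_id %in% c("L2", "L3")) {
    lev <- as.integer(sub("L", "", config_id))
    pitch <- lead$contact_length + lead$inter_contact_gap
    center <- lead$tip + (lead$contact_length / 2 + pitch * (lev - 1)) * lead$axis
    list(config_id = config_id, kind = "pseudoring", level = lev,
         center = center, outward = NULL)
  } else {
    stop(sprintf("unknown config_id '%s'", config_id))
  }
}

config_level <- function(config_id) {
  config_id <- normalize_config_id(config_id)
  lv <- c(C1 = 1L, C2 = 2L, C3 = 2L, C4 = 2L, C5 = 3L, C6 = 3L, C7 = 3L,
          C8 = 4L, L2 = 2L, L3 = 3L)
  unname(lv[config_id])
}
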