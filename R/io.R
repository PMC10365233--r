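# Tabular dialects and NIfTI mask I/O.

amplitude_grid <- function() seq(0.5, 8, by = 0.5)

review_configs <- function() c("C1", "C2", "C3", "C4", "C5", "C6", "C7", "C8",
                               "L2", "L3")

# Levels of the 1-3-3-1 lead: L1 and L4 are the distal/proximal rings C1/C8;
# L2/L3 are pseudorings over the directional contacts.
level_configs <- function() c(L1 = "C1", L2 = "L2", L3 = "L3", L4 = "C8")
contact_configs <- function() paste0("C", 1:8)

normalize_config_id <- function(config_id) {
  x <- toupper(trimws(config_id))
  x[x == "L1"] <- "C1"
  x[x == "L4"] <- "C8"
  x[x == "R1"] <- "L2"   # figure-style pseudoring aliases
  x[x == "R2"] <- "L3"
  bad <- setdiff(unique(x), review_configs())
  if (length(bad))
    stop(sprintf("unknown config_id token(s): %s", paste(bad, collapse = ", ")))
  x
}

parse_threshold <- function(x, what, path = "<reviews>") {
  x <- trimws(x)
  value <- rep(NA_real_, length(x))
  censored <- rep(FALSE, length(x))
  censored[x == ">8"] <- TRUE
  num_idx <- which(!censored & nzchar(x))
  if (length(num_idx)) {
    v <- suppressWarnings(as.numeric(x[num_idx]))
    if (any(is.na(v)))
      stop(sprintf("%s: unparseable %s value(s): %s", path, what,
                   paste(unique(x[num_idx][is.na(v)]), collapse = ", ")))
    off <- !vapply(v, function(z) any(abs(z - amplitude_grid()) < 1e-9), TRUE)
    if (any(off))
      stop(sprintf("%s: %s value(s) off the 0.5 mA grid: %s", path, what,
                   paste(unique(v[off]), collapse = ", ")))
    value[num_idx] <- v
  }
  list(value = value, censored = censored)
}

#' Read a monopolar-review table
#'
#' The CSV dialect has columns `subject_id,lead_id,config_id,
#' effect_threshold_mA,side_effect_threshold_mA,tested`. Thresholds lie on
#' the 0.5 mA grid; a censored threshold (sweep reached 8 mA without the
#' outcome, or the sweep was aborted) is written as `">8"`; an untested
#' configuration has empty threshold fields. Config tokens `L1`/`L4` (and
#' `R1`/`R2`) are normalized to the physical configurations `C1`/`C8`
#' (`L2`/`L3`).
#'
#' @param path Path to the review CSV.
#' @return Data frame with columns `subject_id`, `lead_id`, `config_id`,
#'   `effect_threshold_mA`, `effect_censored`, `side_effect_threshold_mA`,
#'   `side_effect_censored`, `tested`.
#' @export
read_reviews <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", comment.char = "#")
  need <- c("subject_id", "lead_id", "config_id", "effect_threshold_mA",
            "side_effect_threshold_mA", "tested")
  if (!identical(names(df), need))
    stop(sprintf("'%s': review CSV columns must be exactly: %s", path,
                 paste(need, collapse = ",")))
  eff <- parse_threshold(df$effect_threshold_mA, "effect threshold", path)
  se <- parse_threshold(df$side_effect_threshold_mA, "side-effect threshold", path)
  data.frame(
    subject_id = df$subject_id,
    lead_id = df$lead_id,
    config_id = normalize_config_id(df$config_id),
    effect_threshold_mA = eff$value,
    effect_censored = eff$censored,
    side_effect_threshold_mA = se$value,
    side_effect_censored = se$censored,
    tested = toupper(trimws(df$tested)) %in% c("TRUE", "1", "T", "YES"),
    stringsAsFactors = FALSE)
}

format_threshold <- function(value, censored) {
  out <- ifelse(censored, ">8",
                ifelse(is.na(value), "", sprintf("%.1f", value)))
  out
}

#' Write a monopolar-review table
#'
#' Inverse of [read_reviews()]; censored thresholds are serialized as `">8"`
#' and untested thresholds as empty fields.
#'
#' @param reviews Review data frame in the in-memory form of [read_reviews()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reviews <- function(reviews, path) {
  out <- data.frame(
    subject_id = reviews$subject_id,
    lead_id = reviews$lead_id,
    config_id = reviews$config_id,
    effect_threshold_mA = format_threshold(reviews$effect_threshold_mA,
                                           reviews$effect_censored),
    side_effect_threshold_mA = format_threshold(reviews$side_effect_threshold_mA,
                                                reviews$side_effect_censored),
    tested = ifelse(reviews$tested, "TRUE", "FALSE"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read lead poses from CSV
#'
#' Columns: `subject_id,lead_id,hemisphere,tip_x,tip_y,tip_z,axis_x,axis_y,
#' axis_z,rotation_rad`. One row per lead, coordinates in world mm.
#'
#' @param path Path to the pose CSV.
#' @return Data frame of poses.
#' @export
read_lead_poses <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("subject_id", "lead_id", "hemisphere", "tip_x", "tip_y", "tip_z",
            "axis_x", "axis_y", "axis_z", "rotation_rad")
  if (!all(need %in% names(df)))
    stop(sprintf("'%s': lead pose CSV must contain columns: %s", path,
                 paste(need, collapse = ",")))
  df[need]
}

#' Write lead poses to CSV
#'
#' @param poses Data frame as returned by [read_lead_poses()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lead_poses <- function(poses, path) {
  utils::write.csv(poses, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a binary NIfTI-1 mask
#'
#' Voxels with value > 0.5 are "inside"; voxel centers map to world mm via
#' the image affine.
#'
#' @param path Path to a NIfTI file.
#' @return List with `grid` (logical array) and `affine` (4 x 4 voxel-to-world
#'   matrix, 0-based voxel indices).
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  affine <- structure(RNifti::xform(img), class = NULL)
  list(grid = as.array(img) > 0.5, affine = unclass(affine))
}

#' Write a binary mask as NIfTI-1
#'
#' @param grid Logical or 0/1 numeric array.
#' @param affine 4 x 4 voxel-to-world affine (0-based voxel indices).
#' @param path Output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(grid, affine, path) {
  img <- RNifti::asNifti(array(as.numeric(grid), dim = dim(grid)))
  # pixdim must match the affine scaling before the xform is attached
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  affine <- structure(affine, code = 2L)
  RNifti::sform(img) <- affine
  RNifti::qform(img) <- affine
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' @param results Any JSON-serializable structure.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
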