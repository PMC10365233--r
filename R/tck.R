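# MRtrix track (.tck) files: text header terminated by "END\n", then
# little-endian float32 triplets; streamlines separated by a NaN triplet and
# the stream terminated by an Inf triplet.

#' Read an MRtrix track (.tck) file
#'
#' Coordinates are returned in the file's native mm space. Streamline weights
#' are not part of the TCK container; see [read_weights()].
#'
#' @param path Path to a .tck file.
#' @return List of streamline matrices (n x 3).
#' @export
read_tck <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  header <- parse_tck_header(raw, path)
  n_floats <- (length(raw) - header$offset) %/% 4L
  vals <- readBin(raw[(header$offset + 1L):length(raw)], "numeric",
                  n = n_floats, size = 4L, endian = header$endian)
  if (length(vals) %% 3L != 0L)
    stop(sprintf("truncated track stream in '%s': %d floats is not a whole number of triplets",
                 path, length(vals)))
  m <- matrix(vals, ncol = 3L, byrow = TRUE)
  is_term <- is.infinite(m[, 1L])
  if (!any(is_term))
    stop(sprintf("truncated track stream in '%s': no Inf terminator triplet", path))
  m <- m[seq_len(which(is_term)[1L] - 1L), , drop = FALSE]
  is_sep <- is.nan(m[, 1L])
  grp <- cumsum(c(TRUE, utils::head(is_sep, -1L)))
  keep <- !is_sep
  streams <- if (nrow(m) == 0L) list() else
    unname(split.data.frame(m[keep, , drop = FALSE], grp[keep]))
  streams <- lapply(streams, function(s) { dimnames(s) <- NULL; s })
  if (!is.na(header$count) && header$count != length(streams))
    warning(sprintf("'%s': header count field is %d but %d streamlines present",
                    path, header$count, length(streams)))
  streams
}

parse_tck_header <- function(raw, path) {
  end_pat <- charToRaw("\nEND\n")
  limit <- min(length(raw), 65536L)
  hdr_end <- NA_integer_
  for (i in seq_len(max(0L, limit - 4L))) {
    if (raw[i] == end_pat[1L] && identical(raw[i:(i + 4L)], end_pat)) {
      hdr_end <- i + 4L
      break
    }
  }
  if (is.na(hdr_end))
    stop(sprintf("malformed track header in '%s': no END line found", path))
  lines <- strsplit(rawToChar(raw[seq_len(hdr_end)]), "\n", fixed = TRUE)[[1L]]
  if (length(lines) == 0L || !identical(trimws(lines[1L]), "mrtrix tracks"))
    stop(sprintf("malformed track header in '%s': missing 'mrtrix tracks' magic line", path))
  kv <- lines[-1L]
  kv <- kv[nzchar(kv) & kv != "END"]
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  get1 <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
  datatype <- get1("datatype")
  if (is.na(datatype))
    stop(sprintf("malformed track header in '%s': missing 'datatype' field", path))
  endian <- switch(datatype,
    Float32LE = "little", Float32BE = "big",
    stop(sprintf("unsupported datatype '%s' in '%s': only float32 tracks are supported",
                 datatype, path)))
  file_field <- get1("file")
  if (is.na(file_field) || !grepl("^\\. [0-9]+$", file_field))
    stop(sprintf("malformed track header in '%s': bad or missing 'file' field", path))
  offset <- as.integer(sub("^\\. ", "", file_field))
  count <- suppressWarnings(as.integer(get1("count")))
  list(offset = offset, count = count, endian = endian)
}

#' Write streamlines to an MRtrix track (.tck) file
#'
#' @param streamlines List of streamline matrices (n x 3, mm), or a
#'   `tract_bundle` whose streamlines are written (weights are not stored in
#'   TCK; see [write_weights()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tck <- function(streamlines, path) {
  if (inherits(streamlines, "tract_bundle")) streamlines <- streamlines$streamlines
  lapply(streamlines, validate_streamline)
  n <- length(streamlines)
  make_header <- function(offset) {
    sprintf("mrtrix tracks\ndatatype: Float32LE\ncount: %d\nfile: . %d\nEND\n",
            n, offset)
  }
  # the offset appears inside the header, so iterate until self-consistent
  offset <- nchar(make_header(0L))
  repeat {
    new_offset <- nchar(make_header(offset))
    if (new_offset == offset) break
    offset <- new_offset
  }
  blocks <- lapply(streamlines, function(s) rbind(s, c(NaN, NaN, NaN)))
  m <- do.call(rbind, c(blocks, list(c(Inf, Inf, Inf))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(make_header(offset), con, eos = NULL)
  writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read SIFT2-style streamline weights
#'
#' Plain-text weights, one float per line or whitespace-separated, in
#' streamline order.
#'
#' @param path Path to the weights file.
#' @param n_expected Expected number of weights (the streamline count).
#' @return Numeric vector of positive weights, length `n_expected`.
#' @export
read_weights <- function(path, n_expected) {
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  per_line <- lapply(toks, function(x) as.numeric(x[nzchar(x)]))
  w <- unlist(per_line, use.names = FALSE)
  if (any(is.na(w)))
    stop(sprintf("'%s': non-numeric weight entries", path))
  if (length(w) != n_expected)
    stop(sprintf("'%s': %d weights found but %d streamlines expected",
                 path, length(w), n_expected))
  if (any(w <= 0)) {
    line_no <- rep(seq_along(per_line), lengths(per_line))
    bad <- unique(line_no[w <= 0])
    stop(sprintf("'%s': non-positive weight(s) on line(s) %s",
                 path, paste(bad, collapse = ", ")))
  }
  w
}

#' Write streamline weights as plain text, one per line
#'
#' @param weights Numeric vector of positive weights.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be finite and > 0")
  writeLines(sprintf("%.9g", weights), path)
  invisible(path)
}
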