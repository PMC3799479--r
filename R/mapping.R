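#' Construct an injective alignment mapping
#'
#' A mapping (matching) `M` pairs proteins of network X with proteins of
#' network Y such that no protein appears twice on either side. Mappings may
#' be partial: nodes of either network can be left unmatched.
#'
#' @param x,y equal-length character vectors of paired identifiers.
#' @return An object of class `alignment_mapping`: a data frame with columns
#'   `x` and `y`, sorted by `x`.
#' @export
alignment_mapping <- function(x = character(), y = character()) {
  x <- as.character(x)
  y <- as.character(y)
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  if (anyDuplicated(x)) {
    stop_input("mapping is not injective: x identifier '",
               x[duplicated(x)][1L], "' appears more than once")
  }
  if (anyDuplicated(y)) {
    stop_input("mapping is not injective: y identifier '",
               y[duplicated(y)][1L], "' appears more than once")
  }
  ord <- order(x, method = "radix")
  df <- data.frame(x = x[ord], y = y[ord], stringsAsFactors = FALSE)
  class(df) <- c("alignment_mapping", "data.frame")
  df
}

#' @export
print.alignment_mapping <- function(x, ...) {
  cat(sprintf("Alignment mapping: %d pairs\n", nrow(x)))
  if (nrow(x) > 0L) {
    utils::head(as.data.frame(x), 6L) |> print(row.names = FALSE)
    if (nrow(x) > 6L) cat(sprintf("... and %d more\n", nrow(x) - 6L))
  }
  invisible(x)
}

#' Read an alignment mapping
#'
#' Two tab-separated identifier columns (x, y); `#`-comment lines ignored.
#' Any third-party aligner output in this form can be ingested.
#'
#' @param path path to the file.
#' @return An [alignment_mapping()]; repeated x or y identifiers raise an
#'   injectivity error naming the offender.
#' @export
read_mapping <- function(path) {
  assert_file(path, "mapping")
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) return(alignment_mapping())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    stop_input(sprintf(
      "malformed mapping line %d (expected 2 tab-separated columns): %s",
      lineno[bad[1L]], lines[bad[1L]]
    ))
  }
  m <- do.call(rbind, parts)
  alignment_mapping(m[, 1L], m[, 2L])
}

#' Write an alignment mapping
#'
#' Writes a two-column TSV sorted by x-identifier, so
#' `read_mapping(write_mapping(m, f))` round-trips exactly.
#'
#' @param mapping an [alignment_mapping()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(mapping, path) {
  stopifnot(inherits(mapping, "alignment_mapping"))
  writeLines(paste(mapping$x, mapping$y, sep = "\t"), path)
  invisible(path)
}

#' Node correctness against a planted truth
#'
#' Fraction of the true pairs recovered: `|m intersect truth| / |truth|`.
#'
#' @param m an [alignment_mapping()] (e.g. an inferred alignment).
#' @param truth the reference [alignment_mapping()]; must be non-empty.
#' @return A number in `[0, 1]`.
#' @export
node_correctness <- function(m, truth) {
  stopifnot(inherits(m, "alignment_mapping"), inherits(truth, "alignment_mapping"))
  if (nrow(truth) == 0L) stop_input("truth mapping is empty")
  if (nrow(m) == 0L) return(0)
  key_m <- paste(m$x, m$y, sep = "\r")
  key_t <- paste(truth$x, truth$y, sep = "\r")
  sum(key_m %in% key_t) / length(key_t)
}
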