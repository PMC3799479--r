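#' Construct a sparse similarity store
#'
#' Holds strictly positive pairwise sequence-similarity scores (e.g. BLAST bit
#' scores) between proteins of two networks. Absent pairs score 0. Access via
#' [sim_score()] is symmetric: `(x, y)` and `(y, x)` return the same value.
#'
#' @param x,y character vectors of protein identifiers.
#' @param score numeric vector of non-negative scores; zero-score rows are
#'   dropped, duplicate `(x, y)` rows resolved by keeping the maximum.
#' @return An object of class `similarity_store`: a list with a data frame
#'   `pairs` (columns `x`, `y`, `score`) and a named score lookup.
#' @export
similarity_store <- function(x = character(), y = character(), score = numeric()) {
  x <- as.character(x)
  y <- as.character(y)
  score <- as.numeric(score)
  if (length(x) != length(y) || length(x) != length(score)) {
    stop_input("x, y and score must have equal length")
  }
  if (any(is.na(score))) stop_input("scores must be numeric and non-missing")
  if (any(score < 0)) stop_input("scores must be non-negative")
  keep <- score > 0
  x <- x[keep]; y <- y[keep]; score <- score[keep]
  if (length(x) > 0L) {
    key <- paste(x, y, sep = "\r")
    if (anyDuplicated(key)) {
      mx <- tapply(score, key, max)   # duplicate (x, y) rows keep the maximum
      first <- !duplicated(key)
      x <- x[first]; y <- y[first]
      score <- as.numeric(mx[key[first]])
    }
  }
  ord <- order(x, y, method = "radix")
  pairs <- data.frame(x = x[ord], y = y[ord], score = score[ord],
                      stringsAsFactors = FALSE)
  lookup <- pairs$score
  names(lookup) <- paste(pairs$x, pairs$y, sep = "\r")
  structure(list(pairs = pairs, lookup = lookup), class = "similarity_store")
}

#' @export
print.similarity_store <- function(x, ...) {
  cat(sprintf(
    "Similarity store: %d positive-score pairs (%d x-ids, %d y-ids)\n",
    nrow(x$pairs), length(unique(x$pairs$x)), length(unique(x$pairs$y))
  ))
  invisible(x)
}

#' Number of stored pairs
#' @param store a [similarity_store()].
#' @return integer count of positive-score pairs.
#' @export
n_pairs <- function(store) nrow(store$pairs)

#' Query a similarity score
#'
#' Symmetric access: if `(a, b)` is absent, `(b, a)` is consulted; absent
#' pairs score 0.
#'
#' @param store a [similarity_store()].
#' @param a,b protein identifiers (vectorized, recycled to common length).
#' @return numeric vector of scores.
#' @export
sim_score <- function(store, a, b) {
  k1 <- paste(a, b, sep = "\r")
  v <- store$lookup[k1]
  miss <- is.na(v)
  if (any(miss)) {
    k2 <- paste(b[miss], a[miss], sep = "\r")
    v[miss] <- store$lookup[k2]
  }
  v[is.na(v)] <- 0
  unname(v)
}

#' Read a similarity table
#'
#' Three tab-separated columns: x-identifier, y-identifier, numeric score.
#' Lines starting with `#` are ignored. Zero scores are omitted; duplicated
#' `(x, y)` rows keep the maximum score.
#'
#' @param path path to the file.
#' @return A [similarity_store()].
#' @export
read_similarity <- function(path) {
  assert_file(path, "similarity")
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) return(similarity_store())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0L) {
    stop_input(sprintf(
      "malformed similarity line %d (expected 3 tab-separated columns): %s",
      lineno[bad[1L]], lines[bad[1L]]
    ))
  }
  m <- do.call(rbind, parts)
  score <- suppressWarnings(as.numeric(m[, 3L]))
  if (anyNA(score)) {
    bad <- which(is.na(score))[1L]
    stop_input(sprintf("non-numeric score on line %d: %s", lineno[bad], m[bad, 3L]))
  }
  if (any(score < 0)) {
    bad <- which(score < 0)[1L]
    stop_input(sprintf("negative score on line %d: %s", lineno[bad], m[bad, 3L]))
  }
  similarity_store(m[, 1L], m[, 2L], score)
}

#' Symmetrize directed similarity scores
#'
#' BLAST scores can be asymmetric: the table may carry both `(i, j)` and
#' `(j, i)` with different values. This collapses each unordered pair to a
#' single canonical entry holding the maximum of the directed values.
#'
#' @param raw a [similarity_store()] possibly holding both orientations.
#' @return A [similarity_store()] with one entry per unordered pair (stored
#'   with the lexicographically smaller identifier first).
#' @export
symmetrize_scores <- function(raw) {
  stopifnot(inherits(raw, "similarity_store"))
  p <- raw$pairs
  if (nrow(p) == 0L) return(raw)
  a <- pmin(p$x, p$y)
  b <- pmax(p$x, p$y)
  similarity_store(a, b, p$score)
}

#' Normalize scores to (0, 1]
#'
#' Divides every score by the global maximum, so all scores lie in (0, 1]
#' and the maximum is exactly 1. Idempotent.
#'
#' @param sym a non-empty [similarity_store()] (typically symmetrized).
#' @return A [similarity_store()] with rescaled scores.
#' @export
normalize_scores <- function(sym) {
  stopifnot(inherits(sym, "similarity_store"))
  if (nrow(sym$pairs) == 0L) {
    stop_input("cannot normalize an empty similarity store")
  }
  mx <- max(sym$pairs$score)
  similarity_store(sym$pairs$x, sym$pairs$y, sym$pairs$score / mx)
}

#' Write a similarity table
#' @param store a [similarity_store()].
#' @param path output path (three-column TSV).
#' @return `path`, invisibly.
#' @export
write_similarity <- function(store, path) {
  stopifnot(inherits(store, "similarity_store"))
  p <- store$pairs
  writeLines(paste(p$x, p$y, format(p$score, trim = TRUE, scientific = FALSE),
                   sep = "\t"), path)
  invisible(path)
}
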