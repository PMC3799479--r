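#' Initial mapping by maximum-weight bipartite matching
#'
#' Computes a matching over the positive-similarity pairs maximizing the total
#' sequence score, the classical topology-free seed for alignment refinement
#' (the assignment produced by the Hungarian algorithm / blossom-style
#' maximum-weight matching). Pairs with zero or absent similarity are never
#' matched. Among equal-weight optima, the lexicographically smallest
#' `(x, y)` pair sequence is returned, which makes the result deterministic.
#'
#' @param inst an [alignment_instance()].
#' @param lexicographic resolve ties among optimal matchings toward the
#'   lexicographically smallest pair sequence (default `TRUE`; turning it off
#'   skips the tie-break pass and returns whichever optimum the matching
#'   backend produces).
#' @return An [alignment_mapping()] (empty if the store holds no positive
#'   scores).
#' @export
initial_matching <- function(inst, lexicographic = TRUE) {
  stopifnot(inherits(inst, "alignment_instance"))
  p <- inst$sim$pairs
  if (nrow(p) == 0L) return(alignment_mapping())
  sol <- matching_solve(p)
  w_opt <- sol$weight
  if (!lexicographic) return(alignment_mapping(sol$x, sol$y))
  tol <- 1e-9 * max(1, abs(w_opt))
  fixed_x <- character()
  fixed_y <- character()
  fixed_score <- 0
  for (x in sort(unique(p$x), method = "radix")) {
    cand <- p[p$x == x & !(p$y %in% fixed_y), , drop = FALSE]
    cand <- cand[order(cand$y, method = "radix"), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      y <- cand$y[k]
      rest <- p[!(p$x %in% c(fixed_x, x)) & !(p$y %in% c(fixed_y, y)), , drop = FALSE]
      total <- fixed_score + cand$score[k] +
        if (nrow(rest) > 0L) matching_solve(rest)$weight else 0
      if (total >= w_opt - tol) {
        fixed_x <- c(fixed_x, x)
        fixed_y <- c(fixed_y, y)
        fixed_score <- fixed_score + cand$score[k]
        break
      }
    }
    # if no candidate preserves optimality, x stays unmatched
  }
  alignment_mapping(fixed_x, fixed_y)
}

# Max-weight bipartite matching over a pairs data frame (x, y, score > 0).
# Returns matched x/y vectors and the total weight.
matching_solve <- function(pairs) {
  xs <- sort(unique(pairs$x), method = "radix")
  ys <- sort(unique(pairs$y), method = "radix")
  # disjoint vertex namespaces: the same identifier may appear on both sides
  vnames <- c(paste0("X\r", xs), paste0("Y\r", ys))
  types <- c(rep(FALSE, length(xs)), rep(TRUE, length(ys)))
  ei <- match(paste0("X\r", pairs$x), vnames)
  ej <- match(paste0("Y\r", pairs$y), vnames)
  g <- igraph::make_bipartite_graph(types, rbind(ei, ej), directed = FALSE)
  res <- igraph::max_bipartite_match(g, weights = pairs$score)
  mx <- res$matching[seq_along(xs)]   # partner vertex index or NA, per x
  matched <- !is.na(mx)
  list(
    x = xs[matched],
    y = ys[mx[matched] - length(xs)],
    weight = res$matching_weight
  )
}

#' Automatic topology weight
#'
#' Picks `alpha` from the realized score split of the initial mapping so that
#' the topology contribution is weighted twice as heavily as it is in the
#' initial mapping: with `S0` the total sequence score and `T0` the total
#' topology similarity of `m0`, `alpha* = 2 S0 / (2 S0 + T0)`, which makes
#' `alpha* T0 = 2 (1 - alpha*) S0` hold exactly. The result is clamped to
#' `[0.01, 0.99]`. When `m0` carries no sequence score at all (the
#' sequence-free regime), `alpha = 1` is returned.
#'
#' @param m0 the initial [alignment_mapping()].
#' @param inst an [alignment_instance()].
#' @return A single number in `(0, 1]`.
#' @export
auto_alpha <- function(m0, inst) {
  s0 <- sequence_score(m0, inst)
  if (s0 <= 0) return(1)
  t0 <- topology_total(m0, inst)
  alpha <- 2 * s0 / (2 * s0 + t0)
  min(max(alpha, 0.01), 0.99)
}
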