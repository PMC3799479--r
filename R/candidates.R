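#' Build per-vertex swap candidate sets
#'
#' For every vertex `x` of network X, `N_c(x)` is the list of at most `c`
#' partners in Y ranked best-first; likewise `N_c(y)` over X. Only swaps whose
#' introduced partner lies in a candidate list are examined by the refiner,
#' which keeps the search space small. In practice `c = 20` suffices; values
#' near the maximum degree of the networks are a reasonable upper choice.
#'
#' Two ranking modes:
#' \describe{
#'   \item{sequence}{candidates are the partners with positive sequence
#'     similarity, ranked by score (ties broken by identifier). Vertices
#'     without any positive score get empty lists.}
#'   \item{topology}{for sequence-free alignments: all partners ranked by
#'     degree agreement, `-|deg(x) - deg(y)|`, ties broken by higher
#'     `min(deg)`, then identifier.}
#' }
#'
#' @param inst an [alignment_instance()].
#' @param mode `"sequence"` (default) or `"topology"`.
#' @param c maximum candidates per vertex (positive integer, default 20).
#' @return An object of class `candidate_index`: list with named lists
#'   `for_x`, `for_y` of ranked identifier vectors, plus `mode` and `c`.
#' @export
build_candidates <- function(inst, mode = c("sequence", "topology"), c = 20L) {
  mode <- match.arg(mode)
  if (!is_count(c)) stop_input("c must be a positive integer")
  stopifnot(inherits(inst, "alignment_instance"))
  c <- as.integer(c)
  if (mode == "sequence") {
    p <- inst$sim$pairs
    for_x <- ranked_split(p$x, p$y, p$score, inst$net_x$nodes, c)
    for_y <- ranked_split(p$y, p$x, p$score, inst$net_y$nodes, c)
  } else {
    degx <- node_degrees(inst$net_x)
    degy <- node_degrees(inst$net_y)
    for_x <- degree_ranked(degx, degy, c)
    for_y <- degree_ranked(degy, degx, c)
  }
  structure(list(for_x = for_x, for_y = for_y, mode = mode, c = c),
            class = "candidate_index")
}

#' @export
print.candidate_index <- function(x, ...) {
  cat(sprintf(
    "Candidate index (%s mode, c = %d): %d x-lists, %d y-lists\n",
    x$mode, x$c, length(x$for_x), length(x$for_y)
  ))
  invisible(x)
}

# split partner/score by owner, rank score desc then id asc, truncate to c
ranked_split <- function(owner, partner, score, owners_all, c) {
  out <- rep(list(character()), length(owners_all))
  names(out) <- owners_all
  if (length(owner) > 0L) {
    ord <- order(owner, -score, partner, method = "radix")
    sp <- split(partner[ord], owner[ord])
    sp <- lapply(sp, utils::head, c)
    known <- intersect(names(sp), owners_all)
    out[known] <- sp[known]
  }
  out
}

# rank all opposite-side vertices by degree agreement for each owner vertex
degree_ranked <- function(deg_own, deg_opp, c) {
  out <- rep(list(character()), length(deg_own))
  names(out) <- names(deg_own)
  if (length(deg_opp) == 0L) return(out)
  ids_opp <- names(deg_opp)
  for (v in names(deg_own)) {
    d <- deg_own[[v]]
    gap <- abs(d - deg_opp)
    mind <- pmin(d, deg_opp)
    ord <- order(gap, -mind, ids_opp, method = "radix")
    out[[v]] <- ids_opp[utils::head(ord, c)]
  }
  out
}
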