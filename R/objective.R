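#' Topology similarity of a matched pair
#'
#' For a matched pair `e = (x, y)`, counts the matched pairs `(x', y')` in the
#' mapping with `x'` a neighbor of `x` in network X and `y'` a neighbor of `y`
#' in network Y — the conserved interactions incident to `e`.
#'
#' @param x,y identifiers of a pair that must belong to `mapping`.
#' @param mapping an [alignment_mapping()].
#' @param inst an [alignment_instance()].
#' @return Non-negative integer.
#' @export
topology_similarity <- function(x, y, mapping, inst) {
  ci <- compile_instance(inst)
  mi <- mapping_to_int(mapping, ci)
  xi <- match(x, ci$xids)
  yi <- match(y, ci$yids)
  if (is.na(xi) || is.na(yi) || mi$mapx[xi] != yi) {
    stop_contract("pair (", x, ", ", y, ") is not in the mapping")
  }
  t_pair_int(ci, mi$mapx, xi, yi)
}

# t(e | M) for integer indices; assumes mapx[xi] == yi
t_pair_int <- function(ci, mapx, xi, yi) {
  nb <- ci$adjx[[xi]]
  if (length(nb) == 0L) return(0L)
  imgs <- mapx[nb]
  imgs <- imgs[imgs > 0L]
  if (length(imgs) == 0L) return(0L)
  sum(imgs %in% ci$adjy[[yi]])
}

#' Conserved interactions under a mapping
#'
#' Counts edges `(u, v)` of network X whose endpoints are both matched and
#' whose images form an edge of network Y.
#'
#' @param mapping an [alignment_mapping()].
#' @param inst an [alignment_instance()].
#' @return Non-negative integer.
#' @export
conserved_edge_count <- function(mapping, inst) {
  ci <- compile_instance(inst)
  mi <- mapping_to_int(mapping, ci)
  conserved_int(ci, mi$mapx)
}

conserved_int <- function(ci, mapx) {
  ex <- ci$ex
  if (nrow(ex) == 0L) return(0L)
  fu <- mapx[ex[, 1L]]
  fv <- mapx[ex[, 2L]]
  both <- fu > 0L & fv > 0L
  if (!any(both)) return(0L)
  fu <- fu[both]; fv <- fv[both]
  cnt <- 0L
  for (k in seq_along(fu)) {
    if (fv[k] %in% ci$adjy[[fu[k]]]) cnt <- cnt + 1L
  }
  cnt
}

#' Sequence score of a mapping
#'
#' Sum of similarity scores over matched pairs; absent pairs contribute 0.
#'
#' @inheritParams conserved_edge_count
#' @return Non-negative real.
#' @export
sequence_score <- function(mapping, inst) {
  stopifnot(inherits(mapping, "alignment_mapping"))
  if (nrow(mapping) == 0L) return(0)
  sum(sim_score(inst$sim, mapping$x, mapping$y))
}

seq_score_int <- function(ci, mapx) {
  xi <- which(mapx > 0L)
  if (length(xi) == 0L) return(0)
  sum(ci$S[cbind(xi, mapx[xi])])
}

#' Alignment objective
#'
#' The weight of a mapping `M` is the convex combination
#' `w(M) = alpha * sum_t + (1 - alpha) * sum_s`, where `sum_t` is the total
#' topology similarity over matched pairs (twice the conserved-edge count)
#' and `sum_s` the total sequence score. `alpha = 0` uses sequence data only;
#' `alpha = 1` uses topology only.
#'
#' @inheritParams conserved_edge_count
#' @param alpha topology weight in `[0, 1]`.
#' @return The objective value (non-negative real).
#' @export
alignment_objective <- function(mapping, inst, alpha) {
  if (!is_prob(alpha)) stop_input("alpha must be a single number in [0, 1]")
  ci <- compile_instance(inst)
  mi <- mapping_to_int(mapping, ci)
  objective_int(ci, mi$mapx, alpha)
}

objective_int <- function(ci, mapx, alpha) {
  alpha * 2 * conserved_int(ci, mapx) + (1 - alpha) * seq_score_int(ci, mapx)
}

#' Total topology similarity of a mapping
#'
#' `sum over e in M of t(e | M)`; equal to twice the conserved-edge count,
#' since every conserved interaction is seen from both of its endpoints.
#'
#' @inheritParams conserved_edge_count
#' @return Non-negative integer.
#' @export
topology_total <- function(mapping, inst) {
  2L * conserved_edge_count(mapping, inst)
}
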