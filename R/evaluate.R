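#' Edge-correctness ratio
#'
#' Fraction of interactions conserved by the alignment, normalized by the
#' smaller edge set: `EC = conserved / min(|E_X|, |E_Y|)`. The minimum-side
#' normalization keeps the ratio comparable when the two networks differ
#' greatly in size. Returns 0 when either network has no edges.
#'
#' @param m an [alignment_mapping()].
#' @param inst an [alignment_instance()].
#' @return A number in `[0, 1]`.
#' @export
ec_ratio <- function(m, inst) {
  mn <- min(n_edges(inst$net_x), n_edges(inst$net_y))
  if (mn == 0L) return(0)
  conserved_edge_count(m, inst) / mn
}

#' Functional coherence of an aligned protein pair
#'
#' For proteins `x` and `y` with GO term sets `S_x` and `S_y`, every term
#' pair `(g_x, g_y)` with non-empty standardized sets (see
#' [standardized_terms()]) contributes the fractional overlap
#' `|Std(g_x) n Std(g_y)| / |Std(g_x) u Std(g_y)|`; the pair's FC is the
#' median of these overlaps. Undefined (`NA`) when either protein has no
#' usable terms.
#'
#' @param x,y protein identifiers.
#' @param ann a [go_annotations()].
#' @param dag a [go_dag()].
#' @return A number in `[0, 1]`, or `NA` if undefined.
#' @export
fc_pair <- function(x, y, ann, dag) {
  stopifnot(inherits(ann, "go_annotations"), inherits(dag, "go_dag"))
  tx <- ann$terms_of[[x]]
  ty <- ann$terms_of[[y]]
  if (is.null(tx) || is.null(ty)) return(NA_real_)
  std_x <- lapply(tx, standardized_terms, dag = dag)
  std_y <- lapply(ty, standardized_terms, dag = dag)
  std_x <- std_x[lengths(std_x) > 0L]
  std_y <- std_y[lengths(std_y) > 0L]
  if (length(std_x) == 0L || length(std_y) == 0L) return(NA_real_)
  overlaps <- numeric()
  for (sx in std_x) {
    for (sy in std_y) {
      overlaps <- c(overlaps,
                    length(intersect(sx, sy)) / length(union(sx, sy)))
    }
  }
  stats::median(overlaps)
}

#' Functional coherence of a mapping
#'
#' Arithmetic mean of [fc_pair()] over the aligned pairs for which it is
#' defined (proteins without usable GO annotation are skipped; typically only
#' 60-70% of proteins in a PPI network carry a GO annotation).
#'
#' @param m an [alignment_mapping()].
#' @param ann a [go_annotations()].
#' @param dag a [go_dag()].
#' @return A number in `[0, 1]` with attribute `n_evaluable` (the count of
#'   aligned pairs entering the mean), or `NA` (with `n_evaluable = 0`) when
#'   no pair is evaluable.
#' @export
fc_mapping <- function(m, ann, dag) {
  stopifnot(inherits(m, "alignment_mapping"))
  vals <- mapply(fc_pair, m$x, m$y,
                 MoreArgs = list(ann = ann, dag = dag), USE.NAMES = FALSE)
  vals <- as.numeric(vals)
  ok <- !is.na(vals)
  out <- if (any(ok)) mean(vals[ok]) else NA_real_
  attr(out, "n_evaluable") <- sum(ok)
  out
}

#' Evaluate an alignment
#'
#' Convenience wrapper computing the quality metrics of a mapping: conserved
#' edges, EC ratio, sequence score, total topology similarity, and (when GO
#' data are supplied) functional coherence.
#'
#' @param m an [alignment_mapping()].
#' @param inst an [alignment_instance()].
#' @param ann optional [go_annotations()].
#' @param dag optional [go_dag()] (required with `ann`).
#' @return A list with fields `n_pairs`, `conserved_edges`, `ec_ratio`,
#'   `sequence_score`, `topology_total` and, if GO data were given, `fc`
#'   and `fc_evaluable_pairs`.
#' @export
evaluate_alignment <- function(m, inst, ann = NULL, dag = NULL) {
  out <- list(
    n_pairs = nrow(m),
    conserved_edges = conserved_edge_count(m, inst),
    ec_ratio = ec_ratio(m, inst),
    sequence_score = sequence_score(m, inst),
    topology_total = topology_total(m, inst)
  )
  if (!is.null(ann)) {
    if (is.null(dag)) stop_input("dag must be supplied together with ann")
    fc <- fc_mapping(m, ann, dag)
    out$fc <- as.numeric(fc)
    out$fc_evaluable_pairs <- attr(fc, "n_evaluable")
  }
  out
}
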