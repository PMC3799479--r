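#' Bundle two networks and their similarity scores
#'
#' An alignment instance is the edge-weighted complete bipartite graph over
#' the vertex sets of networks X and Y, with sequence-similarity weights on
#' the cross-species pairs. Score pairs are oriented so the first identifier
#' belongs to X and the second to Y (entries stored the other way round are
#' flipped; pairs referencing unknown identifiers are dropped with a warning).
#'
#' @param net_x,net_y [ppi_network()] objects for the two species.
#' @param sim a [similarity_store()] of cross-species scores; may be empty.
#' @return An object of class `alignment_instance` with fields `net_x`,
#'   `net_y`, `sim` and `dropped_pairs` (count of score pairs whose
#'   identifiers match neither orientation).
#' @export
alignment_instance <- function(net_x, net_y, sim = similarity_store()) {
  stopifnot(inherits(net_x, "ppi_network"), inherits(net_y, "ppi_network"),
            inherits(sim, "similarity_store"))
  p <- sim$pairs
  dropped <- 0L
  if (nrow(p) > 0L) {
    ok_fwd <- p$x %in% net_x$nodes & p$y %in% net_y$nodes
    ok_rev <- !ok_fwd & p$y %in% net_x$nodes & p$x %in% net_y$nodes
    dropped <- sum(!ok_fwd & !ok_rev)
    if (dropped > 0L) {
      warning(sprintf(
        "%d similarity pair(s) reference identifiers absent from both networks; dropped",
        dropped
      ))
    }
    xs <- c(p$x[ok_fwd], p$y[ok_rev])
    ys <- c(p$y[ok_fwd], p$x[ok_rev])
    sc <- c(p$score[ok_fwd], p$score[ok_rev])
    sim <- similarity_store(xs, ys, sc)
  }
  structure(
    list(net_x = net_x, net_y = net_y, sim = sim, dropped_pairs = dropped),
    class = "alignment_instance"
  )
}

#' @export
print.alignment_instance <- function(x, ...) {
  cat(sprintf(
    "Alignment instance: X = %d nodes / %d edges; Y = %d nodes / %d edges; %d score pairs\n",
    n_nodes(x$net_x), n_edges(x$net_x), n_nodes(x$net_y), n_edges(x$net_y),
    nrow(x$sim$pairs)
  ))
  invisible(x)
}

# ---- internal integer-indexed representation -------------------------------
#
# The refinement engine works on integer node indices for speed: adjacency as
# lists of integer vectors, similarity as a dense nx-by-ny matrix (instances
# at refiner scale are small enough), mappings as a pair of inverse integer
# vectors with 0 = unmatched.

compile_instance <- function(inst) {
  stopifnot(inherits(inst, "alignment_instance"))
  xids <- inst$net_x$nodes
  yids <- inst$net_y$nodes
  nx <- length(xids)
  ny <- length(yids)
  adjx <- int_adjacency(inst$net_x, xids)
  adjy <- int_adjacency(inst$net_y, yids)
  S <- matrix(0, nrow = max(nx, 1L), ncol = max(ny, 1L))
  p <- inst$sim$pairs
  if (nrow(p) > 0L) {
    S[cbind(match(p$x, xids), match(p$y, yids))] <- p$score
  }
  list(
    inst = inst, xids = xids, yids = yids, nx = nx, ny = ny,
    adjx = adjx, adjy = adjy,
    degx = lengths(adjx), degy = lengths(adjy),
    ex = edge_index_matrix(inst$net_x, xids),
    S = S
  )
}

int_adjacency <- function(net, ids) {
  adj <- rep(list(integer()), length(ids))
  if (nrow(net$edges) > 0L) {
    u <- match(net$edges[, 1L], ids)
    v <- match(net$edges[, 2L], ids)
    for (k in seq_along(u)) {
      adj[[u[k]]] <- c(adj[[u[k]]], v[k])
      adj[[v[k]]] <- c(adj[[v[k]]], u[k])
    }
    adj <- lapply(adj, sort.int)
  }
  adj
}

edge_index_matrix <- function(net, ids) {
  if (nrow(net$edges) == 0L) return(matrix(integer(), ncol = 2L))
  cbind(match(net$edges[, 1L], ids), match(net$edges[, 2L], ids))
}

# membership test against Y adjacency (degrees in PPI data are small)
has_edge_y <- function(ci, y1, y2) {
  y2 %in% ci$adjy[[y1]]
}

# mapping -> inverse integer vectors; validates endpoints against node sets
mapping_to_int <- function(m, ci) {
  stopifnot(inherits(m, "alignment_mapping"))
  mapx <- integer(ci$nx)
  mapy <- integer(ci$ny)
  if (nrow(m) > 0L) {
    xi <- match(m$x, ci$xids)
    yi <- match(m$y, ci$yids)
    if (anyNA(xi)) {
      stop_input("mapping references x identifier absent from network X: ",
                 m$x[which(is.na(xi))[1L]])
    }
    if (anyNA(yi)) {
      stop_input("mapping references y identifier absent from network Y: ",
                 m$y[which(is.na(yi))[1L]])
    }
    mapx[xi] <- yi
    mapy[yi] <- xi
  }
  list(mapx = mapx, mapy = mapy)
}

int_to_mapping <- function(mapx, ci) {
  xi <- which(mapx > 0L)
  alignment_mapping(ci$xids[xi], ci$yids[mapx[xi]])
}
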