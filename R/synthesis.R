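#' Geometric random graph with exact node and edge counts
#'
#' Places `n` points uniformly at random in the unit square and connects the
#' `m` closest pairs, i.e. the disk graph at the smallest radius admitting at
#' least `m` edges, trimmed to exactly `m` by dropping the longest ties.
#' Geometric random graphs are a standard null model for PPI topology
#' (proteins interact when close in some biochemical space), and fixing both
#' counts makes randomized networks size-matched to a real network.
#'
#' @param n number of nodes.
#' @param m number of edges; must satisfy `0 <= m <= n(n-1)/2`.
#' @param seed integer seed; the same seed reproduces the same graph exactly.
#' @param dim dimension of the embedding space (default 2).
#' @param prefix node identifier prefix (nodes are `<prefix>1 ... <prefix>n`).
#' @return A [ppi_network()] with exactly `n` nodes and `m` edges.
#' @export
geometric_random_graph <- function(n, m, seed, dim = 2L, prefix = "v") {
  if (!is_count(n)) stop_input("n must be a positive integer")
  if (!is.numeric(m) || length(m) != 1L || m < 0 || m != floor(m)) {
    stop_input("m must be a non-negative integer")
  }
  max_m <- n * (n - 1) / 2
  if (m > max_m) {
    stop_input(sprintf("m = %d exceeds the maximum %d for n = %d", m, max_m, n))
  }
  ids <- paste0(prefix, seq_len(n))
  if (m == 0L || n < 2L) {
    return(ppi_network(matrix(character(), ncol = 2L), nodes = ids,
                       name = sprintf("grg(n=%d,m=%d)", n, m)))
  }
  pts <- with_seed(seed, matrix(stats::runif(n * dim), nrow = n))
  d <- as.matrix(stats::dist(pts))
  iu <- which(upper.tri(d), arr.ind = TRUE)
  dv <- d[iu]
  # deterministic selection of the m shortest pairs; ties broken by pair order
  ord <- order(dv, iu[, 1L], iu[, 2L])
  sel <- iu[ord[seq_len(m)], , drop = FALSE]
  ppi_network(cbind(ids[sel[, 1L]], ids[sel[, 2L]]), nodes = ids,
              name = sprintf("grg(n=%d,m=%d)", n, m))
}

#' Synthesize a planted alignment instance
#'
#' Generates a pair of networks with a known ground-truth bijection plus a
#' noisy similarity table, emulating the incomplete and inaccurate character
#' of real PPI data with two noise knobs:
#' \describe{
#'   \item{rho_e (edge noise)}{network Y is a relabeled copy of X in which a
#'     fraction `rho_e` of edges is removed and the same number of random
#'     non-edges added — false negatives and false positives.}
#'   \item{rho_s (score noise)}{every true pair `(x, truth(x))` receives a
#'     score near `s_true` (perturbed by +-10%); for a fraction `rho_s` of
#'     X-proteins the true-pair score is deleted and replaced by 3 random
#'     decoy pairs with scores drawn uniformly from `(0, s_noise]` — lost
#'     and misleading sequence homology.}
#' }
#' At `rho_e = rho_s = 0` the maximum-weight matching recovers the planted
#' truth exactly; as `rho_s` grows, only the topology term carries signal for
#' the scrambled proteins.
#'
#' @param n number of proteins per network (at least 2).
#' @param p edge density of network X under the Erdos-Renyi model, or target
#'   density for the geometric model (in `(0, 1]`, default 0.1).
#' @param rho_e fraction of edges rewired in Y (default 0).
#' @param rho_s fraction of X-proteins with scrambled scores (default 0).
#' @param s_true mean similarity of true pairs (default 1).
#' @param s_noise upper bound of decoy scores (default 0.5).
#' @param model `"er"` (Erdos-Renyi, default) or `"geometric"` for network X.
#' @param seed integer seed; fully determines the instance.
#' @return An object of class `planted_instance`: list with `inst` (an
#'   [alignment_instance()]), `truth` (the planted [alignment_mapping()]
#'   bijection) and `params`.
#' @export
planted_instance <- function(n, p = 0.1, rho_e = 0, rho_s = 0, s_true = 1,
                             s_noise = 0.5, model = c("er", "geometric"),
                             seed = 1L) {
  model <- match.arg(model)
  if (!is_count(n) || n < 2) stop_input("n must be an integer >= 2")
  if (!is.numeric(p) || p <= 0 || p > 1) stop_input("p must be in (0, 1]")
  if (!is_prob(rho_e) || !is_prob(rho_s)) {
    stop_input("rho_e and rho_s must be in [0, 1]")
  }
  with_seed(seed, {
    xids <- paste0("x", seq_len(n))
    yids <- paste0("y", seq_len(n))
    all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    if (model == "er") {
      sel <- stats::runif(nrow(all_pairs)) < p
      ex <- all_pairs[sel, , drop = FALSE]
    } else {
      m_target <- round(p * nrow(all_pairs))
      g <- geometric_random_graph(n, m_target, seed = seed + 1L, prefix = "x")
      ex <- cbind(match(g$edges[, 1L], xids), match(g$edges[, 2L], xids))
    }
    net_x <- ppi_network(cbind(xids[ex[, 1L]], xids[ex[, 2L]]), nodes = xids,
                         name = "planted-X")
    # planted bijection: x_i -> y_perm(i)
    perm <- sample.int(n)
    truth <- alignment_mapping(xids, yids[perm])
    # Y edges: image of X edges, then rewire a fraction rho_e
    ey <- cbind(perm[ex[, 1L]], perm[ex[, 2L]])
    ey <- cbind(pmin(ey[, 1L], ey[, 2L]), pmax(ey[, 1L], ey[, 2L]))
    n_rewire <- round(rho_e * nrow(ey))
    if (n_rewire > 0L && nrow(ey) > 0L) {
      drop_idx <- sample.int(nrow(ey), n_rewire)
      key_all <- all_pairs[, 1L] * (n + 1) + all_pairs[, 2L]
      key_kept <- ey[-drop_idx, 1L] * (n + 1) + ey[-drop_idx, 2L]
      key_old <- ey[, 1L] * (n + 1) + ey[, 2L]
      non_edges <- which(!(key_all %in% key_old))
      add_idx <- sample(non_edges, min(n_rewire, length(non_edges)))
      ey <- rbind(ey[-drop_idx, , drop = FALSE],
                  all_pairs[add_idx, , drop = FALSE])
    }
    net_y <- ppi_network(cbind(yids[ey[, 1L]], yids[ey[, 2L]]), nodes = yids,
                         name = "planted-Y")
    # similarity: true-pair scores, then scramble a fraction rho_s
    sx <- xids
    sy <- yids[perm]
    sc <- s_true * stats::runif(n, 0.9, 1.1)
    n_scramble <- round(rho_s * n)
    if (n_scramble > 0L) {
      scrambled <- sample.int(n, n_scramble)
      keep <- setdiff(seq_len(n), scrambled)
      sx <- sx[keep]; sy <- sy[keep]; sc <- sc[keep]
      for (i in scrambled) {
        decoys <- sample.int(n, min(3L, n))
        sx <- c(sx, rep(xids[i], length(decoys)))
        sy <- c(sy, yids[decoys])
        sc <- c(sc, stats::runif(length(decoys), 0, s_noise))
      }
    }
    sim <- similarity_store(sx, sy, sc)
    structure(list(
      inst = alignment_instance(net_x, net_y, sim),
      truth = truth,
      params = list(n = n, p = p, rho_e = rho_e, rho_s = rho_s,
                    s_true = s_true, s_noise = s_noise, model = model,
                    seed = seed)
    ), class = "planted_instance")
  })
}

#' @export
print.planted_instance <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Planted instance: n = %d, p = %.3g, rho_e = %.2f, rho_s = %.2f (%s model, seed %d)\n",
    p$n, p$p, p$rho_e, p$rho_s, p$model, p$seed
  ))
  print(x$inst)
  invisible(x)
}
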