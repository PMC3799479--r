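# Shared fixtures: three hand-analysed toy instances and random-instance
# generators with independent brute-force oracles.

# Toy A: X is a triangle, Y a 3-path, mapping aligns them in order.
toy_a <- function() {
  net_x <- ppi_network(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  net_y <- ppi_network(rbind(c("1", "2"), c("2", "3")))
  list(
    inst = alignment_instance(net_x, net_y),
    m = alignment_mapping(c("a", "b", "c"), c("1", "2", "3"))
  )
}

# Toy B: one edge per network, similarity favouring a topology-discordant
# matching; one 2-swap reaches the optimum.
toy_b <- function() {
  net_x <- ppi_network(rbind(c("x1", "x2")), nodes = c("x1", "x2", "x3"))
  net_y <- ppi_network(rbind(c("y1", "y2")), nodes = c("y1", "y2", "y3"))
  sim <- similarity_store(
    x = c("x1", "x2", "x3", "x2", "x3"),
    y = c("y1", "y3", "y2", "y2", "y3"),
    score = c(1.0, 0.6, 0.6, 0.5, 0.5)
  )
  list(
    inst = alignment_instance(net_x, net_y, sim),
    m0 = alignment_mapping(c("x1", "x2", "x3"), c("y1", "y3", "y2"))
  )
}

# Toy C: two 3-paths, initial mapping a 3-cycle off the identity; no 2-swap
# improves but the 3-cycle move to the identity does.
toy_c <- function() {
  net_x <- ppi_network(rbind(c("x1", "x2"), c("x2", "x3")))
  net_y <- ppi_network(rbind(c("y1", "y2"), c("y2", "y3")))
  sim <- similarity_store(
    x = c("x1", "x2", "x3", "x1", "x3"),
    y = c("y2", "y3", "y1", "y1", "y3"),
    score = c(1.0, 1.0, 1.0, 0.9, 0.9)
  )
  list(
    inst = alignment_instance(net_x, net_y, sim),
    m0 = alignment_mapping(c("x1", "x2", "x3"), c("y2", "y3", "y1"))
  )
}

# Random small instance: nx, ny nodes, Bernoulli edges, sparse random scores.
random_instance <- function(seed, nx = NULL, ny = NULL, p_edge = 0.4,
                            p_score = 0.5) {
  set.seed(seed)
  if (is.null(nx)) nx <- sample(2:6, 1L)
  if (is.null(ny)) ny <- sample(2:6, 1L)
  xids <- paste0("x", seq_len(nx))
  yids <- paste0("y", seq_len(ny))
  rand_edges <- function(ids) {
    n <- length(ids)
    if (n < 2L) return(matrix(character(), ncol = 2L))
    pr <- utils::combn(n, 2L)
    sel <- stats::runif(ncol(pr)) < p_edge
    cbind(ids[pr[1L, sel]], ids[pr[2L, sel]])
  }
  net_x <- ppi_network(rand_edges(xids), nodes = xids)
  net_y <- ppi_network(rand_edges(yids), nodes = yids)
  grid <- expand.grid(x = xids, y = yids, stringsAsFactors = FALSE)
  sel <- stats::runif(nrow(grid)) < p_score
  sim <- similarity_store(grid$x[sel], grid$y[sel],
                          round(stats::runif(sum(sel), 0.1, 1), 3))
  alignment_instance(net_x, net_y, sim)
}

# Random injective (partial) mapping over an instance's node sets.
random_mapping <- function(inst, seed) {
  set.seed(seed)
  xids <- inst$net_x$nodes
  yids <- inst$net_y$nodes
  k <- sample(0:min(length(xids), length(yids)), 1L)
  if (k == 0L) return(alignment_mapping())
  alignment_mapping(sample(xids, k), sample(yids, k))
}

# Independent oracle: maximum total similarity over ALL matchings, by
# exhaustive recursion over the positive-score pairs.
brute_force_best_weight <- function(inst) {
  p <- inst$sim$pairs
  if (nrow(p) == 0L) return(0)
  xs <- unique(p$x)
  rec <- function(i, used_y) {
    if (i > length(xs)) return(0)
    best <- rec(i + 1L, used_y)
    sub <- p[p$x == xs[i] & !(p$y %in% used_y), , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      best <- max(best, sub$score[k] + rec(i + 1L, c(used_y, sub$y[k])))
    }
    best
  }
  rec(1L, character())
}

# Independent oracle for the full objective over ALL matchings (used to bound
# the refiner): maximizes alpha * sum_t + (1 - alpha) * sum_s exhaustively.
brute_force_best_objective <- function(inst, alpha) {
  xids <- inst$net_x$nodes
  yids <- inst$net_y$nodes
  best <- -Inf
  rec <- function(i, xs, ys, free_y) {
    if (i > length(xids)) {
      m <- alignment_mapping(xs, ys)
      w <- alignment_objective(m, inst, alpha)
      if (w > best) best <<- w
      return(invisible(NULL))
    }
    rec(i + 1L, xs, ys, free_y)   # leave x_i unmatched
    for (y in free_y) {
      rec(i + 1L, c(xs, xids[i]), c(ys, y), setdiff(free_y, y))
    }
  }
  rec(1L, character(), character(), yids)
  best
}

# tiny OBO + annotation writers used by the io and evaluation tests
write_chain_obo <- function(path, labels = c("R", "A", "B", "C", "D", "E", "F", "G")) {
  lines <- c("format-version: 1.2", "")
  for (i in seq_along(labels)) {
    lines <- c(lines, "[Term]", paste0("id: ", labels[i]),
               paste0("name: term ", labels[i]),
               "namespace: test_ns")
    if (i > 1L) lines <- c(lines, paste0("is_a: ", labels[i - 1L], " ! parent"))
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  path
}
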