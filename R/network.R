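#' Construct a PPI network
#'
#' A `ppi_network` is a simple undirected graph: a set of protein identifiers
#' (opaque, case-sensitive strings) and a set of unordered interaction edges.
#' Self-loops are dropped (and counted) and duplicate edges collapsed, so the
#' stored graph is always simple.
#'
#' @param edges two-column character matrix or data frame of endpoints; may
#'   have zero rows.
#' @param nodes optional character vector of node identifiers; defaults to the
#'   identifiers appearing in `edges`. Extra identifiers give isolated nodes.
#' @param name label for the network (used in printing).
#' @return An object of class `ppi_network` with fields `name`, `nodes`
#'   (sorted character vector), `edges` (two-column character matrix, each row
#'   sorted so `edges[, 1] <= edges[, 2]`, rows unique and sorted) and
#'   `loops_dropped` (count of discarded self-loops).
#' @seealso [read_network()], [node_degrees()], [max_degree()]
#' @export
ppi_network <- function(edges, nodes = NULL, name = "network") {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (!is.character(edges)) storage.mode(edges) <- "character"
  if (ncol(edges) != 2L) {
    stop_input("edges must have exactly two columns")
  }
  loops <- edges[, 1L] == edges[, 2L]
  n_loops <- sum(loops)
  loop_nodes <- edges[loops, 1L]   # a dropped loop still names its protein
  edges <- edges[!loops, , drop = FALSE]
  # canonical unordered-pair form: row-wise sorted endpoints, deduplicated
  a <- pmin(edges[, 1L], edges[, 2L])
  b <- pmax(edges[, 1L], edges[, 2L])
  key <- paste(a, b, sep = "\r")
  keep <- !duplicated(key)
  em <- cbind(a[keep], b[keep])
  ord <- order(em[, 1L], em[, 2L], method = "radix")
  em <- em[ord, , drop = FALSE]
  colnames(em) <- c("u", "v")
  all_nodes <- sort(unique(c(as.vector(em), loop_nodes, as.character(nodes))),
                    method = "radix")
  structure(
    list(name = name, nodes = all_nodes, edges = em, loops_dropped = n_loops),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf(
    "PPI network '%s': %d nodes, %d edges (max degree %d)\n",
    x$name, n_nodes(x), n_edges(x),
    if (n_nodes(x) > 0L) max_degree(x) else 0L
  ))
  invisible(x)
}

#' Network summary statistics
#'
#' @param net a [ppi_network()].
#' @return `n_nodes()` and `n_edges()` return counts; `node_degrees()` a named
#'   integer vector over all nodes (isolated nodes have degree 0);
#'   `max_degree()` the maximum degree (0 for an empty network).
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname n_nodes
#' @export
node_degrees <- function(net) {
  deg <- integer(length(net$nodes))
  names(deg) <- net$nodes
  if (nrow(net$edges) > 0L) {
    tab <- table(factor(as.vector(net$edges), levels = net$nodes))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' @rdname n_nodes
#' @export
max_degree <- function(net) {
  if (length(net$nodes) == 0L) return(0L)
  max(node_degrees(net))
}

# adjacency as a named list of sorted character vectors
adjacency_list <- function(net) {
  adj <- rep(list(character()), length(net$nodes))
  names(adj) <- net$nodes
  if (nrow(net$edges) > 0L) {
    sp1 <- split(net$edges[, 2L], net$edges[, 1L])
    sp2 <- split(net$edges[, 1L], net$edges[, 2L])
    for (u in names(sp1)) adj[[u]] <- c(adj[[u]], sp1[[u]])
    for (u in names(sp2)) adj[[u]] <- c(adj[[u]], sp2[[u]])
    adj <- lapply(adj, sort, method = "radix")
  }
  adj
}

#' Read a network from disk
#'
#' Supported formats: `edgelist` (two tab-separated identifier columns) and
#' `sif` (source, interaction type, target). Lines starting with `#` are
#' ignored in both. Self-loops are dropped and counted, duplicate and
#' reversed edges collapsed.
#'
#' @param path path to the file.
#' @param fmt `"edgelist"` (default) or `"sif"`.
#' @param name network label; defaults to the file name.
#' @return A [ppi_network()]. The number of dropped self-loops is available
#'   as `$loops_dropped`.
#' @export
read_network <- function(path, fmt = c("edgelist", "sif"), name = NULL) {
  fmt <- match.arg(fmt)
  assert_file(path, "network")
  if (is.null(name)) name <- basename(path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(ppi_network(matrix(character(), ncol = 2L), name = name))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  want <- if (fmt == "edgelist") 2L else 3L
  bad <- which(lengths(parts) != want)
  if (length(bad) > 0L) {
    stop_input(sprintf(
      "malformed %s line %d (expected %d tab-separated columns): %s",
      fmt, lineno[bad[1L]], want, lines[bad[1L]]
    ))
  }
  m <- do.call(rbind, parts)
  edges <- if (fmt == "edgelist") m[, c(1L, 2L), drop = FALSE] else m[, c(1L, 3L), drop = FALSE]
  ppi_network(edges, name = name)
}

#' Write a network as a two-column edge list
#'
#' @param net a [ppi_network()].
#' @param path output path.
#' @return `path`, invisibly. Isolated nodes are not representable in an edge
#'   list and are omitted.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  writeLines(paste(net$edges[, 1L], net$edges[, 2L], sep = "\t"), path)
  invisible(path)
}
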