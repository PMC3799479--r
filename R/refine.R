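#' Objective change of a 2-Opt swap
#'
#' For two matched pairs `e1 = (x, y)` and `e2 = (x', y')`, computes
#' `w(M') - w(M)` where `M'` replaces them by `(x, y')` and `(x', y)`. The
#' change is computed incrementally from the topology terms of pairs adjacent
#' to the four touched vertices and equals a full recomputation exactly.
#'
#' @param mapping an [alignment_mapping()].
#' @param e1,e2 length-2 character vectors `c(x, y)`; both must be pairs of
#'   `mapping` and distinct.
#' @param inst an [alignment_instance()].
#' @param alpha topology weight in `[0, 1]`.
#' @return The objective delta (may be negative).
#' @export
swap_delta_2 <- function(mapping, e1, e2, inst, alpha) {
  if (!is_prob(alpha)) stop_input("alpha must be a single number in [0, 1]")
  ci <- compile_instance(inst)
  mi <- mapping_to_int(mapping, ci)
  p1 <- pair_index(ci, mi$mapx, e1)
  p2 <- pair_index(ci, mi$mapx, e2)
  if (p1[1L] == p2[1L]) stop_contract("e1 and e2 must be distinct pairs")
  delta2_int(ci, mi$mapx, p1[1L], p2[1L], alpha)
}

#' Objective change of a reassignment to an unmatched partner
#'
#' For a matched pair `e = (x, y)` and an unmatched vertex `y_new` of network
#' Y, computes `w(M') - w(M)` where `M'` replaces `(x, y)` by `(x, y_new)`.
#' This move reaches improvements that pure pair swaps cannot when one
#' network has spare vertices.
#'
#' @inheritParams swap_delta_2
#' @param e length-2 character vector `c(x, y)`, a pair of `mapping`.
#' @param y_new identifier of an unmatched Y vertex.
#' @return The objective delta (may be negative).
#' @export
swap_delta_unmatched <- function(mapping, e, y_new, inst, alpha) {
  if (!is_prob(alpha)) stop_input("alpha must be a single number in [0, 1]")
  ci <- compile_instance(inst)
  mi <- mapping_to_int(mapping, ci)
  p <- pair_index(ci, mi$mapx, e)
  yn <- match(y_new, ci$yids)
  if (is.na(yn)) stop_input("unknown y identifier: ", y_new)
  if (mi$mapy[yn] > 0L) stop_contract("y_new '", y_new, "' is already matched")
  delta_unm_int(ci, mi$mapx, p[1L], yn, alpha)
}

#' Best 3-Opt move on a triple of matched pairs
#'
#' Evaluates the five non-identity reassignments of the three Y endpoints
#' among the three X endpoints (the three pairwise swaps and the two
#' 3-cycles) and returns the one with maximal objective change.
#'
#' @inheritParams swap_delta_2
#' @param triple list of three distinct length-2 character vectors `c(x, y)`,
#'   all pairs of `mapping`.
#' @return A list with `pairs` (3x2 character matrix of the reassigned
#'   pairs) and `delta` (its objective change; may be negative or zero).
#' @export
best_3opt_move <- function(mapping, triple, inst, alpha) {
  if (!is_prob(alpha)) stop_input("alpha must be a single number in [0, 1]")
  if (length(triple) != 3L) stop_contract("triple must list exactly 3 pairs")
  ci <- compile_instance(inst)
  mi <- mapping_to_int(mapping, ci)
  xs <- vapply(triple, function(e) pair_index(ci, mi$mapx, e)[1L], integer(1))
  if (anyDuplicated(xs)) stop_contract("triple contains duplicate pairs")
  best <- best3_int(ci, mi$mapx, xs, alpha)
  ys_new <- mi$mapx[xs][best$perm]
  list(
    pairs = cbind(x = ci$xids[xs], y = ci$yids[ys_new]),
    delta = best$delta
  )
}

# ---- integer-level move evaluation -----------------------------------------

pair_index <- function(ci, mapx, e) {
  xi <- match(e[[1L]], ci$xids)
  yi <- match(e[[2L]], ci$yids)
  if (is.na(xi) || is.na(yi) || mapx[xi] != yi) {
    stop_contract("pair (", e[[1L]], ", ", e[[2L]], ") is not in the mapping")
  }
  c(xi, yi)
}

delta2_int <- function(ci, mapx, x1, x2, alpha) {
  y1 <- mapx[x1]; y2 <- mapx[x2]
  ds <- ci$S[x1, y2] + ci$S[x2, y1] - ci$S[x1, y1] - ci$S[x2, y2]
  dc <- 0L
  nb <- ci$adjx[[x1]]
  if (length(nb) > 0L) {
    f <- mapx[nb[nb != x2]]
    f <- f[f > 0L]
    if (length(f) > 0L) {
      dc <- dc + sum(f %in% ci$adjy[[y2]]) - sum(f %in% ci$adjy[[y1]])
    }
  }
  nb <- ci$adjx[[x2]]
  if (length(nb) > 0L) {
    f <- mapx[nb[nb != x1]]
    f <- f[f > 0L]
    if (length(f) > 0L) {
      dc <- dc + sum(f %in% ci$adjy[[y1]]) - sum(f %in% ci$adjy[[y2]])
    }
  }
  alpha * 2 * dc + (1 - alpha) * ds
}

delta_unm_int <- function(ci, mapx, x1, ynew, alpha) {
  y1 <- mapx[x1]
  ds <- ci$S[x1, ynew] - ci$S[x1, y1]
  dc <- 0L
  nb <- ci$adjx[[x1]]
  if (length(nb) > 0L) {
    f <- mapx[nb]
    f <- f[f > 0L]
    if (length(f) > 0L) {
      dc <- sum(f %in% ci$adjy[[ynew]]) - sum(f %in% ci$adjy[[y1]])
    }
  }
  alpha * 2 * dc + (1 - alpha) * ds
}

# conserved X-edges incident to the x-vertices in `trio`, each counted once
local_conserved <- function(ci, mapx, trio) {
  cnt <- 0L
  for (xi in trio) {
    yi <- mapx[xi]
    if (yi == 0L) next
    ayi <- ci$adjy[[yi]]
    for (u in ci$adjx[[xi]]) {
      if (u %in% trio && u < xi) next   # already counted from the other side
      fu <- mapx[u]
      if (fu > 0L && fu %in% ayi) cnt <- cnt + 1L
    }
  }
  cnt
}

# the five non-identity reassignments of three y-endpoints among three x's
PERMS3 <- list(c(2L, 1L, 3L), c(3L, 2L, 1L), c(1L, 3L, 2L),
               c(2L, 3L, 1L), c(3L, 1L, 2L))

best3_int <- function(ci, mapx, xs, alpha) {
  ys <- mapx[xs]
  s_base <- ci$S[cbind(xs, ys)]
  c_base <- local_conserved(ci, mapx, xs)
  best_delta <- -Inf
  best_perm <- NULL
  for (perm in PERMS3) {
    ys_new <- ys[perm]
    mapx2 <- mapx
    mapx2[xs] <- ys_new
    ds <- sum(ci$S[cbind(xs, ys_new)]) - sum(s_base)
    dc <- local_conserved(ci, mapx2, xs) - c_base
    d <- alpha * 2 * dc + (1 - alpha) * ds
    if (d > best_delta) {
      best_delta <- d
      best_perm <- perm
    }
  }
  list(delta = best_delta, perm = best_perm)
}

# ---- the refinement loop ---------------------------------------------------

# Scan for the first strictly improving admissible move. Returns NULL or a
# move descriptor. Deterministic: x-pairs in x-identifier order, then y-side,
# candidates in rank order; `order_x`/`order_y` permute the scan when a seed
# is given. 3-Opt triples are scanned only after the 2-level scan finds
# nothing, capped at 10 * |M| triples per scan.
scan_improving <- function(st) {
  ci <- st$ci; mapx <- st$mapx; mapy <- st$mapy
  alpha <- st$alpha; tol <- st$tol
  for (x1 in st$order_x) {
    y1 <- mapx[x1]
    if (y1 == 0L) next
    for (yc in st$candx[[x1]]) {
      if (yc == y1) next
      x2 <- mapy[yc]
      if (x2 > 0L) {
        d <- delta2_int(ci, mapx, x1, x2, alpha)
        if (d > tol) return(list(kind = "swap2", x1 = x1, x2 = x2, delta = d))
      } else if (st$allow_unmatched) {
        d <- delta_unm_int(ci, mapx, x1, yc, alpha)
        if (d > tol) return(list(kind = "reassign", x1 = x1, ynew = yc, delta = d))
      }
    }
  }
  for (y1 in st$order_y) {
    x1 <- mapy[y1]
    if (x1 == 0L) next
    for (xc in st$candy[[y1]]) {
      if (xc == x1) next
      if (mapx[xc] > 0L) {
        d <- delta2_int(ci, mapx, x1, xc, alpha)
        if (d > tol) return(list(kind = "swap2", x1 = x1, x2 = xc, delta = d))
      }
    }
  }
  if (st$opt_order >= 3L) {
    n_matched <- sum(mapx > 0L)
    cap <- 10L * max(n_matched, 1L)
    tried <- 0L
    for (pair12 in admissible_pairs(st)) {
      x1 <- pair12[1L]; x2 <- pair12[2L]
      y1 <- mapx[x1]; y2 <- mapx[x2]
      thirds <- third_edges(st, x1, x2, y1, y2)
      for (x3 in thirds) {
        tried <- tried + 1L
        if (tried > cap) return(NULL)
        best <- best3_int(ci, mapx, c(x1, x2, x3), alpha)
        if (best$delta > tol) {
          return(list(kind = "swap3", xs = c(x1, x2, x3), perm = best$perm,
                      delta = best$delta))
        }
      }
    }
  }
  NULL
}

# admissible 2-swap (x1, x2) pairs in deterministic scan order
admissible_pairs <- function(st) {
  mapx <- st$mapx; mapy <- st$mapy
  out <- list()
  seen <- character()
  push <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    if (!(key %in% seen)) {
      seen <<- c(seen, key)
      out[[length(out) + 1L]] <<- c(a, b)
    }
  }
  for (x1 in st$order_x) {
    if (mapx[x1] == 0L) next
    for (yc in st$candx[[x1]]) {
      x2 <- mapy[yc]
      if (x2 > 0L && x2 != x1) push(x1, x2)
    }
  }
  for (y1 in st$order_y) {
    x1 <- mapy[y1]
    if (x1 == 0L) next
    for (xc in st$candy[[y1]]) {
      if (xc != x1 && mapx[xc] > 0L) push(x1, xc)
    }
  }
  out
}

# matched third x-vertices adjacent (in X, or via Y adjacency of the images)
# to the four vertices touched by the 2-swap
third_edges <- function(st, x1, x2, y1, y2) {
  mapy <- st$mapy
  xs <- c(st$ci$adjx[[x1]], st$ci$adjx[[x2]])
  ys <- c(st$ci$adjy[[y1]], st$ci$adjy[[y2]])
  xs <- c(xs, mapy[ys][mapy[ys] > 0L])
  xs <- sort.int(unique(xs))
  xs <- xs[xs != x1 & xs != x2 & st$mapx[xs] > 0L]
  xs
}

apply_move <- function(st, mv) {
  if (mv$kind == "swap2") {
    y1 <- st$mapx[mv$x1]; y2 <- st$mapx[mv$x2]
    st$mapx[mv$x1] <- y2; st$mapx[mv$x2] <- y1
    st$mapy[y1] <- mv$x2; st$mapy[y2] <- mv$x1
  } else if (mv$kind == "reassign") {
    y1 <- st$mapx[mv$x1]
    st$mapx[mv$x1] <- mv$ynew
    st$mapy[y1] <- 0L
    st$mapy[mv$ynew] <- mv$x1
  } else {
    ys <- st$mapx[mv$xs]
    ys_new <- ys[mv$perm]
    st$mapx[mv$xs] <- ys_new
    st$mapy[ys_new] <- mv$xs
  }
  st
}

build_state <- function(m0, inst, alpha, candidates, mode, c, opt_order,
                        max_iterations, allow_unmatched, seed, tol) {
  ci <- compile_instance(inst)
  mi <- mapping_to_int(m0, ci)
  if (identical(alpha, "auto")) alpha <- auto_alpha(m0, inst)
  if (!is_prob(alpha)) stop_input("alpha must be 'auto' or a number in [0, 1]")
  if (is.null(candidates)) {
    candidates <- build_candidates(inst, mode = mode, c = c)
  }
  stopifnot(inherits(candidates, "candidate_index"))
  candx <- lapply(ci$xids, function(id) {
    v <- match(candidates$for_x[[id]], ci$yids)
    v[!is.na(v)]
  })
  candy <- lapply(ci$yids, function(id) {
    v <- match(candidates$for_y[[id]], ci$xids)
    v[!is.na(v)]
  })
  order_x <- seq_len(ci$nx)
  order_y <- seq_len(ci$ny)
  if (!is.null(seed)) {
    with_seed(seed, {
      order_x <- sample(order_x)
      order_y <- sample(order_y)
    })
  }
  list(ci = ci, mapx = mi$mapx, mapy = mi$mapy, alpha = alpha,
       candx = candx, candy = candy, candidates = candidates,
       order_x = order_x, order_y = order_y,
       opt_order = as.integer(opt_order),
       max_iterations = as.integer(max_iterations),
       allow_unmatched = isTRUE(allow_unmatched), tol = tol)
}

#' Refine an alignment by 2-Opt / 3-Opt local search
#'
#' The main entry point. Starting from an initial mapping `m0` (for example
#' [initial_matching()], or any third-party aligner's output read with
#' [read_mapping()]), repeatedly applies the first strictly improving
#' admissible move — a 2-Opt partner swap, a reassignment to an unmatched
#' vertex, or (for `opt_order = 3`) a 3-Opt reassignment of a triple — until
#' a full scan finds no improving move (a local optimum of the objective
#' [alignment_objective()]) or the iteration cap is reached.
#'
#' Moves are admissible only when the newly introduced partner lies in the
#' corresponding candidate list (see [build_candidates()]). The scan is
#' deterministic (pairs in identifier order, candidates best-first); `seed`
#' optionally shuffles the scan order for robustness studies. An improvement
#' must exceed `tol` to be accepted, so ties are never taken and the
#' objective trajectory is strictly increasing, which guarantees termination.
#'
#' @param m0 initial [alignment_mapping()].
#' @param inst an [alignment_instance()].
#' @param alpha topology weight in `[0, 1]`, or `"auto"` (default) for the
#'   rule of [auto_alpha()].
#' @param candidates a [build_candidates()] index, or `NULL` to build one
#'   from `mode` and `c`.
#' @param mode candidate ranking mode when `candidates` is `NULL`:
#'   `"sequence"` (default) or `"topology"` (for sequence-free alignments).
#' @param c candidate list size (default 20).
#' @param opt_order 2 for pair swaps only, 3 to add triple moves (default 2).
#' @param max_iterations cap on accepted moves (default 10000).
#' @param allow_unmatched also consider reassignments to unmatched Y vertices
#'   (default `TRUE`).
#' @param seed optional integer; shuffles the scan order only.
#' @param tol minimal accepted improvement (default 1e-9).
#' @return An object of class `refine_result` with fields `mapping` (the
#'   refined [alignment_mapping()]), `swap_count`, `objective_trajectory`
#'   (length `swap_count + 1`, starting at the initial objective),
#'   `terminated_by` (`"local_optimum"` or `"iteration_cap"`), `alpha`,
#'   `initial_objective`, `final_objective`, `moves` (a data frame logging
#'   each accepted move) and `params`.
#' @examples
#' net_x <- ppi_network(rbind(c("x1", "x2")), nodes = c("x1", "x2", "x3"))
#' net_y <- ppi_network(rbind(c("y1", "y2")), nodes = c("y1", "y2", "y3"))
#' sim <- similarity_store(
#'   x = c("x1", "x2", "x3", "x2", "x3"),
#'   y = c("y1", "y3", "y2", "y2", "y3"),
#'   score = c(1.0, 0.6, 0.6, 0.5, 0.5)
#' )
#' inst <- alignment_instance(net_x, net_y, sim)
#' m0 <- initial_matching(inst)
#' res <- refine_alignment(m0, inst, alpha = 0.5, c = 2)
#' res$swap_count            # 1
#' res$objective_trajectory  # 1.1 2.0
#' @export
refine_alignment <- function(m0, inst, alpha = "auto", candidates = NULL,
                             mode = c("sequence", "topology"), c = 20L,
                             opt_order = 2L, max_iterations = 10000L,
                             allow_unmatched = TRUE, seed = NULL,
                             tol = 1e-9) {
  mode <- match.arg(mode)
  if (!opt_order %in% c(2L, 3L)) stop_input("opt_order must be 2 or 3")
  if (!is_count(max_iterations)) stop_input("max_iterations must be a positive integer")
  st <- build_state(m0, inst, alpha, candidates, mode, c, opt_order,
                    max_iterations, allow_unmatched, seed, tol)
  w <- objective_int(st$ci, st$mapx, st$alpha)
  traj <- w
  moves <- list()
  swap_count <- 0L
  terminated <- "local_optimum"
  repeat {
    if (swap_count >= st$max_iterations) {
      terminated <- "iteration_cap"
      break
    }
    mv <- scan_improving(st)
    if (is.null(mv)) break
    st <- apply_move(st, mv)
    swap_count <- swap_count + 1L
    w <- w + mv$delta
    traj <- c(traj, w)
    moves[[swap_count]] <- data.frame(
      iteration = swap_count, kind = mv$kind, delta = mv$delta,
      stringsAsFactors = FALSE
    )
  }
  final_mapping <- int_to_mapping(st$mapx, st$ci)
  structure(list(
    mapping = final_mapping,
    swap_count = swap_count,
    objective_trajectory = traj,
    terminated_by = terminated,
    alpha = st$alpha,
    initial_objective = traj[1L],
    final_objective = objective_int(st$ci, st$mapx, st$alpha),
    moves = if (length(moves) > 0L) do.call(rbind, moves) else
      data.frame(iteration = integer(), kind = character(), delta = numeric()),
    params = list(mode = st$candidates$mode, c = st$candidates$c,
                  opt_order = st$opt_order, max_iterations = st$max_iterations,
                  allow_unmatched = st$allow_unmatched, seed = seed, tol = tol)
  ), class = "refine_result")
}

#' Certify a mapping as a local optimum
#'
#' Re-scans all admissible moves (same neighborhood definition as
#' [refine_alignment()]) and reports whether none improves the objective by
#' more than `tol`. Used as a post-hoc certificate of the refiner's
#' termination condition.
#'
#' @inheritParams refine_alignment
#' @param mapping the [alignment_mapping()] to certify.
#' @return `TRUE` if no admissible improving move exists, else `FALSE`.
#' @export
is_local_optimum <- function(mapping, inst, alpha, candidates = NULL,
                             mode = c("sequence", "topology"), c = 20L,
                             opt_order = 2L, allow_unmatched = TRUE,
                             seed = NULL, tol = 1e-9) {
  mode <- match.arg(mode)
  st <- build_state(mapping, inst, alpha, candidates, mode, c, opt_order,
                    1L, allow_unmatched, seed, tol)
  is.null(scan_improving(st))
}

#' @export
print.refine_result <- function(x, ...) {
  cat("Alignment refinement (2-Opt/3-Opt local search)\n")
  cat(sprintf("  alpha: %.4f   opt order: %d   candidate mode: %s (c = %d)\n",
              x$alpha, x$params$opt_order, x$params$mode, x$params$c))
  cat(sprintf("  swaps accepted: %d   terminated by: %s\n",
              x$swap_count, x$terminated_by))
  cat(sprintf("  objective: %.6g -> %.6g\n",
              x$initial_objective, x$final_objective))
  invisible(x)
}

#' @export
summary.refine_result <- function(object, ...) {
  kinds <- table(factor(object$moves$kind,
                        levels = c("swap2", "reassign", "swap3")))
  out <- list(
    alpha = object$alpha,
    swap_count = object$swap_count,
    moves_by_kind = kinds,
    terminated_by = object$terminated_by,
    initial_objective = object$initial_objective,
    final_objective = object$final_objective,
    improvement = object$final_objective - object$initial_objective,
    mapped_pairs = nrow(object$mapping)
  )
  class(out) <- "summary.refine_result"
  out
}

#' @export
print.summary.refine_result <- function(x, ...) {
  cat("Refinement summary\n")
  cat(sprintf("  mapped pairs: %d\n", x$mapped_pairs))
  cat(sprintf("  alpha: %.4f\n", x$alpha))
  cat(sprintf("  accepted moves: %d (%s)\n", x$swap_count,
              paste(sprintf("%s: %d", names(x$moves_by_kind), x$moves_by_kind),
                    collapse = ", ")))
  cat(sprintf("  objective: %.6g -> %.6g (+%.6g)\n",
              x$initial_objective, x$final_objective, x$improvement))
  cat(sprintf("  terminated by: %s\n", x$terminated_by))
  invisible(x)
}

#' Plot the objective trajectory of a refinement
#'
#' @param x a `refine_result`.
#' @param ... passed to [plot.default()].
#' @return `x`, invisibly.
#' @export
plot.refine_result <- function(x, ...) {
  plot(seq_along(x$objective_trajectory) - 1L, x$objective_trajectory,
       type = "s", xlab = "accepted move", ylab = "objective w(M)", ...)
  graphics::points(seq_along(x$objective_trajectory) - 1L,
                   x$objective_trajectory, pch = 16, cex = 0.6)
  invisible(x)
}
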