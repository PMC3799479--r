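test_that("candidate lists rank by score with truncation and ties by identifier", {
  tb <- toy_b()
  c2 <- build_candidates(tb$inst, mode = "sequence", c = 2)
  expect_equal(c2$for_x[["x2"]], c("y3", "y2"))
  c1 <- build_candidates(tb$inst, mode = "sequence", c = 1)
  expect_equal(c1$for_x[["x2"]], "y3")
  expect_equal(c2$for_y[["y3"]], c("x2", "x3"))  # 0.6 then 0.5
  expect_error(build_candidates(tb$inst, c = 0), class = "swapalign_input_error")
})

test_that("topology-mode candidates rank by degree agreement", {
  # deg(x1) = 3; y-degrees 3, 1, 5 -> closest degree first
  net_x <- ppi_network(rbind(c("x1", "a"), c("x1", "b"), c("x1", "c")))
  ey <- rbind(c("y1", "p1"), c("y1", "p2"), c("y1", "p3"),
              c("y2", "p1"))
  for (k in 1:5) ey <- rbind(ey, c("y3", paste0("q", k)))
  net_y <- ppi_network(ey)
  idx <- build_candidates(alignment_instance(net_x, net_y), mode = "topology", c = 3)
  expect_equal(idx$for_x[["x1"]][1L], "y1")
})

test_that("2-swap delta matches the hand-computed toy and is an involution", {
  tb <- toy_b()
  d <- swap_delta_2(tb$m0, c("x2", "y3"), c("x3", "y2"), tb$inst, 0.5)
  expect_equal(d, 0.9)
  # swapping back undoes the gain exactly
  m1 <- alignment_mapping(c("x1", "x2", "x3"), c("y1", "y2", "y3"))
  d_back <- swap_delta_2(m1, c("x2", "y2"), c("x3", "y3"), tb$inst, 0.5)
  expect_equal(d + d_back, 0)
  expect_error(swap_delta_2(tb$m0, c("x2", "y3"), c("x2", "y3"), tb$inst, 0.5),
               class = "swapalign_contract_error")
  expect_error(swap_delta_2(tb$m0, c("x1", "y9"), c("x2", "y3"), tb$inst, 0.5),
               class = "swapalign_contract_error")
})

test_that("no swap improves a max-weight matching at alpha = 0", {
  for (seed in 1:20) {
    inst <- random_instance(seed)
    m0 <- initial_matching(inst)
    if (nrow(m0) < 2L) next
    for (i in seq_len(nrow(m0) - 1L)) {
      d <- swap_delta_2(m0, c(m0$x[i], m0$y[i]),
                        c(m0$x[i + 1L], m0$y[i + 1L]), inst, 0)
      expect_lte(d, 1e-12)
    }
  }
})

test_that("unmatched-target reassignment delta matches hand computation", {
  net_x <- ppi_network(rbind(c("x1", "x2")))
  net_y <- ppi_network(rbind(c("y1", "y2")), nodes = c("y1", "y2", "y3"))
  sim <- similarity_store(c("x1", "x2", "x2"), c("y1", "y3", "y2"),
                          c(0.9, 1.0, 0.8))
  inst <- alignment_instance(net_x, net_y, sim)
  m0 <- alignment_mapping(c("x1", "x2"), c("y1", "y3"))
  expect_equal(swap_delta_unmatched(m0, c("x2", "y3"), "y2", inst, 0.5), 0.9)
  # alpha = 0 reduces to the score difference
  expect_equal(swap_delta_unmatched(m0, c("x2", "y3"), "y2", inst, 0),
               0.8 - 1.0)
  # zero-score, zero-topology target strictly loses
  expect_lt(swap_delta_unmatched(alignment_mapping("x1", "y1"),
                                 c("x1", "y1"), "y3", inst, 0.5), 0)
  expect_error(swap_delta_unmatched(m0, c("x2", "y3"), "y1", inst, 0.5),
               class = "swapalign_contract_error")
})

test_that("the best 3-Opt move on the 3-cycle toy is the cycle to identity", {
  tc <- toy_c()
  trip <- list(c("x1", "y2"), c("x2", "y3"), c("x3", "y1"))
  mv <- best_3opt_move(tc$m0, trip, tc$inst, 0.5)
  expect_equal(mv$delta, 0.4)
  got <- mv$pairs[order(mv$pairs[, "x"]), ]
  expect_equal(unname(got[, "y"]), c("y1", "y2", "y3"))
  # each of the three pairwise swaps is non-improving
  combs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  for (cmb in combs) {
    d <- swap_delta_2(tc$m0, trip[[cmb[1L]]], trip[[cmb[2L]]], tc$inst, 0.5)
    expect_lte(d, 0)
  }
  expect_error(best_3opt_move(tc$m0, list(trip[[1]], trip[[1]], trip[[2]]),
                              tc$inst, 0.5),
               class = "swapalign_contract_error")
})

test_that("incremental deltas equal full objective recomputation", {
  n_checked <- 0L
  for (seed in 1:120) {
    inst <- random_instance(seed)
    m <- random_mapping(inst, seed + 5000)
    if (nrow(m) < 2L) next
    set.seed(seed)
    alpha <- runif(1)
    w0 <- alignment_objective(m, inst, alpha)
    ij <- sample(nrow(m), 2L)
    e1 <- c(m$x[ij[1L]], m$y[ij[1L]])
    e2 <- c(m$x[ij[2L]], m$y[ij[2L]])
    d <- swap_delta_2(m, e1, e2, inst, alpha)
    xs <- m$x; ys <- m$y
    ys[ij] <- ys[rev(ij)]
    w1 <- alignment_objective(alignment_mapping(xs, ys), inst, alpha)
    expect_equal(d, w1 - w0, tolerance = 1e-12)
    n_checked <- n_checked + 1L
    # unmatched move, when a free y exists
    free <- setdiff(inst$net_y$nodes, m$y)
    if (length(free) > 0L) {
      du <- swap_delta_unmatched(m, e1, free[1L], inst, alpha)
      ys2 <- m$y; ys2[ij[1L]] <- free[1L]
      wu <- alignment_objective(alignment_mapping(m$x, ys2), inst, alpha)
      expect_equal(du, wu - w0, tolerance = 1e-12)
    }
  }
  expect_gte(n_checked, 50L)
})

test_that("refinement solves the toy instances as hand-traced", {
  tb <- toy_b()
  res <- refine_alignment(tb$m0, tb$inst, alpha = 0.5, c = 2, opt_order = 2)
  expect_equal(res$swap_count, 1L)
  expect_equal(res$objective_trajectory, c(1.1, 2.0))
  expect_equal(res$terminated_by, "local_optimum")
  expect_equal(as.data.frame(res$mapping),
               data.frame(x = c("x1", "x2", "x3"), y = c("y1", "y2", "y3")))

  tc <- toy_c()
  r2 <- refine_alignment(tc$m0, tc$inst, alpha = 0.5, opt_order = 2)
  expect_equal(r2$swap_count, 0L)
  r3 <- refine_alignment(tc$m0, tc$inst, alpha = 0.5, opt_order = 3)
  expect_equal(r3$swap_count, 1L)
  expect_equal(r3$final_objective, 2.9)
})

test_that("refinement from the max-weight matching at alpha = 0 makes no swaps", {
  for (seed in 1:10) {
    inst <- random_instance(seed)
    m0 <- initial_matching(inst)
    res <- refine_alignment(m0, inst, alpha = 0, opt_order = 3)
    expect_equal(res$swap_count, 0L)
  }
})

test_that("trajectories increase strictly and certify local optimality", {
  for (seed in 1:30) {
    inst <- random_instance(seed)
    m0 <- initial_matching(inst)
    set.seed(seed); alpha <- runif(1)
    res <- refine_alignment(m0, inst, alpha = alpha, opt_order = 3,
                            c = max(2L, n_nodes(inst$net_y)))
    traj <- res$objective_trajectory
    expect_length(traj, res$swap_count + 1L)
    if (length(traj) > 1L) expect_true(all(diff(traj) > 1e-9))
    expect_equal(res$final_objective, traj[length(traj)], tolerance = 1e-9)
    expect_equal(res$terminated_by, "local_optimum")
    expect_true(is_local_optimum(res$mapping, inst, alpha = alpha,
                                 opt_order = 3,
                                 c = max(2L, n_nodes(inst$net_y))))
  }
})

test_that("3-Opt refinement never finishes below 2-Opt from the same start", {
  fixtures <- list(toy_b(), toy_c())
  for (f in fixtures) {
    r2 <- refine_alignment(f$m0, f$inst, alpha = 0.5, opt_order = 2)
    r3 <- refine_alignment(f$m0, f$inst, alpha = 0.5, opt_order = 3)
    expect_gte(r3$final_objective, r2$final_objective - 1e-12)
  }
  for (seed in 1:25) {
    inst <- random_instance(seed)
    m0 <- initial_matching(inst)
    set.seed(seed); alpha <- runif(1)
    r2 <- refine_alignment(m0, inst, alpha = alpha, opt_order = 2)
    r3 <- refine_alignment(m0, inst, alpha = alpha, opt_order = 3)
    expect_gte(r3$final_objective, r2$final_objective - 1e-12)
  }
})

test_that("refined objective lies between the start and the global optimum", {
  for (seed in 1:40) {
    inst <- random_instance(seed, nx = sample(2:5, 1), ny = sample(2:5, 1))
    m0 <- initial_matching(inst)
    set.seed(seed); alpha <- runif(1)
    res <- refine_alignment(m0, inst, alpha = alpha, opt_order = 3,
                            c = n_nodes(inst$net_y) + 1L)
    w_star <- brute_force_best_objective(inst, alpha)
    expect_gte(res$final_objective, res$initial_objective - 1e-12)
    expect_lte(res$final_objective, w_star + 1e-9)
  }
})

test_that("the iteration cap terminates the loop and is flagged", {
  tb <- toy_b()
  # force at least one improving move available but cap at. . . the cap bites
  res <- refine_alignment(tb$m0, tb$inst, alpha = 0.5, c = 2,
                          max_iterations = 1)
  expect_lte(res$swap_count, 1L)
  # on an instance needing >1 move the cap is reported
  for (seed in 1:50) {
    inst <- random_instance(seed)
    m0 <- initial_matching(inst)
    full <- refine_alignment(m0, inst, alpha = 0.9, opt_order = 2)
    if (full$swap_count >= 2L) {
      capped <- refine_alignment(m0, inst, alpha = 0.9, opt_order = 2,
                                 max_iterations = 1)
      expect_equal(capped$swap_count, 1L)
      expect_equal(capped$terminated_by, "iteration_cap")
      break
    }
  }
})

test_that("result methods print, summarise and plot", {
  tb <- toy_b()
  res <- refine_alignment(tb$m0, tb$inst, alpha = 0.5, c = 2)
  expect_output(print(res), "swaps accepted: 1")
  s <- summary(res)
  expect_output(print(s), "accepted moves: 1")
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f)
  expect_silent(plot(res))
  grDevices::dev.off()
  expect_true(file.exists(f))
})
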