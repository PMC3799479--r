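test_that("score symmetrization keeps the maximum of the two orientations", {
  s <- similarity_store(c("x", "y"), c("y", "x"), c(3, 5))
  sym <- symmetrize_scores(s)
  expect_equal(n_pairs(sym), 1L)
  expect_equal(sim_score(sym, "x", "y"), 5)
  expect_equal(sim_score(sym, "y", "x"), 5)

  s1 <- symmetrize_scores(similarity_store("x", "y", 3))
  expect_equal(sim_score(s1, "x", "y"), 3)

  expect_equal(n_pairs(symmetrize_scores(similarity_store())), 0L)
})

test_that("normalization scales by the global maximum and is idempotent", {
  s <- similarity_store(c("x1", "x2"), c("y1", "y2"), c(2, 4))
  ns <- normalize_scores(s)
  expect_equal(sim_score(ns, "x1", "y1"), 0.5)
  expect_equal(sim_score(ns, "x2", "y2"), 1.0)

  s1 <- normalize_scores(similarity_store("a", "b", 7))
  expect_equal(sim_score(s1, "a", "b"), 1.0)

  expect_equal(normalize_scores(ns)$pairs, ns$pairs)
  expect_error(normalize_scores(similarity_store()),
               class = "swapalign_input_error")
})

test_that("initial matching maximizes total similarity on the 2x2 example", {
  net_x <- ppi_network(matrix(character(), ncol = 2), nodes = c("x1", "x2"))
  net_y <- ppi_network(matrix(character(), ncol = 2), nodes = c("y1", "y2"))
  sim <- similarity_store(c("x1", "x1", "x2", "x2"),
                          c("y1", "y2", "y1", "y2"), c(3, 1, 2, 4))
  inst <- alignment_instance(net_x, net_y, sim)
  m <- initial_matching(inst)
  expect_equal(as.data.frame(m),
               data.frame(x = c("x1", "x2"), y = c("y1", "y2")))
  expect_equal(sequence_score(m, inst), 7)

  single <- alignment_instance(net_x, net_y, similarity_store("x1", "y2", 1))
  expect_equal(as.data.frame(initial_matching(single)),
               data.frame(x = "x1", y = "y2"))

  empty <- alignment_instance(net_x, net_y, similarity_store())
  expect_equal(nrow(initial_matching(empty)), 0L)
})

test_that("initial matching equals the brute-force optimum on random instances", {
  for (seed in 1:60) {
    inst <- random_instance(seed)
    m <- initial_matching(inst)
    expect_equal(sequence_score(m, inst), brute_force_best_weight(inst),
                 tolerance = 1e-9)
  }
})

test_that("normalization preserves the optimal matching as a set of pairs", {
  for (seed in 1:20) {
    inst <- random_instance(seed)
    if (n_pairs(inst$sim) == 0L) next
    inst_n <- alignment_instance(inst$net_x, inst$net_y,
                                 normalize_scores(inst$sim))
    expect_identical(as.data.frame(initial_matching(inst)),
                     as.data.frame(initial_matching(inst_n)))
  }
})

test_that("auto alpha implements the half-weight rule", {
  # closed form on constructed score splits: alpha* = 2 S0 / (2 S0 + T0)
  tb <- toy_b()
  m_id <- alignment_mapping(c("x1", "x2", "x3"), c("y1", "y2", "y3"))
  s0 <- sequence_score(m_id, tb$inst)   # 2.0
  t0 <- topology_total(m_id, tb$inst)   # 2
  expect_equal(auto_alpha(m_id, tb$inst), 2 * s0 / (2 * s0 + t0))

  # S0 = 10, T0 = 20 -> 0.5 and S0 = 10, T0 = 5 -> 0.8 via scaled instances
  mk <- function(s0, t_edges) {
    # a path of t_edges + 1 matched pairs in both networks gives T0 = 2 * t_edges
    n <- t_edges + 1L
    xids <- paste0("x", seq_len(n)); yids <- paste0("y", seq_len(n))
    ex <- cbind(xids[-n], xids[-1L])
    ey <- cbind(yids[-n], yids[-1L])
    sim <- similarity_store(xids, yids, rep(s0 / n, n))
    inst <- alignment_instance(ppi_network(ex), ppi_network(ey), sim)
    list(inst = inst, m = alignment_mapping(xids, yids))
  }
  f <- mk(10, 10L)  # T0 = 20
  expect_equal(auto_alpha(f$m, f$inst), 0.5)
  # T0 = 0: no edges conserved -> pre-clamp 1, clamped to 0.99
  net_x <- ppi_network(matrix(character(), ncol = 2), nodes = "x1")
  net_y <- ppi_network(matrix(character(), ncol = 2), nodes = "y1")
  inst0 <- alignment_instance(net_x, net_y, similarity_store("x1", "y1", 1))
  expect_equal(auto_alpha(alignment_mapping("x1", "y1"), inst0), 0.99)
  # S0 = 0: sequence-free regime, alpha = 1
  inst_nos <- alignment_instance(net_x, net_y, similarity_store())
  expect_equal(auto_alpha(alignment_mapping("x1", "y1"), inst_nos), 1)
})

test_that("auto alpha balances realized contributions two-to-one", {
  for (seed in 1:30) {
    inst <- random_instance(seed)
    m <- random_mapping(inst, seed + 3000)
    s0 <- sequence_score(m, inst)
    if (s0 <= 0) next
    t0 <- topology_total(m, inst)
    a_raw <- 2 * s0 / (2 * s0 + t0)
    expect_equal(a_raw * t0, 2 * (1 - a_raw) * s0, tolerance = 1e-12)
  }
})
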