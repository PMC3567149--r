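subopt_fixture <- function(seed = 900) {
  # a graph rich enough that removing optimal nodes leaves alternatives
  inst <- random_instance(n = 12, max_edges = 16, seed = seed, beta = 1.5)
  opt <- solve_exact(inst)
  list(inst = inst, opt = opt)
}

test_that("suboptimal solutions exclude the required node count", {
  fx <- subopt_fixture()
  k <- ceiling(0.15 * length(fx$opt$nodes))
  subs <- suppressWarnings(
    solve_suboptimal(fx$inst, fx$opt, fraction = 0.15, n_solutions = 5,
                     seed = 2, solver = "exact"))
  expect_gt(length(subs), 0L)
  for (s in subs) {
    expect_gte(length(setdiff(fx$opt$nodes, s$nodes)), k)
    expect_gte(s$objective, fx$opt$objective - 1e-9)
    expect_equal(pcst_objective(fx$inst, s), s$objective, tolerance = 1e-9)
  }
  # sorted by objective
  objs <- vapply(subs, `[[`, numeric(1), "objective")
  expect_equal(objs, sort(objs))
})

test_that("fraction zero returns copies of the optimal solution", {
  fx <- subopt_fixture()
  subs <- solve_suboptimal(fx$inst, fx$opt, fraction = 0, n_solutions = 3,
                           seed = 1)
  expect_length(subs, 3L)
  for (s in subs) expect_equal(s$nodes, fx$opt$nodes)
})

test_that("a 10-node optimum at fraction 0.15 must drop at least 2 nodes", {
  expect_equal(ceiling(0.15 * 10), 2)
  fx <- subopt_fixture(seed = 905)
  if (length(fx$opt$nodes) >= 10) {
    subs <- suppressWarnings(
      solve_suboptimal(fx$inst, fx$opt, n_solutions = 3, seed = 3,
                       solver = "exact"))
    for (s in subs)
      expect_gte(length(setdiff(fx$opt$nodes, s$nodes)),
                 ceiling(0.15 * length(fx$opt$nodes)))
  }
})

test_that("composites are unions with multiplicities and contain the optimum", {
  fx <- subopt_fixture()
  # zero suboptimals: composite == optimal with multiplicity 1
  c0 <- merge_solutions(fx$opt, list())
  expect_setequal(c0$nodes$node, fx$opt$nodes)
  expect_true(all(c0$nodes$multiplicity == 1L))
  # duplicated solution doubles multiplicities, same topology
  c2 <- merge_solutions(fx$opt, list(fx$opt))
  expect_setequal(c2$nodes$node, fx$opt$nodes)
  expect_true(all(c2$nodes$multiplicity == 2L))
  expect_equal(nrow(c2$edges), nrow(c0$edges))
  # overlap arithmetic on hand-built solutions
  g <- toy_graph(c("A", "A"), c("B", "C"), c(0.9, 0.8))
  inst <- pcst_instance(g, c(A = 5, B = 5, C = 5), beta = 1)
  s_ab <- prizelink:::solution_network(inst, c("A", "B"),
                                       prizelink:::edge_rows(g, "A", "B"),
                                       "exact")
  s_ac <- prizelink:::solution_network(inst, c("A", "C"),
                                       prizelink:::edge_rows(g, "A", "C"),
                                       "exact")
  cm <- merge_solutions(s_ab, list(s_ac))
  expect_setequal(cm$nodes$node, c("A", "B", "C"))
  expect_equal(cm$nodes$multiplicity[cm$nodes$node == "A"], 2L)
  expect_equal(cm$nodes$multiplicity[cm$nodes$node == "B"], 1L)
  # composite contains every suboptimal's nodes too
  subs <- suppressWarnings(
    solve_suboptimal(fx$inst, fx$opt, n_solutions = 4, seed = 5,
                     solver = "exact"))
  comp <- merge_solutions(fx$opt, subs)
  expect_true(all(fx$opt$nodes %in% comp$nodes$node))
  expect_lte(max(comp$nodes$multiplicity), 1L + length(subs))
})

test_that("the beta sweep spans empty to all-termini networks", {
  inst <- random_instance(9, 13, seed = 910, beta = 1)
  g <- inst$graph
  pen <- inst$penalty[inst$penalty > 0]
  # beta below any cost/penalty scale: empty network
  lo <- min(g$edges$cost) / sum(pen) / 10
  # beta above sum of costs over the smallest penalty: everything reachable
  hi <- sum(g$edges$cost) / min(pen) * 10
  sweep <- beta_sweep(g, pen, betas = c(lo, hi), solver = "exact")
  # at negligible beta no edge is worth paying for; the solution is at
  # most a single free node (a singleton always weakly beats the empty
  # tree, since it pays one penalty fewer and costs nothing)
  expect_lte(sweep$n_nodes[1], 1L)
  expect_equal(sweep$n_edges[1], 0L)
  comp <- igraph::components(prizelink:::as_igraph(g))$membership
  comp_sizes <- table(comp[names(pen)])
  reachable <- max(comp_sizes)   # termini sharing the largest component
  expect_gte(sweep$n_termini_included[2], reachable)
  # efficiency ratio definition
  with_steiner <- data.frame(beta = 1, n_nodes = 25, n_edges = 24,
                             n_termini_included = 20, n_steiner = 5)
  expect_equal(with_steiner$n_termini_included / with_steiner$n_steiner, 4)
  expect_true(all(is.infinite(sweep$efficiency_ratio[sweep$n_steiner == 0])))
})
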