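test_that("objective closed forms hold for empty, singleton and path trees", {
  g <- toy_graph(c("A", "B"), c("B", "C"), exp(-c(1, 2)))  # costs 1 and 2
  inst <- pcst_instance(g, c(A = 5, C = 5), beta = 1)
  empty <- list(nodes = character(), edges = NULL)
  expect_equal(pcst_objective(inst, empty), 10)           # all penalties paid
  single <- list(nodes = "A", edges = NULL)
  expect_equal(pcst_objective(inst, single), 5)           # beta (sum p - p(A))
  path <- list(nodes = c("A", "B", "C"), edges = g$edges)
  expect_equal(pcst_objective(inst, path), 3)             # edge costs only
  # the full path beats the singleton, and solve_exact finds it
  sol <- solve_exact(inst)
  expect_equal(sol$objective, 3, tolerance = 1e-9)
  expect_equal(sol$nodes, c("A", "B", "C"))
  expect_equal(sol$steiner_nodes, "B")
  # invalid trees are rejected
  expect_error(pcst_objective(inst, list(nodes = c("A", "C"),
                                         edges = g$edges)), "not a tree")
  expect_error(pcst_objective(inst, list(nodes = "Z", edges = NULL)),
               "absent")
})

test_that("a single edge is collected iff its cost beats the penalties", {
  g <- toy_graph("A", "B", exp(-1))   # cost 1
  cheap <- pcst_instance(g, c(A = 2, B = 2), beta = 1)
  sol <- solve_exact(cheap)
  expect_equal(sol$nodes, c("A", "B"))
  expect_equal(sol$objective, 1)
  # dominated edge: cost larger than any reachable penalty sum
  dear <- pcst_instance(g, c(A = 0.3, B = 0.3), beta = 1)
  sol2 <- solve_exact(dear)
  expect_lte(length(sol2$nodes), 1L)   # keep at most one node, no edge
  expect_equal(nrow(sol2$edges), 0L)
})

test_that("exact solver matches edge-subset brute force on random instances", {
  for (s in 1:12) {
    inst <- random_instance(n = sample(6:9, 1), max_edges = 12, seed = 400 + s)
    sol <- solve_exact(inst)
    expect_equal(sol$objective, pcst_brute_force(inst), tolerance = 1e-9)
    # returned objective is self-consistent
    expect_equal(pcst_objective(inst, sol), sol$objective, tolerance = 1e-9)
  }
})

test_that("ties break toward the lexicographically smallest node set", {
  # two symmetric termini joined through either of two equal-cost paths
  g <- toy_graph(c("A", "B", "A", "D"), c("B", "C", "D", "C"),
                 rep(exp(-0.5), 4))
  inst <- pcst_instance(g, c(A = 10, C = 10), beta = 1)
  sol <- solve_exact(inst)
  expect_equal(sol$nodes, c("A", "B", "C"))  # {A,B,C} < {A,C,D}
})

test_that("node input order does not change the solution", {
  inst <- random_instance(8, 12, seed = 77)
  e <- inst$graph$edges
  perm <- sample(nrow(e))
  g2 <- build_graph(e[perm, c("node_a", "node_b", "confidence")])
  inst2 <- pcst_instance(g2, inst$penalty[inst$penalty > 0], inst$beta)
  expect_equal(solve_exact(inst2)$nodes, solve_exact(inst)$nodes)
})

test_that("penalty scaling by lambda with beta/lambda leaves the tree fixed", {
  for (s in 1:5) {
    inst <- random_instance(8, 12, seed = 500 + s, beta = 1)
    lambda <- 3.7
    scaled <- pcst_instance(inst$graph, inst$penalty * lambda,
                            beta = inst$beta / lambda)
    expect_equal(solve_exact(scaled)$nodes, solve_exact(inst)$nodes)
  }
})

test_that("node_limit is enforced", {
  inst <- random_instance(10, 14, seed = 1)
  expect_error(solve_exact(inst, node_limit = 5), "node_limit")
})

test_that("heuristic solutions are valid trees within the trivial bounds", {
  for (s in 1:20) {
    inst <- random_instance(n = sample(8:12, 1), max_edges = 16,
                            seed = 600 + s)
    h <- solve_heuristic(inst, seed = s)
    # tree invariant is enforced by construction; objective self-consistent
    expect_equal(pcst_objective(inst, h), h$objective, tolerance = 1e-9)
    empty_obj <- inst$beta * sum(inst$penalty)
    best_single <- empty_obj - inst$beta * max(inst$penalty)
    expect_lte(h$objective, empty_obj + 1e-9)
    expect_lte(h$objective, best_single + 1e-9)
    # never better than the exact optimum, reproducible under the same seed
    expect_gte(h$objective, solve_exact(inst)$objective - 1e-9)
    expect_equal(solve_heuristic(inst, seed = s)$nodes, h$nodes)
  }
})

test_that("heuristic handles empty penalties and split components", {
  g <- toy_graph(c("A", "C"), c("B", "D"), c(0.9, 0.9))  # two components
  none <- pcst_instance(g, c(A = 0), beta = 1)
  expect_equal(length(solve_heuristic(none, 1)$nodes), 0L)
  split <- pcst_instance(g, c(A = 5, B = 5, C = 5, D = 5), beta = 1)
  sol <- solve_heuristic(split, 1)
  comp <- igraph::components(prizelink:::as_igraph(g))$membership
  expect_equal(length(unique(comp[sol$nodes])), 1L)  # confined to one side
})
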