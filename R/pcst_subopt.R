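#' Constrained suboptimal PCST solutions
#'
#' Generates alternative near-optimal networks by forcing each solution to
#' exclude at least `ceil(fraction * |V(optimal)|)` nodes of the optimal
#' solution: a forbidden node subset of that size is sampled (seeded,
#' duplicate subsets rejected), removed from the graph, and the instance is
#' re-solved. Objectives are evaluated against the *original* instance, so
#' every suboptimal objective is at least the optimal one, and solutions
#' are returned sorted by objective.
#'
#' @param instance a [pcst_instance()].
#' @param optimal the optimal `solution_network` (non-empty).
#' @param fraction fraction of optimal nodes each suboptimal solution must
#'   exclude (default 0.15). `fraction = 0` returns copies of the optimal
#'   solution.
#' @param n_solutions number of suboptimal solutions requested (default
#'   10).
#' @param seed integer seed for subset sampling.
#' @param solver,node_limit,n_roots solver settings, as in [solve_pcst()].
#' @return list of `solution_network` objects (possibly fewer than
#'   requested, with a warning, when re-solving is infeasible).
#' @export
solve_suboptimal <- function(instance, optimal, fraction = 0.15,
                             n_solutions = 10L, seed = 1L,
                             solver = c("heuristic", "exact"),
                             node_limit = 18L, n_roots = 3L) {
  solver <- match.arg(solver)
  if (length(optimal$nodes) == 0L) stop("optimal solution is empty")
  k <- ceiling(fraction * length(optimal$nodes))
  if (k == 0L) {
    return(replicate(n_solutions, optimal, simplify = FALSE))
  }
  sols <- list()
  seen <- character()
  local_seed(seed, {
    attempts <- 0L
    while (length(sols) < n_solutions && attempts < 20L * n_solutions) {
      attempts <- attempts + 1L
      forbidden <- sort(sample(optimal$nodes, k))
      sig <- paste(forbidden, collapse = ",")
      if (sig %in% seen) next
      seen <- c(seen, sig)
      sub_graph <- drop_nodes(instance$graph, forbidden)
      if (is.null(sub_graph)) next
      p <- instance$penalty
      p <- p[names(p) %in% sub_graph$nodes]
      sub_inst <- pcst_instance(sub_graph, p, instance$beta)
      sol <- tryCatch(
        solve_pcst(sub_inst, solver, seed = seed + attempts,
                   node_limit = node_limit, n_roots = n_roots),
        error = function(e) NULL)
      if (is.null(sol)) next
      # re-express against the original instance (pays forbidden penalties)
      sols[[length(sols) + 1L]] <- solution_network(
        instance, sol$nodes, sol$edges, solver = sol$solver)
    }
  })
  if (length(sols) < n_solutions)
    warning("only ", length(sols), " of ", n_solutions,
            " suboptimal solutions found")
  sols[order(vapply(sols, `[[`, numeric(1), "objective"))]
}

#' Merge optimal and suboptimal solutions into a composite network
#'
#' The composite is the union of nodes and edges across all solutions,
#' annotated with multiplicities (in how many solutions each node/edge
#' appears). It always contains the optimal solution.
#'
#' @param optimal the optimal `solution_network`.
#' @param suboptimals list of `solution_network` objects from
#'   [solve_suboptimal()] (may be empty).
#' @return a `composite_network`: list with `nodes` (data frame `node`,
#'   `multiplicity`) and `edges` (data frame `node_a`, `node_b`,
#'   `confidence`, `cost`, `multiplicity`).
#' @export
merge_solutions <- function(optimal, suboptimals = list()) {
  all_sols <- c(list(optimal), suboptimals)
  node_tab <- table(unlist(lapply(all_sols, `[[`, "nodes")))
  nodes <- data.frame(node = names(node_tab),
                      multiplicity = as.integer(node_tab),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$node), , drop = FALSE]
  edge_dfs <- lapply(all_sols, function(s) s$edges)
  edge_dfs <- edge_dfs[!vapply(edge_dfs, is.null, logical(1))]
  edges <- do.call(rbind, edge_dfs)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(node_a = character(), node_b = character(),
                        confidence = numeric(), cost = numeric(),
                        multiplicity = integer())
  } else {
    key <- paste(edges$node_a, edges$node_b, sep = "\r")
    mult <- table(key)
    edges <- edges[!duplicated(key), , drop = FALSE]
    edges$multiplicity <- as.integer(mult[paste(edges$node_a, edges$node_b,
                                                sep = "\r")])
    edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  }
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 n_solutions = length(all_sols)),
            class = "composite_network")
}

#' @export
print.composite_network <- function(x, ...) {
  cat("composite_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges from", x$n_solutions, "solutions\n")
  invisible(x)
}

#' Sweep the beta scaling parameter
#'
#' Solves the same instance across a grid of beta values with identical
#' solver settings and reports, per beta, the network size and the
#' efficiency ratio (included termini / Steiner nodes; `Inf` when there
#' are no Steiner nodes). Small beta yields the empty network (penalties
#' are negligible against edge costs); very large beta includes every
#' reachable terminus.
#'
#' @param graph a `weighted_graph`.
#' @param penalties penalties, as in [pcst_instance()].
#' @param betas positive beta values (default `seq(10, 120, by = 10)`).
#' @param solver,seed,node_limit,n_roots solver settings, as in
#'   [solve_pcst()].
#' @return data frame with one row per beta: `beta`, `n_nodes`,
#'   `n_edges`, `n_termini_included`, `n_steiner`, `efficiency_ratio`.
#' @export
beta_sweep <- function(graph, penalties, betas = seq(10, 120, by = 10),
                       solver = c("heuristic", "exact"), seed = 1L,
                       node_limit = 18L, n_roots = 3L) {
  solver <- match.arg(solver)
  stopifnot(length(betas) > 0L, all(betas > 0))
  rows <- lapply(betas, function(b) {
    sol <- solve_pcst(pcst_instance(graph, penalties, b), solver,
                      seed = seed, node_limit = node_limit,
                      n_roots = n_roots)
    n_t <- length(sol$included_termini)
    n_s <- length(sol$steiner_nodes)
    data.frame(beta = b, n_nodes = length(sol$nodes),
               n_edges = nrow(sol$edges), n_termini_included = n_t,
               n_steiner = n_s,
               efficiency_ratio = if (n_s > 0L) n_t / n_s else Inf)
  })
  do.call(rbind, rows)
}
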