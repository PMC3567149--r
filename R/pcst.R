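#' Assemble a prize-collecting Steiner tree instance
#'
#' Pairs a cost-weighted interactome with nonnegative node penalties and a
#' scaling parameter beta. Nodes with positive penalty are the termini;
#' all other nodes carry zero penalty and can only enter a solution as
#' Steiner nodes. The optimization seeks a subtree `T` minimizing
#' `beta * sum_{v not in T} p(v) + sum_{e in T} c(e)`.
#'
#' @param graph a `weighted_graph` from [build_graph()].
#' @param penalties named numeric vector of penalties, or a data frame
#'   with `protein_id` and `penalty` columns (an optional `source` column
#'   is retained for output typing).
#' @param beta positive scalar balancing excluded-penalty payments against
#'   edge costs; larger beta yields larger networks.
#' @return a `pcst_instance`: list with `graph`, `penalty` (full named
#'   vector over all nodes), `beta`, `termini` and `penalty_source`.
#' @export
pcst_instance <- function(graph, penalties, beta) {
  stopifnot(inherits(graph, "weighted_graph"), beta > 0)
  src <- NULL
  if (is.data.frame(penalties)) {
    if ("source" %in% names(penalties))
      src <- setNames(penalties$source, penalties$protein_id)
    penalties <- setNames(penalties$penalty, penalties$protein_id)
  }
  if (any(penalties < 0)) stop("penalties must be nonnegative")
  missing_nodes <- setdiff(names(penalties)[penalties > 0], graph$nodes)
  if (length(missing_nodes))
    stop("penalized node(s) absent from graph: ",
         paste(head(missing_nodes, 5), collapse = ", "))
  p <- setNames(numeric(length(graph$nodes)), graph$nodes)
  keep <- intersect(names(penalties), graph$nodes)
  p[keep] <- penalties[keep]
  structure(list(graph = graph, penalty = p, beta = beta,
                 termini = names(p)[p > 0], penalty_source = src),
            class = "pcst_instance")
}

#' @export
print.pcst_instance <- function(x, ...) {
  cat("pcst_instance:", length(x$graph$nodes), "nodes,",
      nrow(x$graph$edges), "edges,", length(x$termini),
      "termini, beta =", x$beta, "\n")
  invisible(x)
}

# build a solution_network, validating the tree invariant against the instance
solution_network <- function(instance, nodes, edges, solver,
                             is_optimal = FALSE) {
  nodes <- sort(nodes)
  if (is.null(edges) || length(nodes) == 0L) {
    edges <- instance$graph$edges[0, , drop = FALSE]
  }
  if (length(nodes) > 0L) {
    if (nrow(edges) != length(nodes) - 1L)
      stop("not a tree: |E| != |V| - 1")
    if (nrow(edges) > 0L) {
      g <- igraph::graph_from_data_frame(edges[, c("node_a", "node_b")],
                                         directed = FALSE,
                                         vertices = data.frame(name = nodes))
      if (igraph::components(g)$no != 1L) stop("not a tree: disconnected")
    }
  }
  p <- instance$penalty
  obj <- instance$beta * sum(p[setdiff(names(p), nodes)]) + sum(edges$cost)
  structure(list(nodes = nodes, edges = edges, objective = obj,
                 included_termini = intersect(nodes, instance$termini),
                 steiner_nodes = setdiff(nodes, instance$termini),
                 is_optimal = is_optimal, solver = solver),
            class = "solution_network")
}

#' @export
print.solution_network <- function(x, ...) {
  cat(sprintf(
    "solution_network (%s): %d nodes (%d termini, %d Steiner), %d edges, objective %.6g\n",
    x$solver, length(x$nodes), length(x$included_termini),
    length(x$steiner_nodes), nrow(x$edges), x$objective))
  invisible(x)
}

#' Objective value of a candidate tree
#'
#' `beta * sum_{v not in T} p(v) + sum_{e in T} c(e)`. The empty tree pays
#' every penalty; a single-node tree at a terminus `v` pays
#' `beta * (sum(p) - p(v))`.
#'
#' @param instance a [pcst_instance()].
#' @param tree a `solution_network`, or a list with `nodes` (character)
#'   and `edges` (data frame with `node_a`, `node_b` columns) describing a
#'   subtree of the instance graph.
#' @return numeric objective value.
#' @export
pcst_objective <- function(instance, tree) {
  nodes <- tree$nodes
  edges <- tree$edges
  if (!all(nodes %in% instance$graph$nodes))
    stop("tree contains nodes absent from the graph")
  ge <- instance$graph$edges
  gkey <- paste(ge$node_a, ge$node_b, sep = "\r")
  if (length(nodes)) {
    n_e <- if (is.null(edges)) 0L else nrow(edges)
    if (n_e != length(nodes) - 1L) stop("not a tree: |E| != |V| - 1")
  }
  ecost <- 0
  if (!is.null(edges) && nrow(edges) > 0L) {
    key <- paste(pmin(edges$node_a, edges$node_b),
                 pmax(edges$node_a, edges$node_b), sep = "\r")
    idx <- match(key, gkey)
    if (anyNA(idx)) stop("tree contains edges absent from the graph")
    if (nrow(edges) > 1L) {
      g <- igraph::graph_from_data_frame(edges[, c("node_a", "node_b")],
                                         directed = FALSE,
                                         vertices = data.frame(name = nodes))
      if (igraph::components(g)$no != 1L) stop("not a tree: disconnected")
    }
    ecost <- sum(ge$cost[idx])
  }
  p <- instance$penalty
  instance$beta * sum(p[setdiff(names(p), nodes)]) + ecost
}

#' Exact PCST solver for small instances
#'
#' Enumerates node subsets (the cheapest tree spanning a fixed node set is
#' the minimum spanning tree of the induced subgraph), including the empty
#' and all single-node trees, and returns a global minimizer. Ties are
#' broken deterministically in favor of the lexicographically smallest
#' sorted node-id list.
#'
#' @param instance a [pcst_instance()].
#' @param node_limit refuse instances with more nodes than this (default
#'   18; enumeration is exponential in the node count).
#' @return a `solution_network` with `is_optimal = TRUE`.
#' @export
solve_exact <- function(instance, node_limit = 18L) {
  nodes <- instance$graph$nodes
  n <- length(nodes)
  if (n > node_limit)
    stop("instance has ", n, " nodes, exceeding node_limit = ", node_limit)
  e <- instance$graph$edges
  res <- pcst_exact_cpp(n, match(e$node_a, nodes) - 1L,
                        match(e$node_b, nodes) - 1L, e$cost,
                        as.numeric(instance$penalty[nodes]), instance$beta)
  sol_nodes <- nodes[res$nodes + 1L]
  edges <- edge_rows(instance$graph, nodes[res$edge_a + 1L],
                     nodes[res$edge_b + 1L])
  solution_network(instance, sol_nodes, edges, solver = "exact",
                   is_optimal = TRUE)
}

# look up edge rows (with confidence/cost) for unordered node pairs
edge_rows <- function(graph, a, b) {
  ge <- graph$edges
  if (length(a) == 0L) return(ge[0, , drop = FALSE])
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  idx <- match(key, paste(ge$node_a, ge$node_b, sep = "\r"))
  if (anyNA(idx)) stop("edge not present in graph")
  out <- ge[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Moat-growing PCST heuristic for large instances
#'
#' A Goemans-Williamson-flavored heuristic: starting from each of several
#' seeded root termini, the tree greedily absorbs the terminus with the
#' best prize-minus-path-cost gain along shortest cost paths, the node set
#' is re-treeified as the minimum spanning tree of its induced subgraph,
#' and strong pruning removes subtrees whose collected prizes do not pay
#' for their edges. The best result over all roots, the empty tree and the
#' best single-node tree is returned, so the heuristic objective never
#' exceeds the trivial closed-form bounds (and is at least the exact
#' optimum by definition).
#'
#' @param instance a [pcst_instance()].
#' @param seed integer seed controlling root sampling (results are
#'   reproducible for a fixed seed).
#' @param n_roots number of root termini to try (the highest-penalty
#'   terminus plus seeded random picks).
#' @return a `solution_network` with `solver = "heuristic"`.
#' @export
solve_heuristic <- function(instance, seed = 1L, n_roots = 3L) {
  termini <- instance$termini
  empty <- solution_network(instance, character(), NULL, "heuristic")
  if (length(termini) == 0L) return(empty)
  # best single-node tree: highest-penalty terminus
  best_single <- solution_network(
    instance, termini[which.max(instance$penalty[termini])], NULL,
    "heuristic")
  best <- if (best_single$objective <= empty$objective) best_single else empty
  g <- as_igraph(instance$graph)
  roots <- local_seed(seed, {
    r <- termini[which.max(instance$penalty[termini])]
    extra <- setdiff(termini, r)
    if (length(extra) > 0L && n_roots > 1L)
      r <- c(r, sample(extra, min(n_roots - 1L, length(extra))))
    r
  })
  for (root in roots) {
    cand <- grow_from_root(instance, g, root)
    if (!is.null(cand) && cand$objective < best$objective - 1e-12) best <- cand
  }
  best
}

# greedy terminus absorption + MST re-treeify + strong pruning, single root
grow_from_root <- function(instance, g, root) {
  beta <- instance$beta
  p <- instance$penalty
  in_tree <- root
  remaining <- setdiff(instance$termini, root)
  comp <- igraph::components(g)
  root_comp <- comp$membership[root]
  remaining <- remaining[comp$membership[remaining] == root_comp]
  while (length(remaining) > 0L) {
    d <- igraph::distances(g, v = in_tree, to = remaining)
    dmin <- apply(d, 2, min)
    gain <- beta * p[remaining] - dmin
    k <- which.max(gain)
    if (gain[k] <= 0) break
    target <- remaining[k]
    from <- in_tree[which.min(d[, k])]
    path <- igraph::shortest_paths(g, from = from, to = target,
                                   output = "vpath")$vpath[[1]]
    in_tree <- union(in_tree, names(path))
    remaining <- setdiff(remaining, target)
  }
  # re-treeify: MST of the induced subgraph on the grown node set
  sub <- igraph::induced_subgraph(g, in_tree)
  mst <- igraph::mst(sub, weights = igraph::E(sub)$weight)
  tree <- strong_prune(mst, p, beta, root)
  edges <- if (igraph::ecount(tree) > 0L) {
    el <- igraph::as_edgelist(tree)
    edge_rows(instance$graph, el[, 1L], el[, 2L])
  } else NULL
  solution_network(instance, igraph::V(tree)$name, edges, "heuristic")
}

# strong pruning: drop any subtree whose net worth does not pay its edge
strong_prune <- function(tree, penalty, beta, root) {
  n <- igraph::vcount(tree)
  if (n <= 1L) return(tree)
  nm <- igraph::V(tree)$name
  bfs <- igraph::bfs(tree, root = match(root, nm), father = TRUE)
  order <- as.integer(bfs$order)
  father <- as.integer(bfs$father)
  worth <- beta * penalty[nm]
  keep <- rep(TRUE, n)
  adj <- igraph::as_adjacency_matrix(tree, attr = "weight", sparse = TRUE)
  for (v in rev(order)) {          # children before parents
    f <- father[v]
    if (is.na(f)) next
    w_edge <- adj[v, f]
    if (worth[v] <= w_edge) {
      # prune v and its whole subtree
      drop <- v
      frontier <- v
      while (length(frontier)) {
        kids <- which(father %in% frontier & keep)
        kids <- setdiff(kids, drop)
        drop <- c(drop, kids)
        frontier <- kids
      }
      keep[drop] <- FALSE
    } else {
      worth[f] <- worth[f] + worth[v] - w_edge
    }
  }
  igraph::induced_subgraph(tree, which(keep))
}

#' Solve a PCST instance with the requested solver
#'
#' @param instance a [pcst_instance()].
#' @param solver `"exact"` (subset enumeration, small instances) or
#'   `"heuristic"` (moat growing + strong pruning).
#' @param seed seed for the heuristic's root sampling.
#' @param node_limit passed to [solve_exact()].
#' @param n_roots passed to [solve_heuristic()].
#' @return a `solution_network`.
#' @export
solve_pcst <- function(instance, solver = c("heuristic", "exact"),
                       seed = 1L, node_limit = 18L, n_roots = 3L) {
  solver <- match.arg(solver)
  if (solver == "exact") solve_exact(instance, node_limit)
  else solve_heuristic(instance, seed, n_roots)
}
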