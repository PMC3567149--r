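# Independent oracles and fixture builders used across the suite.
# Oracles deliberately take different computational routes than the
# package implementation (edge-subset enumeration vs node-subset MST,
# explicit binomial-coefficient sums vs phyper, full permutation
# enumeration vs closed forms).

toy_graph <- function(a, b, conf) {
  build_graph(data.frame(node_a = a, node_b = b, confidence = conf,
                         stringsAsFactors = FALSE))
}

# random sparse PCST instance on n nodes with at most max_edges edges
random_instance <- function(n, max_edges, seed, beta = NULL) {
  set.seed(seed)
  ids <- sprintf("N%02d", seq_len(n))
  pairs <- t(combn(n, 2))
  m <- min(max_edges, nrow(pairs))
  sel <- pairs[sample(nrow(pairs), m), , drop = FALSE]
  conf <- runif(m, 0.3, 0.99)
  g <- toy_graph(ids[sel[, 1]], ids[sel[, 2]], conf)
  n_term <- sample(2:max(2, floor(n / 2)), 1)
  term <- sample(g$nodes, min(n_term, length(g$nodes)))
  pen <- setNames(runif(length(term), 0.2, 3), term)
  if (is.null(beta)) beta <- runif(1, 0.5, 2)
  pcst_instance(g, pen, beta)
}

# brute-force PCST optimum by enumeration over EDGE subsets (plus the
# empty tree and every single-node tree); independent of the node-subset
# + MST route used by solve_exact()
pcst_brute_force <- function(inst) {
  e <- inst$graph$edges
  m <- nrow(e)
  stopifnot(m <= 16)
  p <- inst$penalty
  total <- sum(p)
  best <- inst$beta * total
  for (v in inst$graph$nodes) {
    obj <- inst$beta * (total - p[[v]])
    if (obj < best) best <- obj
  }
  for (mask in seq_len(2^m - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) != 0)
    sub <- e[idx, , drop = FALSE]
    vs <- unique(c(sub$node_a, sub$node_b))
    if (length(idx) != length(vs) - 1L) next        # not a tree on |V| nodes
    # connectivity via union-find
    parent <- seq_along(vs)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    acyclic <- TRUE
    for (k in seq_len(nrow(sub))) {
      ra <- find(match(sub$node_a[k], vs))
      rb <- find(match(sub$node_b[k], vs))
      if (ra == rb) { acyclic <- FALSE; break }
      parent[ra] <- rb
    }
    if (!acyclic) next
    obj <- inst$beta * (total - sum(p[vs])) + sum(sub$cost)
    if (obj < best) best <- obj
  }
  unname(best)
}

# hypergeometric upper tail from explicit binomial-coefficient sums
hgt_choose <- function(N, K, n, k) {
  if (k <= 0) return(1)
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# mHG statistic of a label vector via the explicit-sum tail
mhg_stat_oracle <- function(labels) {
  N <- length(labels)
  B <- sum(labels)
  b <- cumsum(labels)
  min(vapply(seq_len(N - 1), function(n) hgt_choose(N, B, n, b[n]),
             numeric(1)))
}

# exact mHG p-value by enumeration over all C(N, B) label orderings
mhg_p_oracle <- function(statistic, N, B) {
  pos <- combn(N, B)
  stats <- apply(pos, 2, function(ones) {
    lab <- integer(N)
    lab[ones] <- 1L
    mhg_stat_oracle(lab)
  })
  mean(stats <= statistic * (1 + 1e-9))
}

# exact one-sided rank-sum p by enumeration over group assignments
ranksum_p_oracle <- function(ra, rb, alternative = "better") {
  pooled <- c(ra, rb)
  combs <- combn(length(pooled), length(ra))
  sums <- colSums(matrix(pooled[combs], nrow = length(ra)))
  obs <- sum(ra)
  mu <- mean(sums)
  if (alternative == "better") mean(sums <= obs + 1e-12)
  else mean(abs(sums - mu) >= abs(obs - mu) - 1e-12)
}

rc_dna <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
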