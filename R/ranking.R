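#' Connectivity scores of interactome nodes against a PCST solution
#'
#' Every node in the interactome, whether inside or outside the solution,
#' is scored by the sum of confidence values of its edges into the
#' solution node set. Since edge confidences are likelihood-based, a large
#' score means many high-confidence interactions with the response
#' network. Scores depend only on confidences, never on the cost
#' representation.
#'
#' @param graph a `weighted_graph`.
#' @param pcst_nodes character vector of solution node ids (must all be
#'   graph nodes).
#' @return data frame `node_id`, `score`, `in_pcst`, sorted by node id.
#' @export
connectivity_scores <- function(graph, pcst_nodes) {
  missing_nodes <- setdiff(pcst_nodes, graph$nodes)
  if (length(missing_nodes))
    stop("pcst node(s) absent from graph: ",
         paste(head(missing_nodes, 5), collapse = ", "))
  e <- graph$edges
  score <- setNames(numeric(length(graph$nodes)), graph$nodes)
  a_in <- e$node_a %in% pcst_nodes
  b_in <- e$node_b %in% pcst_nodes
  # each edge contributes its confidence to the endpoint opposite a member
  add_a <- rowsum(e$confidence[b_in], e$node_a[b_in])
  add_b <- rowsum(e$confidence[a_in], e$node_b[a_in])
  score[rownames(add_a)] <- score[rownames(add_a)] + add_a[, 1L]
  score[rownames(add_b)] <- score[rownames(add_b)] + add_b[, 1L]
  data.frame(node_id = graph$nodes, score = unname(score),
             in_pcst = graph$nodes %in% pcst_nodes,
             stringsAsFactors = FALSE)
}

#' Rank nodes by descending score with average-rank ties
#'
#' Rank 1 is the best (highest) score; tied scores share the mean of the
#' ranks they span, so half-integer ranks occur. The rank vector always
#' sums to `N (N + 1) / 2`.
#'
#' @param scores data frame from [connectivity_scores()] (or any data
#'   frame with `node_id` and `score`).
#' @return the input with a `rank` column, sorted by rank.
#' @export
rank_nodes <- function(scores) {
  scores$rank <- rank(-scores$score, ties.method = "average")
  scores <- scores[order(scores$rank, scores$node_id), , drop = FALSE]
  rownames(scores) <- NULL
  scores
}

#' Compare the ranks of two node groups
#'
#' Wilcoxon rank-sum test on the rank values of two disjoint node groups.
#' When both groups have at most `exact_max` members the p-value is
#' computed by exact enumeration of all group assignments of the pooled
#' rank values (ties handled exactly); otherwise the normal approximation
#' with continuity and tie corrections is used. The one-sided alternative
#' `"better"` tests whether group A is better ranked (smaller rank
#' numbers) than group B.
#'
#' @param group_a,group_b disjoint character vectors of node ids.
#' @param ranked data frame from [rank_nodes()].
#' @param alternative `"two.sided"` or `"better"`.
#' @param exact_max exact-enumeration size cutoff per group (default 10).
#' @return list with `statistic` (rank-sum of group A's rank values),
#'   `p_value` and `method`.
#' @export
compare_ranks <- function(group_a, group_b, ranked,
                          alternative = c("two.sided", "better"),
                          exact_max = 10L) {
  alternative <- match.arg(alternative)
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty")
  r <- setNames(ranked$rank, ranked$node_id)
  missing_nodes <- setdiff(c(group_a, group_b), names(r))
  if (length(missing_nodes))
    stop("unranked node(s): ", paste(head(missing_nodes, 5), collapse = ", "))
  ra <- r[group_a]
  rb <- r[group_b]
  stat <- sum(ra)
  if (length(ra) <= exact_max && length(rb) <= exact_max) {
    pooled <- c(ra, rb)
    na <- length(ra)
    combs <- combn(length(pooled), na)
    sums <- colSums(matrix(pooled[combs], nrow = na))
    mu <- mean(sums)
    p <- switch(alternative,
                better = mean(sums <= stat + 1e-12),
                two.sided = mean(abs(sums - mu) >= abs(stat - mu) - 1e-12))
    list(statistic = stat, p_value = p, method = "exact permutation")
  } else {
    alt <- if (alternative == "better") "less" else "two.sided"
    wt <- suppressWarnings(wilcox.test(ra, rb, alternative = alt,
                                       exact = FALSE, correct = TRUE))
    list(statistic = stat, p_value = wt$p.value,
         method = "normal approximation")
  }
}
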