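#' Hypergeometric upper-tail probability (one-sided Fisher test)
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` marked items when `n` items are drawn without
#' replacement from a population of `N` containing `K` marked items.
#' Computed in log space via [stats::phyper()].
#'
#' @param N population size.
#' @param K number of marked items in the population.
#' @param n draw size.
#' @param k observed number of marked items in the draw.
#' @return upper-tail probability in `[0, 1]`.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  if (!(k >= 0 && k <= n && n <= N && K >= 0 && K <= N))
    stop("require 0 <= k <= n <= N and 0 <= K <= N")
  exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

# HGT over all prefixes of a 0/1 label vector, n = 1..N-1 (vectorized)
prefix_tails <- function(labels) {
  N <- length(labels)
  B <- sum(labels)
  n <- seq_len(N - 1L)
  b <- cumsum(labels)[n]
  phyper(b - 1, B, N - B, n, lower.tail = FALSE)
}

#' Minimum-hypergeometric statistic of a ranked binary vector
#'
#' Scans every prefix length `n = 1..N-1` of the ranked 0/1 label vector,
#' computes the hypergeometric upper tail of observing at least `b(n)`
#' ones in the top `n`, and returns the minimum together with the smallest
#' prefix length attaining it. The statistic ignores labels after the last
#' 1 by construction.
#'
#' @param labels 0/1 vector in rank order, with `0 < sum(labels) <
#'   length(labels)`.
#' @return list with `statistic`, `n_star`, `N`, `B`.
#' @export
mhg_statistic <- function(labels) {
  labels <- as.integer(labels)
  N <- length(labels)
  B <- sum(labels)
  if (B == 0L || B == N)
    stop("degenerate label vector: need 0 < B < N")
  hgt <- prefix_tails(labels)
  n_star <- which.min(hgt)         # smallest argmin
  list(statistic = hgt[n_star], n_star = n_star, N = N, B = B)
}

#' Exact p-value of the minimum-hypergeometric statistic
#'
#' The null probability, over uniformly random orderings of `B` ones among
#' `N` labels, that the mHG statistic is at most `statistic`. Computed by
#' the `O(N * B)` lattice-path dynamic program over the `(n, b)` grid:
#' paths are propagated with hypergeometric transition probabilities and
#' absorbed (zeroed) at any cell whose prefix tail is at most the observed
#' statistic; the p-value is one minus the surviving mass.
#'
#' @param statistic mHG statistic in `(0, 1]`.
#' @param N total number of labels.
#' @param B number of ones.
#' @return exact p-value in `[0, 1]`.
#' @export
mhg_pvalue_exact <- function(statistic, N, B) {
  stopifnot(statistic > 0, statistic <= 1, B >= 1, B <= N - 1)
  thresh <- statistic * (1 + 1e-9)   # guard against ties at the minimum
  # dp[b + 1] = P(path at (n, b) without ever entering the significant set)
  dp <- c(1, rep(0, B))
  for (n in 0:(N - 1L)) {
    if (n >= 1L && n <= N - 1L) {
      b <- 0:min(n, B)
      hgt <- phyper(b - 1, B, N - B, n, lower.tail = FALSE)
      dp[b[hgt <= thresh] + 1L] <- 0
    }
    # transition n -> n+1: draw a 1 with prob (B-b)/(N-n)
    b <- 0:B
    p1 <- pmax(0, (B - b) / (N - n))
    new <- dp * (1 - p1)
    new[-1L] <- new[-1L] + dp[-(B + 1L)] * p1[-(B + 1L)]
    dp <- new
  }
  min(1, max(0, 1 - dp[B + 1L]))
}

#' Directional mHG enrichment of a target set in a gene ranking
#'
#' Builds the ranked membership vector of `target_set` in `gene_ranking`
#' (reversed first for `direction = "down"`, so enrichment at the bottom
#' of the original ranking is tested) and returns the mHG statistic with
#' its exact p-value.
#'
#' @param gene_ranking character vector of gene ids, best-ranked first
#'   (e.g. genes sorted by decreasing log2 fold change).
#' @param target_set character vector of target gene ids; must intersect
#'   the ranking and must not cover it entirely.
#' @param direction `"up"` (enrichment at the top) or `"down"`.
#' @return list with `statistic`, `n_star`, `p_exact`, `N`, `B`,
#'   `direction`.
#' @export
directional_mhg <- function(gene_ranking, target_set,
                            direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (direction == "down") gene_ranking <- rev(gene_ranking)
  labels <- as.integer(gene_ranking %in% target_set)
  if (sum(labels) == 0L)
    stop("target set does not intersect the ranking")
  if (sum(labels) == length(labels))
    stop("target set covers the whole ranking")
  s <- mhg_statistic(labels)
  c(s, list(p_exact = mhg_pvalue_exact(s$statistic, s$N, s$B),
            direction = direction))
}

#' mHG test of a ranked binary vector
#'
#' Convenience wrapper combining [mhg_statistic()] and
#' [mhg_pvalue_exact()].
#'
#' @inheritParams mhg_statistic
#' @return list with `statistic`, `n_star`, `p_exact`, `N`, `B`.
#' @export
mhg_test <- function(labels) {
  s <- mhg_statistic(labels)
  c(s, list(p_exact = mhg_pvalue_exact(s$statistic, s$N, s$B)))
}

#' Fisher-exact enrichment of region overlap
#'
#' Counts background regions by membership in the query subset and by
#' overlap (at least one shared base, 0-based half-open intervals) with
#' the reference set, and computes the one-sided Fisher (hypergeometric
#' upper-tail) enrichment p-value of overlap within the query.
#'
#' @param query data frame of regions (`chrom`, `start`, `end`), a subset
#'   of `background`.
#' @param reference data frame of regions to overlap against.
#' @param background data frame of all candidate regions (superset of
#'   `query`).
#' @return list with `table` (2x2 counts), `p_value`, and the margin
#'   counts `N`, `K`, `n`, `k`.
#' @export
region_overlap_enrichment <- function(query, reference, background) {
  if (nrow(background) == 0L) stop("background is empty")
  to_gr <- function(df) {
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(start = df$start + 1L,
                                            end = df$end))
  }
  bg <- to_gr(background)
  ov <- rep(FALSE, nrow(background))
  if (nrow(reference) > 0L)
    ov <- suppressWarnings(  # disjoint seqlevels mean zero overlap, not error
      IRanges::overlapsAny(bg, to_gr(reference), minoverlap = 1L))
  key <- function(df) paste(df$chrom, df$start, df$end, sep = "\r")
  in_query <- key(background) %in% key(query)
  if (sum(in_query) < nrow(query))
    warning("some query regions are absent from the background")
  tab <- table(in_query = factor(in_query, c(TRUE, FALSE)),
               overlaps = factor(ov, c(TRUE, FALSE)))
  N <- nrow(background)
  K <- sum(ov)
  n <- sum(in_query)
  k <- sum(in_query & ov)
  list(table = tab, p_value = hypergeom_tail(N, K, n, k),
       N = N, K = K, n = n, k = k)
}

#' Two-sample t-test on groups of p-values
#'
#' Student's t-test (pooled variance by default, Welch optional) comparing
#' two groups of enrichment p-values, optionally on the `-log10` scale.
#'
#' @param group_a,group_b numeric vectors of p-values (length >= 2 each).
#' @param var_equal pooled-variance Student test when `TRUE` (default),
#'   Welch otherwise.
#' @param log10_transform compare `-log10(p)` values instead of raw
#'   p-values.
#' @return list with `t`, `df`, `p_value`.
#' @export
group_pvalue_ttest <- function(group_a, group_b, var_equal = TRUE,
                               log10_transform = FALSE) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  if (log10_transform) {
    group_a <- -log10(group_a)
    group_b <- -log10(group_b)
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    if (isTRUE(all.equal(mean(group_a), mean(group_b))))
      return(list(t = 0, df = length(group_a) + length(group_b) - 2L,
                  p_value = 1))
    stop("degenerate variance in both groups")
  }
  tt <- t.test(group_a, group_b, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
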