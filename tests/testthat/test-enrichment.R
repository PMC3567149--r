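test_that("hypergeometric tails match explicit binomial-coefficient sums", {
  expect_equal(hypergeom_tail(20, 5, 8, 0), 1)
  expect_error(hypergeom_tail(10, 4, 12, 1), "require")
  set.seed(14)
  for (rep in 1:20) {
    N <- sample(5:30, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_tail(N, K, n, k), hgt_choose(N, K, n, k),
                 tolerance = 1e-12)
  }
  # monotone non-increasing in k
  tails <- sapply(0:8, function(k) hypergeom_tail(20, 10, 8, k))
  expect_true(all(diff(tails) <= 1e-15))
})

test_that("the mHG statistic equals brute-force minimization over prefixes", {
  # perfect enrichment: all B ones first
  res <- mhg_statistic(c(1, 1, 1, rep(0, 7)))
  expect_equal(res$statistic, 1 / choose(10, 3), tolerance = 1e-12)
  expect_equal(res$n_star, 3L)
  # alternating vector can never beat the sorted one
  alt <- mhg_statistic(rep(c(1, 0), 5))
  expect_gte(alt$statistic, res$statistic)
  expect_error(mhg_statistic(rep(1, 5)), "degenerate")
  # random vectors vs the exhaustive oracle
  set.seed(23)
  for (rep in 1:20) {
    N <- sample(6:12, 1)
    B <- sample(2:(N - 2), 1)
    lab <- sample(c(rep(1, B), rep(0, N - B)))
    expect_equal(mhg_statistic(lab)$statistic, mhg_stat_oracle(lab),
                 tolerance = 1e-12)
  }
  # labels after the last 1 are irrelevant
  lab <- c(0, 1, 1, 0, 1, 0, 0, 0)
  expect_equal(mhg_statistic(lab)$statistic,
               mhg_statistic(c(0, 1, 1, 0, 1, 0, 0, 0))$statistic)
})

test_that("the exact mHG p-value matches enumeration over orderings", {
  expect_equal(mhg_pvalue_exact(1, 10, 3), 1)
  set.seed(29)
  for (rep in 1:10) {
    N <- sample(8:12, 1)
    B <- sample(2:4, 1)
    lab <- sample(c(rep(1, B), rep(0, N - B)))
    s <- mhg_statistic(lab)$statistic
    expect_equal(mhg_pvalue_exact(s, N, B), mhg_p_oracle(s, N, B),
                 tolerance = 1e-9)
  }
})

test_that("directional mHG reverses the ranking for down-regulation", {
  genes <- paste0("g", 1:30)
  targets <- paste0("g", 1:5)      # at the very top
  up <- directional_mhg(genes, targets, "up")
  down <- directional_mhg(genes, targets, "down")
  expect_lt(up$p_exact, 0.01)
  expect_gt(down$p_exact, up$p_exact)
  # down equals up on the reversed ranking
  expect_equal(down$statistic,
               directional_mhg(rev(genes), targets, "up")$statistic)
  expect_error(directional_mhg(genes, "nope", "up"), "intersect")
})

test_that("region overlap enrichment counts a toy set like a hand sweep", {
  set.seed(41)
  bg <- data.frame(chrom = "c1", start = seq(0, 1900, by = 100))
  bg$end <- bg$start + 80
  query <- bg[1:6, ]
  reference <- data.frame(chrom = "c1",
                          start = c(50, 150, 1250),
                          end = c(120, 190, 1260))
  res <- region_overlap_enrichment(query, reference, bg)
  # hand count: bg regions overlapping reference are rows 1, 2, 13
  brute <- sapply(seq_len(nrow(bg)), function(i)
    any(pmax(bg$start[i], reference$start) <
          pmin(bg$end[i], reference$end)))
  expect_equal(res$K, sum(brute))
  expect_equal(res$k, sum(brute[1:6]))
  expect_equal(res$p_value, hypergeom_tail(20, res$K, 6, res$k))
  # no contrast and no overlap both give p = 1
  expect_equal(region_overlap_enrichment(bg, reference, bg)$p_value, 1)
  none <- data.frame(chrom = "c9", start = 0, end = 10)
  expect_equal(region_overlap_enrichment(query, none, bg)$p_value, 1)
  expect_error(region_overlap_enrichment(query, reference, bg[0, ]),
               "empty")
})

test_that("adjacent half-open intervals do not overlap", {
  bg <- data.frame(chrom = "c1", start = c(0, 100), end = c(100, 200))
  touching <- data.frame(chrom = "c1", start = 100, end = 150)
  res <- region_overlap_enrichment(bg[1, , drop = FALSE], touching, bg)
  expect_equal(res$k, 0L)   # [0,100) does not share a base with [100,150)
  expect_equal(res$K, 1L)
})

test_that("group p-value t-tests match the pooled-variance closed form", {
  a <- c(0.1, 0.2, 0.3)
  b <- c(0.4, 0.5, 0.6)
  res <- group_pvalue_ttest(a, b)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  swapped <- group_pvalue_ttest(b, a)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p_value, res$p_value)
  same <- group_pvalue_ttest(c(0.2, 0.2), c(0.2, 0.2))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
})

test_that("motif discrimination CV finds a perfectly separating motif", {
  set.seed(51)
  pwms <- lapply(1:6, function(i)
    prizelink:::random_pwm(sprintf("M%d", i), 8))
  names(pwms) <- sapply(pwms, `[[`, "matrix_id")
  site <- pwm_consensus(pwms$M3)
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
  positives <- setNames(
    sapply(1:15, function(i) paste0(rand_seq(20), site, rand_seq(20))),
    paste0("p", 1:15))
  negatives <- setNames(sapply(1:15, function(i) rand_seq(48)),
                        paste0("n", 1:15))
  cv <- motif_discrimination_cv(positives, negatives, pwms, folds = 5,
                                top_k = 2, seed = 7)
  for (f in cv$per_fold)
    expect_equal(f$matrix_id[1], "M3")
  # deterministic fold assignment for a fixed seed
  cv2 <- motif_discrimination_cv(positives, negatives, pwms, folds = 5,
                                 top_k = 2, seed = 7)
  expect_equal(cv2$fold_assignment, cv$fold_assignment)
  expect_error(motif_discrimination_cv(positives[1:3], negatives, pwms),
               "at least")
})

test_that("shuffled labels put any fixed motif in the top k at chance rate", {
  set.seed(61)
  pwms <- lapply(1:10, function(i)
    prizelink:::random_pwm(sprintf("M%02d", i), 8))
  names(pwms) <- sapply(pwms, `[[`, "matrix_id")
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
  seqs <- setNames(sapply(1:20, function(i) rand_seq(40)),
                   paste0("s", 1:20))
  hits <- 0L
  n_shuffle <- 60
  for (i in seq_len(n_shuffle)) {
    idx <- sample(20, 10)
    cv <- motif_discrimination_cv(seqs[idx], seqs[-idx], pwms, folds = 2,
                                  top_k = 2, seed = i)
    hits <- hits + ("M01" %in% cv$top_motifs[[1]])
  }
  # chance rate is top_k / n_motifs = 0.2; allow a generous binomial band
  expect_gt(hits / n_shuffle, 0.2 - 3 * sqrt(0.2 * 0.8 / n_shuffle))
  expect_lt(hits / n_shuffle, 0.2 + 3 * sqrt(0.2 * 0.8 / n_shuffle))
})
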