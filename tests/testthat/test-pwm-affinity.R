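test_that("uniform PWMs score 2 * (S - L + 1) and N windows are excluded", {
  p <- pwm("uni", matrix(25, 4, 6))
  s <- strrep("ACGT", 6)  # length 24
  expect_equal(sequence_affinity(p, s), 2 * (24 - 6 + 1))
  expect_equal(sequence_affinity(p, strrep("N", 30)), 0)
  expect_error(sequence_affinity(p, "ACG"), "shorter")
})

test_that("a concentrated motif scores its hand-computed ratio product", {
  counts <- matrix(0, 4, 4)
  counts[cbind(c(1, 1, 2, 2), 1:4)] <- 1e9   # motif "AACC"
  p <- pwm("AACC", counts, pseudocount = 1e-6)
  # forward window "AACC": (1/0.25)^4 = 256; reverse complement "GGTT": ~0
  expect_equal(sequence_affinity(p, "AACC"), 256, tolerance = 1e-6)
  # a palindromic site is counted on both strands
  counts2 <- matrix(0, 4, 4)
  counts2[cbind(c(1, 2, 3, 4), 1:4)] <- 1e9  # motif "ACGT", self-complementary
  p2 <- pwm("ACGT", counts2, pseudocount = 1e-6)
  expect_equal(sequence_affinity(p2, "ACGT"), 512, tolerance = 1e-4)
})

test_that("affinity is strand-symmetric and additive over N-spaced blocks", {
  set.seed(11)
  for (rep in 1:5) {
    counts <- matrix(rexp(4 * 8), 4, 8)
    p <- pwm(sprintf("R%d", rep), counts)
    s <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
               collapse = "")
    expect_equal(sequence_affinity(p, s), sequence_affinity(p, rc_dna(s)),
                 tolerance = 1e-9)
    s2 <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                collapse = "")
    spacer <- strrep("N", 7)  # L - 1 ambiguous bases kill bridging windows
    expect_equal(sequence_affinity(p, paste0(s, spacer, s2)),
                 sequence_affinity(p, s) + sequence_affinity(p, s2),
                 tolerance = 1e-9)
  }
})

test_that("TRANSFAC matrices round-trip through write/read", {
  set.seed(3)
  pwms <- lapply(1:3, function(i)
    pwm(sprintf("M%02d", i), matrix(sample(0:90, 4 * 8, TRUE), 4, 8)))
  names(pwms) <- sapply(pwms, `[[`, "matrix_id")
  f <- withr::local_tempfile()
  write_transfac(pwms, f)
  back <- read_transfac(f)
  expect_equal(names(back), names(pwms))
  for (i in seq_along(pwms))
    expect_equal(back[[i]]$counts, pwms[[i]]$counts)
})

test_that("summit sequences are sliced half-open, clamped and verbatim", {
  contig <- paste(rep("ACGT", 2500), collapse = "")  # 10 kb
  genome <- Biostrings::DNAStringSet(c(chr1 = contig))
  regions <- data.frame(region_id = c("r1", "r2"), chrom = "chr1",
                        summit = c(500L, 30L))
  seqs <- extract_summit_sequences(regions, genome, flank = 100L)
  expect_equal(nchar(seqs[["r1"]]), 200L)
  expect_equal(seqs[["r1"]], substr(contig, 401, 600))  # [400, 600) 0-based
  expect_equal(nchar(seqs[["r2"]]), 130L)               # clamped at 0
  expect_equal(attr(seqs, "truncated"), c(FALSE, TRUE))
  expect_error(
    extract_summit_sequences(data.frame(region_id = "x", chrom = "chrZ",
                                        summit = 5L), genome),
    "chrZ")
})

test_that("region-to-gene mapping is inclusive at the window boundary", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      tss = c(100000L, 200000L))
  regions <- data.frame(region_id = c("a", "b"), chrom = "chr1",
                        summit = c(140000L, 140001L), condition = "H")
  m <- map_regions_to_genes(regions, genes, window = 40000L)
  expect_equal(m$region_id[m$gene_id == "g1"], "a")   # exactly 40 kb: mapped
  expect_false("b" %in% m$region_id[m$gene_id == "g1"])  # 40001: not mapped
})

test_that("mapping matches a brute-force scan over all pairs", {
  set.seed(5)
  genes <- data.frame(gene_id = paste0("g", 1:3),
                      chrom = c("c1", "c1", "c2"),
                      tss = c(50000L, 120000L, 80000L))
  regions <- data.frame(region_id = paste0("r", 1:4),
                        chrom = c("c1", "c1", "c2", "c2"),
                        summit = c(60000L, 170000L, 90000L, 200000L),
                        condition = c("H", "DK", "H", "DK"))
  m <- map_regions_to_genes(regions, genes, window = 40000L)
  brute <- expand.grid(r = 1:4, g = 1:3)
  brute <- brute[regions$chrom[brute$r] == genes$chrom[brute$g] &
                   abs(regions$summit[brute$r] - genes$tss[brute$g]) <= 40000, ]
  got <- sort(paste(m$region_id, m$gene_id))
  want <- sort(paste(regions$region_id[brute$r], genes$gene_id[brute$g]))
  expect_equal(got, want)
})

test_that("gene affinity is the H sum minus the DK sum", {
  aff <- matrix(c(5, 3, 4, 2), nrow = 4,
                dimnames = list(c("r1", "r2", "r3", "r4"), "M1"))
  # one H sequence only
  m1 <- data.frame(region_id = "r1", gene_id = "g", condition = "H")
  expect_equal(unname(gene_affinity(aff, m1)$N["M1", "g"]), 5)
  # equal H and DK contributions cancel
  m2 <- data.frame(region_id = c("r1", "r1"), gene_id = "g",
                   condition = c("H", "DK"))
  expect_equal(unname(gene_affinity(aff, m2)$N["M1", "g"]), 0)
  # 2 H sequences (3, 4) minus 1 DK sequence (2) = 5
  m3 <- data.frame(region_id = c("r2", "r3", "r4"), gene_id = "g",
                   condition = c("H", "H", "DK"))
  expect_equal(unname(gene_affinity(aff, m3)$N["M1", "g"]), 5)
  expect_error(gene_affinity(aff, data.frame(region_id = "r1",
                                             gene_id = "g",
                                             condition = "weird")),
               "condition")
})
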