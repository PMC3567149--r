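# smaller-than-default sizes keep these structural checks quick; the
# default-scale recovery behavior is exercised in the acceptance suite

test_that("interactome generation is deterministic and marks cheap truth", {
  a <- generate_interactome(n_nodes = 60, seed = 8)
  b <- generate_interactome(n_nodes = 60, seed = 8)
  expect_identical(a$graph$edges, b$graph$edges)
  expect_identical(a$truth$planted_nodes, b$truth$planted_nodes)
  # planted subtree is connected and sized 8-15% of nodes
  tg <- igraph::graph_from_data_frame(a$truth$planted_edges,
                                      directed = FALSE)
  expect_equal(igraph::components(tg)$no, 1L)
  frac <- length(a$truth$planted_nodes) / 60
  expect_gte(frac, 0.05)  # rounding slack below the nominal 8%
  expect_lte(frac, 0.16)
  # planted edges carry systematically higher confidence
  key <- paste(a$graph$edges$node_a, a$graph$edges$node_b)
  pk <- paste(a$truth$planted_edges$node_a, a$truth$planted_edges$node_b)
  planted <- key %in% pk
  expect_gt(mean(a$graph$edges$confidence[planted]),
            mean(a$graph$edges$confidence[!planted]))
  expect_equal(igraph::components(
    prizelink:::as_igraph(a$graph))$no, 1L)   # PA graphs are connected
})

test_that("generated peptides embed in their source proteins exactly once", {
  net <- generate_interactome(n_nodes = 60, seed = 9)
  ph <- generate_phospho(net$graph, net$truth, n_true = 6, n_noise = 3,
                         seed = 2)
  m <- map_peptides(ph$peptides, ph$proteome)
  expect_length(attr(m, "unmapped"), 0L)          # everything maps
  hit <- merge(m, ph$peptides[, c("peptide_id", "source_protein")])
  expect_true(all(vapply(split(hit$protein_id, hit$peptide_id),
                         function(ps) ps[1], character(1)) != ""))
  # each peptide maps to its intended host
  expect_true(all(mapply(function(pid, src)
    src %in% hit$protein_id[hit$peptide_id == pid],
    ph$peptides$peptide_id, ph$peptides$source_protein)))
  # zero-noise generation stays on the planted tree
  ph0 <- generate_phospho(net$graph, net$truth, n_true = 6, n_noise = 0,
                          seed = 3)
  hosts <- unique(ph0$peptides$source_protein)
  expect_true(all(hosts %in% net$truth$planted_nodes))
})

test_that("true phospho signal exceeds the noise background", {
  set.seed(1)
  ratios <- replicate(10, {
    net <- generate_interactome(n_nodes = 60, seed = sample(1e6, 1))
    ph <- generate_phospho(net$graph, net$truth, n_true = 4, n_noise = 8,
                           fc_scale = 2, seed = sample(1e6, 1))
    true_fc <- abs(ph$peptides$log2fc[
      ph$peptides$source_protein %in% net$truth$planted_nodes])
    noise_fc <- abs(ph$peptides$log2fc[
      !ph$peptides$source_protein %in% net$truth$planted_nodes])
    mean(true_fc) / mean(noise_fc)
  })
  expect_gt(mean(ratios > 1), 0.9)
})

test_that("noiseless regulomes give exact slope recovery", {
  net <- generate_interactome(n_nodes = 60, seed = 12)
  reg <- generate_regulome(net$truth, n_genes = 60, n_matrices = 8,
                           n_active = 1, noise_sd = 0, seed = 5)
  fits <- fit_motif_regressions(reg$affinity, reg$genes)
  m <- reg$truth$active_matrices
  expect_equal(fits$slope[fits$matrix_id == m],
               unname(reg$truth$effect_sizes[m]), tolerance = 1e-6)
  expect_true(fits$selected[fits$matrix_id == m])
})

test_that("planted motif instances sit inside their H regions", {
  net <- generate_interactome(n_nodes = 60, seed = 13)
  reg <- generate_regulome(net$truth, n_genes = 40, n_matrices = 6,
                           n_active = 2, seed = 6)
  sites <- reg$truth$planted_sites
  expect_gt(nrow(sites), 0)
  seqs <- extract_summit_sequences(reg$regions, reg$genome, flank = 100)
  for (i in seq_len(min(nrow(sites), 25))) {
    expect_true(grepl(sites$site[i], seqs[[sites$region_id[i]]],
                      fixed = TRUE))
  }
  # planting is strongly H-biased
  cond <- reg$regions$condition[match(sites$region_id,
                                      reg$regions$region_id)]
  expect_gt(mean(cond == "H"), 0.8)
})

test_that("fixture bundles round-trip with valid checksums", {
  dir <- withr::local_tempdir()
  sim <- simulate_study(seed = 3, n_nodes = 60, n_true = 6, n_noise = 3,
                        n_genes = 40, n_matrices = 6, n_active = 2)
  manifest <- write_fixture_bundle(sim, dir)
  for (f in names(manifest$checksums)) {
    expect_equal(unname(tools::md5sum(file.path(dir, f))),
                 manifest$checksums[[f]], info = f)
  }
  # reload and recompute penalties: identical to in-memory values
  peptides <- read_tsv_table(file.path(dir, "peptides.tsv"),
                             c("peptide_id", "sequence", "log2fc"))
  pen_disk <- assign_phospho_penalties(
    peptides, map_peptides(peptides, file.path(dir, "proteome.fa")))
  pen_mem <- assign_phospho_penalties(
    sim$peptides, map_peptides(sim$peptides, sim$proteome))
  expect_equal(pen_disk, pen_mem, tolerance = 1e-9)
  # regions round-trip
  regions <- read_regions_bed(file.path(dir, "regions.bed"))
  expect_equal(regions$summit, sim$regions$summit)
  expect_equal(regions$condition, sim$regions$condition)
})
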