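#' Generate a synthetic interactome with a planted response subtree
#'
#' Builds an undirected preferential-attachment (scale-free) graph, plants
#' a random connected subtree covering 8-15% of the nodes, and assigns
#' edge confidences: `Beta(4, 2)` shifted up by `truth_bonus` (clipped to
#' `(0, 1]`) on planted-tree edges and `Beta(2, 4)` elsewhere, so planted
#' edges are systematically more credible (cheaper) than background
#' edges.
#'
#' @param n_nodes number of proteins (>= 20, default 300).
#' @param attachment edges added per node in the preferential-attachment
#'   growth (default 2).
#' @param truth_bonus confidence shift on planted edges (default 0.25).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return list with `graph` (a `weighted_graph`) and `truth` (a
#'   `synthetic_truth` holding the planted nodes/edges and the generation
#'   config).
#' @export
generate_interactome <- function(n_nodes = 300L, attachment = 2L,
                                 truth_bonus = 0.25, seed = 1L) {
  stopifnot(n_nodes >= 20L)
  local_seed(seed, {
    g <- igraph::sample_pa(n_nodes, m = attachment, directed = FALSE)
    ids <- sprintf("P%04d", seq_len(n_nodes))
    el <- igraph::as_edgelist(g, names = FALSE)
    # planted connected subtree grown by random frontier expansion
    frac <- runif(1, 0.08, 0.15)
    target <- max(3L, round(frac * n_nodes))
    adj <- lapply(seq_len(n_nodes), function(v)
      as.integer(igraph::neighbors(g, v)))
    tree_nodes <- sample(n_nodes, 1L)
    tree_edges <- matrix(integer(), ncol = 2)
    while (length(tree_nodes) < target) {
      cand <- lapply(tree_nodes, function(v)
        setdiff(adj[[v]], tree_nodes))
      nc <- lengths(cand)
      if (sum(nc) == 0L) break
      from <- sample(rep(tree_nodes, nc), 1L)
      to <- sample(rep(setdiff(adj[[from]], tree_nodes), 2L), 1L)
      tree_nodes <- c(tree_nodes, to)
      tree_edges <- rbind(tree_edges, c(from, to))
    }
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    planted_key <- key(tree_edges[, 1L], tree_edges[, 2L])
    edge_key <- key(el[, 1L], el[, 2L])
    planted <- edge_key %in% planted_key
    conf <- numeric(nrow(el))
    conf[planted] <- pmin(1, rbeta(sum(planted), 4, 2) + truth_bonus)
    conf[!planted] <- rbeta(sum(!planted), 2, 4)
    conf <- pmin(pmax(conf, 1e-6), 1)
    interactions <- data.frame(node_a = ids[el[, 1L]], node_b = ids[el[, 2L]],
                               confidence = conf, stringsAsFactors = FALSE)
    graph <- build_graph(interactions)
    truth <- structure(list(
      planted_nodes = sort(ids[tree_nodes]),
      planted_edges = data.frame(node_a = pmin(ids[tree_edges[, 1L]],
                                               ids[tree_edges[, 2L]]),
                                 node_b = pmax(ids[tree_edges[, 1L]],
                                               ids[tree_edges[, 2L]]),
                                 stringsAsFactors = FALSE),
      phospho_termini = character(),
      tf_termini = character(),
      active_matrices = character(),
      config = list(n_nodes = n_nodes, attachment = attachment,
                    truth_bonus = truth_bonus, seed = seed)
    ), class = "synthetic_truth")
    list(graph = graph, truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", length(x$planted_nodes), "planted nodes,",
      length(x$phospho_termini), "phospho termini,",
      length(x$tf_termini), "TF termini,",
      length(x$active_matrices), "active matrices\n")
  invisible(x)
}

#' Generate synthetic phosphopeptides and a matching proteome
#'
#' Creates `n_true` peptides on distinct planted nodes with
#' `|log2fc| ~ Exponential(mean = fc_scale) + 1` and `n_noise` peptides on
#' random non-planted nodes with `|log2fc| ~ Exponential(mean = 0.3 *
#' fc_scale)`; signs are random. Every graph node receives a random
#' protein sequence, and each peptide is embedded exactly once in its
#' source protein, so [map_peptides()] recovers the intended mapping.
#'
#' @param graph the `weighted_graph` from [generate_interactome()].
#' @param truth the matching `synthetic_truth`.
#' @param n_true peptides on planted nodes (default 20; must not exceed
#'   the planted node count).
#' @param n_noise peptides on non-planted nodes (default 8).
#' @param fc_scale signal scale in log2 units (default 2).
#' @param seed integer seed.
#' @return list with `peptides` (data frame `peptide_id`, `sequence`,
#'   `log2fc`), `proteome` (`AAStringSet`) and the updated `truth`
#'   (field `phospho_termini`).
#' @export
generate_phospho <- function(graph, truth, n_true = 20L, n_noise = 8L,
                             fc_scale = 2, seed = 1L) {
  stopifnot(n_true <= length(truth$planted_nodes))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  local_seed(seed, {
    true_prot <- sample(truth$planted_nodes, n_true)
    noise_pool <- setdiff(graph$nodes, truth$planted_nodes)
    noise_prot <- sample(noise_pool, min(n_noise, length(noise_pool)))
    hosts <- c(true_prot, noise_prot)
    n_pep <- length(hosts)
    repeat {
      pep_seq <- vapply(seq_len(n_pep), function(i)
        paste(sample(aa, 12L, replace = TRUE), collapse = ""),
        character(1))
      if (!anyDuplicated(pep_seq)) break
    }
    fc_abs <- c(rexp(length(true_prot), rate = 1 / fc_scale) + 1,
                rexp(length(noise_prot), rate = 1 / (0.3 * fc_scale)))
    log2fc <- fc_abs * sample(c(-1, 1), n_pep, replace = TRUE)
    peptides <- data.frame(
      peptide_id = sprintf("pep%03d", seq_len(n_pep)),
      sequence = pep_seq, log2fc = log2fc,
      source_protein = hosts, stringsAsFactors = FALSE)
    prot_seq <- vapply(graph$nodes, function(nd)
      paste(sample(aa, 40L, replace = TRUE), collapse = ""), character(1))
    for (i in seq_len(n_pep)) {
      s <- prot_seq[[hosts[i]]]
      pos <- sample(nchar(s) + 1L, 1L)
      prot_seq[[hosts[i]]] <- paste0(substr(s, 1, pos - 1L), pep_seq[i],
                                     substr(s, pos, nchar(s)))
    }
    proteome <- Biostrings::AAStringSet(prot_seq)
    truth$phospho_termini <- sort(true_prot)
    truth$config$phospho <- list(n_true = n_true, n_noise = n_noise,
                                 fc_scale = fc_scale, seed = seed)
    list(peptides = peptides, proteome = proteome, truth = truth)
  })
}

# random informative PWM: one dominant base per column
random_pwm <- function(id, len, dominant_count = 85, other_count = 5,
                       pseudocount = 0.1) {
  counts <- matrix(other_count, 4, len)
  dom <- sample(4, len, replace = TRUE)
  counts[cbind(dom, seq_len(len))] <- dominant_count
  pwm(id, counts, pseudocount = pseudocount)
}

# sample a binding-site sequence from PWM column probabilities
sample_site <- function(x) {
  p <- pwm_probs(x)
  paste(vapply(seq_len(ncol(p)), function(j)
    sample(rownames(p), 1L, prob = p[, j]), character(1)), collapse = "")
}

#' Generate a synthetic regulome: genome, regions, PWMs and expression
#'
#' Lays out `n_genes` TSSs on a synthetic chromosome, draws
#' `Poisson(region_rate)` condition-labeled hypersensitive regions per
#' gene and condition within the regulatory window, plants instances of
#' the active motifs preferentially into H-condition regions
#' (`Poisson(1.2)` instances per H region vs `Poisson(0.1)` per DK
#' region), and generates differential expression as a linear function of
#' the *computed* differential motif affinity:
#' `log2fc(g) = sum_m beta_m N[m, g] + Normal(0, noise_sd)`. The affinity
#' `N` is obtained by running the package's own summit-extraction,
#' scanning and gene-affinity code on the generated data, so regression
#' recovery is exact in the noiseless limit by construction.
#'
#' Effect sizes default to alternating-sign magnitudes scaled to unit
#' per-motif signal standard deviation; `noise_sd = NULL` defaults to a
#' signal-to-noise ratio of 4 (`0.25 * sd(signal)`).
#'
#' @param truth a `synthetic_truth` (active matrices are mapped onto
#'   planted nodes distinct from the phospho termini when possible).
#' @param n_genes number of genes (default 200).
#' @param n_matrices size of the PWM library (default 30).
#' @param n_active number of truly active motifs (default 3).
#' @param region_rate Poisson mean of regions per gene and condition
#'   (default 2).
#' @param effect_sizes optional numeric vector of length `n_active`
#'   (slopes on the raw affinity scale); computed from the data scale when
#'   `NULL`.
#' @param noise_sd expression noise standard deviation; `NULL` for
#'   `0.25 * sd(signal)`.
#' @param seed integer seed.
#' @param flank summit flank for scanning (default 100).
#' @param window regulatory window in bp (default 40000).
#' @param gene_spacing TSS spacing in bp (default 25000).
#' @return list with `genome` (`DNAStringSet`), `regions`, `pwms`,
#'   `matrix_map`, `genes` (annotation + `log2fc` + `p`), `affinity`
#'   (the `affinity_table` used to build expression) and the updated
#'   `truth` (fields `active_matrices`, `effect_sizes`, `tf_termini`,
#'   `planted_sites`).
#' @export
generate_regulome <- function(truth, n_genes = 200L, n_matrices = 30L,
                              n_active = 3L, region_rate = 2,
                              effect_sizes = NULL, noise_sd = NULL,
                              seed = 1L, flank = 100L, window = 40000L,
                              gene_spacing = 25000L) {
  stopifnot(n_active <= n_matrices)
  local_seed(seed, {
    chrom <- "chrS"
    chrom_len <- (n_genes + 1L) * gene_spacing + 2L * window
    genome_vec <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
    genes <- data.frame(
      gene_id = sprintf("G%04d", seq_len(n_genes)),
      chrom = chrom,
      tss = window + gene_spacing * seq_len(n_genes),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      stringsAsFactors = FALSE)
    pwms <- lapply(seq_len(n_matrices), function(i)
      random_pwm(sprintf("M%03d", i), len = sample(8:10, 1L)))
    names(pwms) <- vapply(pwms, `[[`, character(1), "matrix_id")
    active <- sort(sample(names(pwms), n_active))
    # active matrices map onto planted TF nodes; others onto background nodes
    tf_pool <- setdiff(truth$planted_nodes, truth$phospho_termini)
    if (length(tf_pool) < n_active)
      tf_pool <- truth$planted_nodes
    tf_nodes <- sample(tf_pool, n_active)
    other <- setdiff(names(pwms), active)
    bg_nodes <- setdiff(truth$config$all_nodes %||%
                          sprintf("P%04d", seq_len(truth$config$n_nodes)),
                        truth$planted_nodes)
    matrix_map <- rbind(
      data.frame(matrix_id = active, protein_id = tf_nodes,
                 stringsAsFactors = FALSE),
      data.frame(matrix_id = other,
                 protein_id = sample(bg_nodes, length(other),
                                     replace = TRUE),
                 stringsAsFactors = FALSE))
    matrix_map <- matrix_map[order(matrix_map$matrix_id), , drop = FALSE]
    rownames(matrix_map) <- NULL
    # regions per gene and condition
    reg <- list()
    for (i in seq_len(n_genes)) {
      for (cond in c("H", "DK")) {
        n_r <- rpois(1, region_rate)
        if (n_r == 0L) next
        summit <- round(runif(n_r, genes$tss[i] - window + flank,
                              genes$tss[i] + window - flank))
        reg[[length(reg) + 1L]] <- data.frame(
          chrom = chrom, start = summit - 250L, end = summit + 250L,
          summit = summit, condition = cond,
          source_gene = genes$gene_id[i], stringsAsFactors = FALSE)
      }
    }
    regions <- do.call(rbind, reg)
    regions <- regions[!duplicated(regions$summit), , drop = FALSE]
    regions$region_id <- sprintf("R%05d", seq_len(nrow(regions)))
    rownames(regions) <- NULL
    # each active motif drives its own random subset of responsive genes;
    # planting only there keeps the per-motif affinities decorrelated, so
    # univariate regressions see each motif's effect rather than a shared
    # region-count signal
    responsive <- lapply(active, function(m)
      genes$gene_id[runif(n_genes) < 0.5])
    names(responsive) <- active
    # plant active-motif instances, mostly in H regions; an occupancy mask
    # prevents sites from overwriting each other (nearby regions share
    # sequence, so collisions would otherwise corrupt recorded sites)
    planted_sites <- list()
    occupied <- logical(chrom_len)
    for (i in seq_len(nrow(regions))) {
      lambda <- if (regions$condition[i] == "H") 1.2 else 0.1
      for (m in active) {
        if (!(regions$source_gene[i] %in% responsive[[m]])) next
        n_inst <- rpois(1, lambda)
        if (n_inst == 0L) next
        L <- pwm_length(pwms[[m]])
        for (k in seq_len(n_inst)) {
          site <- sample_site(pwms[[m]])
          for (try in 1:5) {
            offset <- sample.int(2L * flank - L + 1L, 1L) - 1L
            pos0 <- regions$summit[i] - flank + offset  # 0-based site start
            span <- (pos0 + 1L):(pos0 + L)
            if (any(occupied[span])) next
            occupied[span] <- TRUE
            genome_vec[span] <- strsplit(site, "")[[1L]]
            planted_sites[[length(planted_sites) + 1L]] <- data.frame(
              region_id = regions$region_id[i], matrix_id = m,
              start = pos0, site = site, stringsAsFactors = FALSE)
            break
          }
        }
      }
    }
    genome <- Biostrings::DNAStringSet(
      setNames(paste(genome_vec, collapse = ""), chrom))
    # self-consistent expression from the package's own affinity pipeline
    seqs <- extract_summit_sequences(regions, genome, flank = flank)
    mapping <- map_regions_to_genes(regions, genes, window = window)
    region_aff <- scan_pwm_set(pwms, seqs)$affinity
    aff <- gene_affinity(region_aff, mapping)
    N <- aff$N
    if (is.null(effect_sizes)) {
      base <- rep_len(c(1, -0.8, 0.9, -0.7, 0.8), n_active)
      scale_m <- apply(N[active, , drop = FALSE], 1, sd)
      scale_m[scale_m == 0] <- 1
      effect_sizes <- base / scale_m
    }
    signal <- as.numeric(effect_sizes %*% N[active, , drop = FALSE])
    names(signal) <- colnames(N)
    if (is.null(noise_sd)) noise_sd <- 0.25 * sd(signal)
    log2fc <- setNames(numeric(n_genes), genes$gene_id)
    log2fc[names(signal)] <- signal
    log2fc <- log2fc + rnorm(n_genes, 0, noise_sd)
    genes$log2fc <- unname(log2fc[genes$gene_id])
    z <- if (sd(genes$log2fc) > 0) genes$log2fc / sd(genes$log2fc) else
      genes$log2fc
    genes$p <- 2 * stats::pnorm(-abs(z))  # nominal, for interface parity
    truth$active_matrices <- active
    truth$responsive_genes <- responsive
    truth$effect_sizes <- setNames(effect_sizes, active)
    truth$tf_termini <- sort(tf_nodes)
    truth$planted_sites <- if (length(planted_sites))
      do.call(rbind, planted_sites) else NULL
    truth$config$regulome <- list(
      n_genes = n_genes, n_matrices = n_matrices, n_active = n_active,
      region_rate = region_rate, noise_sd = noise_sd, seed = seed,
      flank = flank, window = window, gene_spacing = gene_spacing)
    list(genome = genome, regions = regions, pwms = pwms,
         matrix_map = matrix_map, genes = genes, affinity = aff,
         truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a complete synthetic study
#'
#' Runs [generate_interactome()], [generate_phospho()] and
#' [generate_regulome()] with a shared base seed and returns every
#' pipeline input plus the ground truth.
#'
#' @param seed integer base seed.
#' @param n_nodes,attachment,truth_bonus interactome parameters.
#' @param n_true,n_noise,fc_scale phosphoproteome parameters.
#' @param n_genes,n_matrices,n_active,region_rate regulome parameters.
#' @param beta default PCST scaling for the synthetic instance (default
#'   1: phospho penalties are O(3) and planted edge costs O(0.15), so
#'   beta = 1 keeps collection and connection on the same scale).
#' @return list with `graph`, `peptides`, `proteome`, `genome`,
#'   `regions`, `pwms`, `matrix_map`, `genes`, `affinity`, `truth`,
#'   `beta`.
#' @export
simulate_study <- function(seed = 1L, n_nodes = 300L, attachment = 2L,
                           truth_bonus = 0.25, n_true = 20L, n_noise = 8L,
                           fc_scale = 2, n_genes = 200L, n_matrices = 30L,
                           n_active = 3L, region_rate = 2, beta = 1) {
  net <- generate_interactome(n_nodes, attachment, truth_bonus, seed)
  ph <- generate_phospho(net$graph, net$truth, n_true, n_noise, fc_scale,
                         seed = seed + 1L)
  reg <- generate_regulome(ph$truth, n_genes, n_matrices, n_active,
                           region_rate, seed = seed + 2L)
  c(list(graph = net$graph, peptides = ph$peptides,
         proteome = ph$proteome, beta = beta),
    reg[c("genome", "regions", "pwms", "matrix_map", "genes",
          "affinity")],
    list(truth = reg$truth))
}

#' Write every pipeline input of a simulated study to disk
#'
#' Emits the external-interface formats read by the pipeline: edge list,
#' peptide table, proteome and genome FASTA, region BED (with summit and
#' condition columns), TRANSFAC matrices, matrix-to-protein map, gene
#' annotation and expression tables, plus a manifest with the seed and
#' md5 checksums of every file.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return the manifest (also written as `manifest.yaml`), invisibly.
#' @export
write_fixture_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(dir, f)
  write_edge_table(sim$graph, path("edges.tsv"))
  write.table(sim$peptides[, c("peptide_id", "sequence", "log2fc")],
              path("peptides.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  Biostrings::writeXStringSet(sim$proteome, path("proteome.fa"))
  Biostrings::writeXStringSet(sim$genome, path("genome.fa"))
  write_regions_bed(sim$regions, path("regions.bed"))
  write_transfac(sim$pwms, path("pwms.transfac"))
  write.table(sim$matrix_map, path("matrix_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$genes[, c("gene_id", "chrom", "tss", "strand")],
              path("annotation.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$genes[, c("gene_id", "log2fc", "p")],
              path("expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c("edges.tsv", "peptides.tsv", "proteome.fa", "genome.fa",
             "regions.bed", "pwms.transfac", "matrix_map.tsv",
             "annotation.tsv", "expression.tsv")
  manifest <- list(
    seed = sim$truth$config$seed,
    beta = sim$beta,
    checksums = as.list(setNames(unname(tools::md5sum(file.path(dir, files))),
                                 files)))
  yaml::write_yaml(manifest, path("manifest.yaml"))
  invisible(manifest)
}
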