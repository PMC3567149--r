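# Pipeline orchestration: configuration, stage functions and provenance.
# Every stage reads files named in the config, writes tab-delimited
# outputs under out_dir and records a manifest with the config hash and
# seed, so any stage can be re-run from prior outputs.

#' Default pipeline configuration
#'
#' Returns the full configuration list: input paths (filled by the
#' `simulate` stage or by the user), the PCST settings (`beta`, solver,
#' node limit, suboptimal fraction and count), the regulatory windows and
#' thresholds, the phospho scale `k` and the seeds. Values can be
#' overridden via `...` or loaded from a YAML file with
#' [load_pipeline_config()].
#'
#' @param out_dir output directory.
#' @param ... named overrides of any default field.
#' @return a named list.
#' @export
pipeline_config <- function(out_dir = "prizelink_out", ...) {
  cfg <- list(
    out_dir = out_dir,
    edges = NULL, peptides = NULL, proteome = NULL, genome = NULL,
    regions = NULL, pwms = NULL, matrix_map = NULL, annotation = NULL,
    expression = NULL,
    beta = 1, solver = "heuristic", node_limit = 18L, n_roots = 3L,
    fraction = 0.15, n_solutions = 10L,
    window = 40000L, flank = 100L, alpha = 0.01, k = 1,
    exclude = character(),
    robustness_sds = c(0.05, 0.1, 0.2, 0.5), robustness_reps = 100L,
    seed = 1L,
    simulate = list(n_nodes = 300L, attachment = 2L, truth_bonus = 0.25,
                    n_true = 20L, n_noise = 8L, fc_scale = 2,
                    n_genes = 200L, n_matrices = 30L, n_active = 3L,
                    region_rate = 2)
  )
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file of overrides.
#' @param ... further overrides applied after the file.
#' @return a configuration list (defaults filled in).
#' @export
load_pipeline_config <- function(path, ...) {
  file_cfg <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  cfg[names(file_cfg)] <- file_cfg
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks numeric domains and, for the stages requested, the existence of
#' every referenced input path. All violations are reported together.
#'
#' @param config configuration list.
#' @param require_inputs character vector of input fields that must point
#'   at existing files.
#' @return the config, invisibly; stops with the full list of offending
#'   fields otherwise.
#' @export
validate_config <- function(config, require_inputs = character()) {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is.numeric(config$beta) && config$beta > 0, "beta must be positive")
  chk(config$solver %in% c("exact", "heuristic"),
      "solver must be 'exact' or 'heuristic'")
  chk(config$fraction >= 0 && config$fraction <= 1,
      "fraction must lie in [0, 1]")
  chk(config$alpha > 0 && config$alpha <= 1, "alpha must lie in (0, 1]")
  chk(config$k > 0, "k must be positive")
  chk(config$window >= 0, "window must be nonnegative")
  chk(config$flank >= 0, "flank must be nonnegative")
  for (f in require_inputs) {
    p <- config[[f]]
    if (is.null(p) || !file.exists(p))
      problems <- c(problems, paste0("input '", f, "' missing or not found: ",
                                     if (is.null(p)) "NULL" else p))
  }
  if (length(problems))
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  invisible(config)
}

# md5 of the canonicalized config, for provenance stamping
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config[order(names(config))], tmp)
  unname(tools::md5sum(tmp))
}

write_stage_manifest <- function(config, stage, outputs) {
  manifest <- list(
    tool = paste("prizelink", as.character(utils::packageVersion("prizelink"))),
    stage = stage, seed = config$seed, beta = config$beta,
    solver = config$solver, config_hash = config_hash(config),
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               basename(outputs))))
  path <- file.path(config$out_dir, paste0(stage, "_manifest.yaml"))
  yaml::write_yaml(manifest, path)
  invisible(path)
}

out_path <- function(config, f) file.path(config$out_dir, f)

#' Run one pipeline stage
#'
#' Stages: `simulate` (write a synthetic fixture bundle and point the
#' config at it), `tf-activity` (motif regressions and TF penalties),
#' `phospho` (peptide mapping and phospho penalties), `pcst` (solve,
#' suboptimals, composite network), `rank` (connectivity ranking),
#' `enrich` (directional mHG of per-motif target sets against the
#' expression ranking), `robustness` (noise perturbation summary) and
#' `all` (every stage in dependency order). Each stage writes its outputs
#' plus a manifest carrying the config hash and seed, and never mutates
#' its inputs.
#'
#' @param name stage name.
#' @param config configuration list from [pipeline_config()].
#' @return named list of output paths, invisibly.
#' @export
run_stage <- function(name = c("simulate", "tf-activity", "phospho",
                               "pcst", "rank", "enrich", "robustness",
                               "all"),
                      config = pipeline_config()) {
  name <- match.arg(name)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(name,
         "simulate" = stage_simulate(config),
         "tf-activity" = stage_tf_activity(config),
         "phospho" = stage_phospho(config),
         "pcst" = stage_pcst(config),
         "rank" = stage_rank(config),
         "enrich" = stage_enrich(config),
         "robustness" = stage_robustness(config),
         "all" = run_pipeline(config))
}

#' Run the full pipeline in dependency order
#'
#' @param config configuration list; when the input paths are unset the
#'   `simulate` stage is run first.
#' @return named list of per-stage outputs, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  out <- list()
  if (is.null(config$edges)) {
    out$simulate <- run_stage("simulate", config)
    config <- attr(out$simulate, "config")
  }
  out$tf_activity <- run_stage("tf-activity", config)
  out$phospho <- run_stage("phospho", config)
  out$pcst <- run_stage("pcst", config)
  out$rank <- run_stage("rank", config)
  out$enrich <- run_stage("enrich", config)
  invisible(out)
}

stage_simulate <- function(config) {
  validate_config(config)
  s <- config$simulate
  sim <- simulate_study(seed = config$seed, n_nodes = s$n_nodes,
                        attachment = s$attachment,
                        truth_bonus = s$truth_bonus, n_true = s$n_true,
                        n_noise = s$n_noise, fc_scale = s$fc_scale,
                        n_genes = s$n_genes, n_matrices = s$n_matrices,
                        n_active = s$n_active,
                        region_rate = s$region_rate, beta = config$beta)
  bundle_dir <- out_path(config, "bundle")
  write_fixture_bundle(sim, bundle_dir)
  config$edges <- file.path(bundle_dir, "edges.tsv")
  config$peptides <- file.path(bundle_dir, "peptides.tsv")
  config$proteome <- file.path(bundle_dir, "proteome.fa")
  config$genome <- file.path(bundle_dir, "genome.fa")
  config$regions <- file.path(bundle_dir, "regions.bed")
  config$pwms <- file.path(bundle_dir, "pwms.transfac")
  config$matrix_map <- file.path(bundle_dir, "matrix_map.tsv")
  config$annotation <- file.path(bundle_dir, "annotation.tsv")
  config$expression <- file.path(bundle_dir, "expression.tsv")
  write_stage_manifest(config, "simulate",
                       file.path(bundle_dir, "edges.tsv"))
  res <- list(bundle = bundle_dir)
  attr(res, "config") <- config
  attr(res, "truth") <- sim$truth
  invisible(res)
}

stage_tf_activity <- function(config) {
  validate_config(config, c("regions", "genome", "pwms", "matrix_map",
                            "annotation", "expression"))
  regions <- read_regions_bed(config$regions)
  pwms <- read_transfac(config$pwms)
  ann <- read_tsv_table(config$annotation, c("gene_id", "chrom", "tss"))
  expr <- read_tsv_table(config$expression, c("gene_id", "log2fc"))
  genes <- merge(ann, expr, by = "gene_id")
  seqs <- extract_summit_sequences(regions, config$genome,
                                   flank = config$flank)
  mapping <- map_regions_to_genes(regions, genes, window = config$window)
  region_aff <- scan_pwm_set(pwms, seqs)$affinity
  aff <- gene_affinity(region_aff, mapping)
  reg <- fit_motif_regressions(aff, genes, alpha = config$alpha)
  mmap <- read_tsv_table(config$matrix_map, c("matrix_id", "protein_id"))
  pen <- assign_tf_penalties(reg, mmap)
  p_reg <- out_path(config, "motif_regressions.tsv")
  p_pen <- out_path(config, "tf_penalties.tsv")
  write.table(reg, p_reg, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(pen, p_pen, sep = "\t", quote = FALSE, row.names = FALSE)
  write_stage_manifest(config, "tf-activity", c(p_reg, p_pen))
  invisible(list(regressions = p_reg, penalties = p_pen))
}

stage_phospho <- function(config) {
  validate_config(config, c("peptides", "proteome"))
  peptides <- read_tsv_table(config$peptides,
                             c("peptide_id", "sequence", "log2fc"))
  mapping <- map_peptides(peptides, config$proteome)
  pen <- assign_phospho_penalties(peptides, mapping, k = config$k)
  p_map <- out_path(config, "peptide_map.tsv")
  p_pen <- out_path(config, "phospho_penalties.tsv")
  write.table(mapping, p_map, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(pen, p_pen, sep = "\t", quote = FALSE, row.names = FALSE)
  write_stage_manifest(config, "phospho", c(p_map, p_pen))
  invisible(list(mapping = p_map, penalties = p_pen))
}

# merged penalty table (protein_id, penalty, source) from stage outputs
read_penalties <- function(config) {
  pen <- list()
  p_tf <- out_path(config, "tf_penalties.tsv")
  p_ph <- out_path(config, "phospho_penalties.tsv")
  if (file.exists(p_tf)) {
    tf <- read_tsv_table(p_tf, c("protein_id", "penalty"))
    if (nrow(tf)) pen$tf <- data.frame(protein_id = tf$protein_id,
                                       penalty = tf$penalty, source = "tf")
  }
  if (file.exists(p_ph)) {
    ph <- read_tsv_table(p_ph, c("protein_id", "penalty"))
    if (nrow(ph)) pen$phospho <- data.frame(protein_id = ph$protein_id,
                                            penalty = ph$penalty,
                                            source = "phospho")
  }
  if (length(pen) == 0L) stop("no penalty tables found under ",
                              config$out_dir)
  df <- do.call(rbind, pen)
  # a protein observed at both levels keeps its larger penalty
  df <- df[order(-df$penalty), , drop = FALSE]
  df <- df[!duplicated(df$protein_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

stage_pcst <- function(config) {
  validate_config(config, "edges")
  graph <- build_graph(read_tsv_table(config$edges,
                                      c("node_a", "node_b", "confidence")),
                       exclude = config$exclude)
  penalties <- read_penalties(config)
  penalties <- penalties[penalties$protein_id %in% graph$nodes, ,
                         drop = FALSE]
  inst <- pcst_instance(graph, penalties, config$beta)
  opt <- solve_pcst(inst, config$solver, seed = config$seed,
                    node_limit = config$node_limit,
                    n_roots = config$n_roots)
  subs <- if (length(opt$nodes) > 0L && config$n_solutions > 0L)
    solve_suboptimal(inst, opt, fraction = config$fraction,
                     n_solutions = config$n_solutions, seed = config$seed,
                     solver = config$solver,
                     node_limit = config$node_limit,
                     n_roots = config$n_roots)
  else list()
  composite <- merge_solutions(opt, subs)
  paths <- write_network_tables(composite, inst, config$out_dir,
                                prefix = "composite")
  opt_only <- merge_solutions(opt, list())
  paths2 <- write_network_tables(opt_only, inst, config$out_dir,
                                 prefix = "optimal")
  message(sprintf(
    "pcst: %d/%d termini included, %d Steiner nodes, objective %.4f",
    length(opt$included_termini), length(inst$termini),
    length(opt$steiner_nodes), opt$objective))
  write_stage_manifest(config, "pcst", c(paths, paths2))
  invisible(list(composite = paths, optimal = paths2,
                 objective = opt$objective))
}

stage_rank <- function(config) {
  validate_config(config, "edges")
  graph <- build_graph(read_tsv_table(config$edges,
                                      c("node_a", "node_b", "confidence")),
                       exclude = config$exclude)
  nodes_path <- out_path(config, "optimal_nodes.tsv")
  if (!file.exists(nodes_path)) stop("run the pcst stage first")
  pcst_nodes <- read_tsv_table(nodes_path, "id")$id
  ranked <- rank_nodes(connectivity_scores(graph, pcst_nodes))
  p_rank <- out_path(config, "ranking.tsv")
  write.table(ranked, p_rank, sep = "\t", quote = FALSE, row.names = FALSE)
  write_stage_manifest(config, "rank", p_rank)
  invisible(list(ranking = p_rank))
}

stage_enrich <- function(config) {
  validate_config(config, c("regions", "genome", "pwms", "matrix_map",
                            "annotation", "expression"))
  regions <- read_regions_bed(config$regions)
  pwms <- read_transfac(config$pwms)
  ann <- read_tsv_table(config$annotation, c("gene_id", "chrom", "tss"))
  expr <- read_tsv_table(config$expression, c("gene_id", "log2fc"))
  genes <- merge(ann, expr, by = "gene_id")
  ranking <- genes$gene_id[order(-genes$log2fc)]
  seqs <- extract_summit_sequences(regions, config$genome,
                                   flank = config$flank)
  mapping <- map_regions_to_genes(regions, genes, window = config$window)
  matches <- motif_match_scores(pwms, seqs)$matches
  rows <- lapply(colnames(matches), function(m) {
    hit_regions <- rownames(matches)[matches[, m]]
    targets <- unique(mapping$gene_id[mapping$region_id %in% hit_regions])
    if (length(targets) == 0L || length(targets) >= length(ranking))
      return(NULL)
    up <- directional_mhg(ranking, targets, "up")
    down <- directional_mhg(ranking, targets, "down")
    data.frame(matrix_id = m, n_targets = length(targets),
               mhg_stat_up = up$statistic, mhg_p_up = up$p_exact,
               mhg_stat_down = down$statistic, mhg_p_down = down$p_exact)
  })
  res <- do.call(rbind, rows)
  p_enr <- out_path(config, "target_enrichment.tsv")
  write.table(res, p_enr, sep = "\t", quote = FALSE, row.names = FALSE)
  write_stage_manifest(config, "enrich", p_enr)
  invisible(list(enrichment = p_enr))
}

stage_robustness <- function(config) {
  validate_config(config, "edges")
  graph <- build_graph(read_tsv_table(config$edges,
                                      c("node_a", "node_b", "confidence")),
                       exclude = config$exclude)
  penalties <- read_penalties(config)
  penalties <- penalties[penalties$protein_id %in% graph$nodes, ,
                         drop = FALSE]
  inst <- pcst_instance(graph, penalties, config$beta)
  out <- lapply(c("penalties", "costs"), function(tg)
    robustness_suite(inst, sds = config$robustness_sds,
                     reps = config$robustness_reps, target = tg,
                     seed = config$seed, solver = config$solver,
                     node_limit = config$node_limit,
                     n_roots = config$n_roots))
  res <- do.call(rbind, out)
  p_rob <- out_path(config, "robustness.tsv")
  write.table(res, p_rob, sep = "\t", quote = FALSE, row.names = FALSE)
  write_stage_manifest(config, "robustness", p_rob)
  invisible(list(robustness = p_rob))
}
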