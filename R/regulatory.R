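#' TRAP-style affinity of a PWM for a sequence
#'
#' Sums, over every window of the sequence on both strands, the product of
#' position-wise likelihood ratios `f(j, base)/bg(base)`, where `f` is the
#' pseudocount-normalized column probability of the PWM. Windows containing
#' an ambiguous base (`N`) contribute zero. A uniform PWM on a uniform
#' background therefore scores `2 * (S - L + 1)` on any unambiguous
#' sequence of length `S`.
#'
#' @param pwm a [pwm()] object.
#' @param sequence DNA string (character or `Biostrings::DNAString`),
#'   alphabet `A/C/G/T/N`, at least as long as the motif.
#' @return nonnegative affinity score.
#' @export
sequence_affinity <- function(pwm, sequence) {
  seq_int <- encode_dna(sequence)
  if (length(seq_int) < pwm_length(pwm))
    stop("sequence shorter than motif (", length(seq_int), " < ",
         pwm_length(pwm), ")")
  scan_pwm_cpp(seq_int, pwm_probs(pwm), pwm$background)$affinity
}

#' Maximum log-odds match score of a PWM on a sequence
#'
#' The best single-window log-odds score over both strands; `-Inf` when no
#' window is free of ambiguous bases. Used for motif "match" calls at a
#' fraction of the maximum achievable log-odds.
#'
#' @inheritParams sequence_affinity
#' @return maximum window log-odds (can be negative).
#' @export
max_logodds_score <- function(pwm, sequence) {
  seq_int <- encode_dna(sequence)
  if (length(seq_int) < pwm_length(pwm))
    stop("sequence shorter than motif")
  scan_pwm_cpp(seq_int, pwm_probs(pwm), pwm$background)$max_logodds
}

# batch affinity/log-odds over a character vector of sequences
# returns list(affinity = seqs x pwms matrix, max_logodds = same shape)
scan_pwm_set <- function(pwms, sequences) {
  enc <- lapply(sequences, encode_dna)
  probs <- lapply(pwms, pwm_probs)
  bgs <- lapply(pwms, `[[`, "background")
  n_s <- length(sequences)
  n_m <- length(pwms)
  aff <- matrix(0, n_s, n_m,
                dimnames = list(names(sequences),
                                vapply(pwms, `[[`, character(1), "matrix_id")))
  lo <- aff
  for (j in seq_len(n_m)) {
    for (i in seq_len(n_s)) {
      r <- scan_pwm_cpp(enc[[i]], probs[[j]], bgs[[j]])
      aff[i, j] <- r$affinity
      lo[i, j] <- r$max_logodds
    }
  }
  list(affinity = aff, max_logodds = lo)
}

#' Extract summit-centered sequences from a genome
#'
#' Returns the `[summit - flank, summit + flank)` slice around each
#' region's summit, uppercased, truncating at chromosome ends (truncation
#' is recorded in a `truncated` attribute column of the result names).
#' Coordinates are 0-based half-open.
#'
#' @param regions data frame with columns `region_id`, `chrom`, `summit`.
#' @param genome a `Biostrings::DNAStringSet` keyed by chromosome name, or
#'   a path to a FASTA file.
#' @param flank nonnegative integer flank (default 100, i.e. 200 bp
#'   windows).
#' @return named character vector of sequences (names are `region_id`),
#'   with a logical `truncated` attribute of the same length.
#' @export
extract_summit_sequences <- function(regions, genome, flank = 100L) {
  if (is.character(genome) && length(genome) == 1L)
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing_chr <- setdiff(unique(regions$chrom), names(genome))
  if (length(missing_chr))
    stop("chromosome(s) not in genome: ", paste(missing_chr, collapse = ", "))
  chr_len <- setNames(Biostrings::width(genome), names(genome))
  start0 <- pmax(regions$summit - flank, 0L)
  end0 <- pmin(regions$summit + flank, chr_len[regions$chrom])
  truncated <- (regions$summit - flank < 0L) |
    (regions$summit + flank > chr_len[regions$chrom])
  seqs <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    seqs[i] <- toupper(as.character(
      Biostrings::subseq(genome[[regions$chrom[i]]],
                         start = start0[i] + 1L, end = end0[i])))
  }
  names(seqs) <- regions$region_id
  attr(seqs, "truncated") <- unname(truncated)
  seqs
}

#' Map regions to genes by summit-to-TSS distance
#'
#' A region maps to a gene when both lie on the same chromosome and the
#' absolute distance between the region summit and the gene TSS is at most
#' `window` (boundary inclusive). Many-to-many mappings are expected: a
#' region may regulate several genes and a gene may have many proximal
#' regions.
#'
#' @param regions data frame with `region_id`, `chrom`, `summit`,
#'   `condition` columns (`condition` is one of the two study labels, e.g.
#'   `"H"` / `"DK"`).
#' @param genes data frame with `gene_id`, `chrom`, `tss` columns.
#' @param window maximum summit-to-TSS distance in bp (default 40000).
#' @return data frame `region_id`, `gene_id`, `condition`, `distance`.
#' @export
map_regions_to_genes <- function(regions, genes, window = 40000L) {
  out <- list()
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L || nrow(r) == 0L) next
    d <- abs(outer(r$summit, g$tss, "-"))
    hit <- which(d <= window, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    out[[ch]] <- data.frame(
      region_id = r$region_id[hit[, 1L]],
      gene_id = g$gene_id[hit[, 2L]],
      condition = r$condition[hit[, 1L]],
      distance = d[hit],
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L)
    return(data.frame(region_id = character(), gene_id = character(),
                      condition = character(), distance = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Differential gene-level motif affinity
#'
#' For each (matrix, gene) pair, sums the per-sequence affinities of the
#' regions mapped to the gene in the first condition and subtracts the sum
#' over regions mapped in the second condition:
#' `N[m, g] = sum_{i in H(g)} a[m, i] - sum_{i in DK(g)} a[m, i]`.
#' Genes with no mapped region in either condition are absent.
#'
#' @param region_affinity numeric matrix of per-sequence affinities,
#'   regions (rows, named by `region_id`) x matrices (columns, named by
#'   `matrix_id`).
#' @param mapping data frame from [map_regions_to_genes()].
#' @param conditions length-2 character vector giving the positive and
#'   negative condition labels (default `c("H", "DK")`).
#' @return an `affinity_table`: list with `N` (matrices x genes matrix) and
#'   the audit inputs `region_affinity` and `mapping`.
#' @export
gene_affinity <- function(region_affinity, mapping,
                          conditions = c("H", "DK")) {
  stopifnot(length(conditions) == 2L)
  mapping <- mapping[mapping$region_id %in% rownames(region_affinity), ,
                     drop = FALSE]
  sign <- ifelse(mapping$condition == conditions[1L], 1,
                 ifelse(mapping$condition == conditions[2L], -1, NA))
  if (any(is.na(sign)))
    stop("conditions other than ", paste(conditions, collapse = "/"),
         " present in mapping")
  contrib <- region_affinity[mapping$region_id, , drop = FALSE] * sign
  N <- rowsum(contrib, group = mapping$gene_id)
  structure(list(N = t(N), region_affinity = region_affinity,
                 mapping = mapping, conditions = conditions),
            class = "affinity_table")
}

#' @export
print.affinity_table <- function(x, ...) {
  cat("affinity_table:", nrow(x$N), "matrices x", ncol(x$N), "genes\n")
  invisible(x)
}

#' Univariate motif-activity regressions
#'
#' For every matrix, fits an ordinary least-squares regression with
#' intercept of differential expression (`log2fc`) on the differential
#' affinity `N[m, .]` across genes, tests the slope against zero with a
#' two-sided t-test, and applies a Bonferroni correction across all tested
#' matrices. Matrices are selected when the corrected p-value falls below
#' `alpha`. Matrices with a zero-variance predictor are skipped with a
#' warning and never selected.
#'
#' @param affinity an `affinity_table` from [gene_affinity()] (or a bare
#'   matrices x genes matrix).
#' @param genes data frame with `gene_id` and `log2fc`; when several rows
#'   share a `gene_id` the row with maximum `|log2fc|` is used
#'   (`collapse = "mean"` averages instead).
#' @param alpha selection threshold on the Bonferroni-corrected p-value
#'   (default 0.01).
#' @param collapse how to resolve duplicate gene rows, `"max"` or
#'   `"mean"`.
#' @return data frame with one row per tested matrix: `matrix_id`,
#'   `slope`, `t_stat`, `p_value`, `p_bonferroni`, `n_genes`, `selected`.
#' @export
fit_motif_regressions <- function(affinity, genes, alpha = 0.01,
                                  collapse = c("max", "mean")) {
  collapse <- match.arg(collapse)
  N <- if (inherits(affinity, "affinity_table")) affinity$N else affinity
  if (anyDuplicated(genes$gene_id)) {
    genes <- if (collapse == "max") {
      o <- order(-abs(genes$log2fc))
      genes[o, ][!duplicated(genes$gene_id[o]), ]
    } else {
      aggregate(log2fc ~ gene_id, data = genes, FUN = mean)
    }
  }
  common <- intersect(colnames(N), genes$gene_id)
  if (length(common) < 3L)
    stop("need at least 3 genes with affinity and expression values")
  y <- genes$log2fc[match(common, genes$gene_id)]
  res <- lapply(rownames(N), function(m) {
    x <- N[m, common]
    n <- length(x)
    if (sd(x) == 0) {
      warning("matrix ", m, " has zero-variance affinity; skipped")
      return(data.frame(matrix_id = m, slope = NA_real_, t_stat = NA_real_,
                        p_value = NA_real_, n_genes = n))
    }
    xc <- x - mean(x)
    yc <- y - mean(y)
    slope <- sum(xc * yc) / sum(xc^2)
    resid <- yc - slope * xc
    se <- sqrt(sum(resid^2) / (n - 2) / sum(xc^2))
    t_stat <- slope / se
    data.frame(matrix_id = m, slope = slope, t_stat = t_stat,
               p_value = 2 * pt(-abs(t_stat), df = n - 2), n_genes = n)
  })
  res <- do.call(rbind, res)
  n_tested <- sum(!is.na(res$p_value))
  res$p_bonferroni <- pmin(1, res$p_value * n_tested)
  res$selected <- !is.na(res$p_bonferroni) & res$p_bonferroni < alpha
  rownames(res) <- NULL
  res
}

#' Transcription-factor penalties from selected regressions
#'
#' Each protein mapped from a selected matrix receives a penalty equal to
#' the absolute t-statistic of that matrix's regression slope; all members
#' of a factor family sharing one matrix receive the same value. A protein
#' mapped from several selected matrices keeps the maximum `|t|`, and the
#' corresponding signed t-statistic is retained.
#'
#' @param regressions data frame from [fit_motif_regressions()]; only rows
#'   with `selected == TRUE` contribute.
#' @param matrix_map data frame with `matrix_id`, `protein_id` columns.
#' @return data frame `protein_id`, `penalty`, `source_matrix_id`,
#'   `signed_t`; unmapped selected matrices are reported in an
#'   `unmapped` attribute.
#' @export
assign_tf_penalties <- function(regressions, matrix_map) {
  sel <- regressions[isTRUE_vec(regressions$selected), , drop = FALSE]
  if (nrow(sel) == 0L) {
    out <- data.frame(protein_id = character(), penalty = numeric(),
                      source_matrix_id = character(), signed_t = numeric())
    attr(out, "unmapped") <- character()
    return(out)
  }
  unmapped <- setdiff(sel$matrix_id, matrix_map$matrix_id)
  hits <- merge(sel, matrix_map, by = "matrix_id")
  hits$abs_t <- abs(hits$t_stat)
  hits <- hits[order(-hits$abs_t), , drop = FALSE]
  hits <- hits[!duplicated(hits$protein_id), , drop = FALSE]
  out <- data.frame(protein_id = hits$protein_id, penalty = hits$abs_t,
                    source_matrix_id = hits$matrix_id,
                    signed_t = hits$t_stat, stringsAsFactors = FALSE)
  out <- out[order(out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped") <- unmapped
  out
}

isTRUE_vec <- function(x) !is.na(x) & x
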