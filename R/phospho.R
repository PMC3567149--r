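#' Map phosphopeptides to proteins by exact substring match
#'
#' A peptide maps to every protein whose sequence contains the peptide as
#' an exact substring; peptides matching several proteins (paralogs) yield
#' one pair per protein, and unmapped peptides are reported in an
#' attribute.
#'
#' @param peptides data frame with `peptide_id` and `sequence` columns
#'   (uppercase amino-acid strings).
#' @param proteome a `Biostrings::AAStringSet` keyed by protein id, or a
#'   path to a protein FASTA file.
#' @return data frame `peptide_id`, `protein_id`; unmapped peptide ids in
#'   attribute `unmapped`.
#' @export
map_peptides <- function(peptides, proteome) {
  if (is.character(proteome) && length(proteome) == 1L)
    proteome <- Biostrings::readAAStringSet(proteome)
  if (length(proteome) == 0L) stop("proteome is empty")
  names(proteome) <- sub("\\s.*$", "", names(proteome))
  prot <- as.character(proteome)
  pairs <- lapply(seq_len(nrow(peptides)), function(i) {
    hit <- which(grepl(peptides$sequence[i], prot, fixed = TRUE))
    if (length(hit) == 0L) return(NULL)
    data.frame(peptide_id = peptides$peptide_id[i],
               protein_id = names(prot)[hit], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pairs)
  if (is.null(out))
    out <- data.frame(peptide_id = character(), protein_id = character())
  rownames(out) <- NULL
  attr(out, "unmapped") <- setdiff(peptides$peptide_id, out$peptide_id)
  out
}

#' Protein penalties from phosphopeptide fold changes
#'
#' Each protein with at least one mapped peptide receives a penalty
#' proportional to the maximum absolute log2 fold change in phosphorylation
#' among its peptides: `penalty(P) = k * max |log2fc|`. A peptide mapping
#' to several proteins contributes the same value to each of them.
#'
#' @param peptides data frame with `peptide_id`, `log2fc` columns.
#' @param mapping data frame from [map_peptides()] (columns `peptide_id`,
#'   `protein_id`).
#' @param k positive proportionality constant (default 1, so phospho and
#'   transcription-factor penalties share a single beta).
#' @return data frame `protein_id`, `penalty`, `peptide_id` (the peptide
#'   attaining the maximum).
#' @export
assign_phospho_penalties <- function(peptides, mapping, k = 1) {
  stopifnot(k > 0)
  df <- merge(mapping, peptides[, c("peptide_id", "log2fc")],
              by = "peptide_id")
  if (any(!is.finite(df$log2fc))) stop("non-finite log2fc on mapped peptide")
  if (nrow(df) == 0L)
    return(data.frame(protein_id = character(), penalty = numeric(),
                      peptide_id = character()))
  df$abs_fc <- abs(df$log2fc)
  df <- df[order(-df$abs_fc), , drop = FALSE]
  df <- df[!duplicated(df$protein_id), , drop = FALSE]
  out <- data.frame(protein_id = df$protein_id, penalty = k * df$abs_fc,
                    peptide_id = df$peptide_id, stringsAsFactors = FALSE)
  out <- out[order(out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
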