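# Readers and writers for the tab-delimited external interfaces.
# Region files are BED-like: BED6 plus an absolute summit coordinate
# (column 7) and a condition label (column 8); coordinates are 0-based
# half-open throughout.

#' Write regions as an extended BED table
#'
#' Columns: chrom, start, end, name (region id), score, strand, summit
#' (absolute coordinate), condition.
#'
#' @param regions data frame with `chrom`, `start`, `end`, `region_id`,
#'   `summit`, `condition` columns.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  df <- data.frame(chrom = regions$chrom, start = regions$start,
                   end = regions$end, name = regions$region_id,
                   score = 0L, strand = ".", summit = regions$summit,
                   condition = regions$condition)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an extended BED region table
#'
#' @param path path written by [write_regions_bed()] (or any 8-column
#'   BED-like file with summit and condition in columns 7-8).
#' @return data frame `region_id`, `chrom`, `start`, `end`, `summit`,
#'   `condition`.
#' @export
read_regions_bed <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 8L) stop("expected 8 columns (BED6 + summit + condition)")
  names(df)[1:8] <- c("chrom", "start", "end", "name", "score", "strand",
                      "summit", "condition")
  bad <- df$end <= df$start | df$summit < df$start | df$summit >= df$end
  if (any(bad)) stop("invalid region at row ", which(bad)[1L])
  data.frame(region_id = df$name, chrom = df$chrom, start = df$start,
             end = df$end, summit = df$summit, condition = df$condition,
             stringsAsFactors = FALSE)
}

#' Read a tab-delimited table with required columns
#'
#' @param path file path.
#' @param required character vector of required column names.
#' @return data frame.
#' @export
read_tsv_table <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(path, " lacks required column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write a network in SIF format
#'
#' One line per edge: `node_a <tab> pp <tab> node_b`.
#'
#' @param edges data frame with `node_a`, `node_b` columns.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_sif <- function(edges, path) {
  lines <- if (nrow(edges)) paste(edges$node_a, "pp", edges$node_b,
                                  sep = "\t") else character()
  writeLines(lines, path)
  invisible(path)
}

#' Write the node and edge tables of a composite or solution network
#'
#' @param composite a `composite_network` from [merge_solutions()].
#' @param instance the originating [pcst_instance()], used to type nodes
#'   as phospho/TF termini or Steiner nodes.
#' @param dir output directory.
#' @param prefix file-name prefix (default `"network"`).
#' @return character vector of written paths, invisibly.
#' @export
write_network_tables <- function(composite, instance, dir,
                                 prefix = "network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  src <- instance$penalty_source
  node_type <- function(v) {
    if (!(v %in% instance$termini)) return("steiner")
    s <- if (!is.null(src) && v %in% names(src)) src[[v]] else "terminal"
    if (s %in% c("phospho", "tf")) paste0("terminal_", s) else "terminal"
  }
  nodes <- data.frame(
    id = composite$nodes$node,
    type = vapply(composite$nodes$node, node_type, character(1)),
    penalty = unname(instance$penalty[composite$nodes$node]),
    multiplicity = composite$nodes$multiplicity)
  p_nodes <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  p_edges <- file.path(dir, paste0(prefix, "_edges.tsv"))
  p_sif <- file.path(dir, paste0(prefix, ".sif"))
  write.table(nodes, p_nodes, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(composite$edges, p_edges, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_sif(composite$edges, p_sif)
  invisible(c(p_nodes, p_edges, p_sif))
}
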