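#' Load protein-protein interactions
#'
#' Reads a tab-delimited interaction file into a data frame of interactions.
#' Two layouts are supported: a plain edge list with at least three columns
#' (`node_a`, `node_b`, `confidence`, optionally `n_publications`,
#' `method_score`, `type_score`), and a minimal MITAB 2.5 subset in which
#' columns 1 and 2 carry interactor identifiers and column 15 a
#' `score:<value>` confidence entry.
#'
#' Parsing is non-lossy: duplicate rows and self-interactions are kept (and
#' the latter flagged) so that [build_graph()] can report what it drops.
#'
#' @param path path to the interaction file.
#' @param format `"edge_list"` or `"mitab_lite"`.
#' @return a data frame with columns `node_a`, `node_b`, `confidence`,
#'   `n_publications`, `method_score`, `type_score` (optional evidence
#'   columns are `NA` when absent) and `self_interaction`.
#' @export
load_interactions <- function(path, format = c("edge_list", "mitab_lite")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("interaction file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no interaction rows in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # plain edge lists may be space-delimited as well
  if (format == "edge_list" && all(lengths(fields) == 1L)) {
    fields <- strsplit(lines, "[[:space:]]+")
  }
  parse_row <- function(f, i) {
    if (format == "edge_list") {
      if (length(f) < 3L)
        stop("malformed interaction row at line ", i, ": need >= 3 columns")
      conf <- suppressWarnings(as.numeric(f[3L]))
      if (is.na(conf))
        stop("non-numeric confidence at line ", i, ": '", f[3L], "'")
      np <- if (length(f) >= 4L) suppressWarnings(as.numeric(f[4L])) else NA_real_
      ms <- if (length(f) >= 5L) suppressWarnings(as.numeric(f[5L])) else NA_real_
      ts <- if (length(f) >= 6L) suppressWarnings(as.numeric(f[6L])) else NA_real_
      list(a = f[1L], b = f[2L], conf = conf, np = np, ms = ms, ts = ts)
    } else {
      if (length(f) < 15L)
        stop("malformed MITAB row at line ", i, ": need >= 15 columns")
      sc <- regmatches(f[15L], regexec("score:([0-9.eE+-]+)", f[15L]))[[1L]]
      if (length(sc) < 2L)
        stop("no parsable 'score:' entry at line ", i)
      conf <- suppressWarnings(as.numeric(sc[2L]))
      if (is.na(conf))
        stop("non-numeric confidence at line ", i, ": '", sc[2L], "'")
      strip_db <- function(x) sub("^[^:]*:", "", x)
      list(a = strip_db(f[1L]), b = strip_db(f[2L]), conf = conf,
           np = NA_real_, ms = NA_real_, ts = NA_real_)
    }
  }
  rows <- Map(parse_row, fields, seq_along(fields))
  out <- data.frame(
    node_a = vapply(rows, `[[`, character(1), "a"),
    node_b = vapply(rows, `[[`, character(1), "b"),
    confidence = vapply(rows, `[[`, numeric(1), "conf"),
    n_publications = vapply(rows, `[[`, numeric(1), "np"),
    method_score = vapply(rows, `[[`, numeric(1), "ms"),
    type_score = vapply(rows, `[[`, numeric(1), "ts"),
    stringsAsFactors = FALSE
  )
  if (any(out$node_a == "" | out$node_b == ""))
    stop("empty interactor identifier at line ",
         which(out$node_a == "" | out$node_b == "")[1L])
  bad <- which(out$confidence <= 0 | out$confidence > 1)
  if (length(bad))
    stop("confidence outside (0,1] at line ", bad[1L], ": ",
         out$confidence[bad[1L]])
  out$self_interaction <- out$node_a == out$node_b
  out
}

#' Score interactions from evidence fields
#'
#' Replaces the confidence column by a weighted mean of three evidence
#' components: a publication count saturating at `pub_saturation`, an
#' experimental-method score and an interaction-type score, each in
#' `[0, 1]`. The result is clipped to `(1e-6, 1]` so that downstream edge
#' costs `-log(s)` stay finite. The incoming confidence is preserved in a
#' `confidence_original` column.
#'
#' @param interactions data frame from [load_interactions()].
#' @param weights named numeric vector `c(pub=, method=, type=)`,
#'   nonnegative and not all zero.
#' @param pub_saturation positive integer; publication counts at or above
#'   this value contribute the maximal publication component.
#' @return the interactions data frame with recomputed `confidence`.
#' @export
score_interactions <- function(interactions,
                               weights = c(pub = 1, method = 1, type = 1),
                               pub_saturation = 5L) {
  stopifnot(pub_saturation >= 1)
  w <- weights[c("pub", "method", "type")]
  if (any(is.na(w)) || any(w < 0) || sum(w) <= 0)
    stop("weights must be nonnegative, named pub/method/type, not all zero")
  need <- c("n_publications", "method_score", "type_score")
  miss <- vapply(need, function(col) any(is.na(interactions[[col]])), logical(1))
  if (any(miss))
    stop("missing evidence fields: ", paste(need[miss], collapse = ", "))
  pub_comp <- pmin(interactions$n_publications, pub_saturation) / pub_saturation
  s <- (w[["pub"]] * pub_comp +
          w[["method"]] * interactions$method_score +
          w[["type"]] * interactions$type_score) / sum(w)
  interactions$confidence_original <- interactions$confidence
  interactions$confidence <- pmin(pmax(s, 1e-6), 1)
  interactions
}

#' Build the cost-weighted interactome graph
#'
#' Converts interactions into an undirected graph whose edges carry both a
#' confidence `s` in `(0, 1]` and a cost `c = -log(s)`, so that minimizing
#' a sum of edge costs maximizes the product of interaction likelihoods.
#' Self-interactions are dropped, parallel edges are collapsed keeping the
#' maximum confidence, and every identifier in `exclude` (for example a
#' promiscuous hub such as ubiquitin) is removed with its incident edges.
#'
#' @param interactions data frame from [load_interactions()] (or with at
#'   least `node_a`, `node_b`, `confidence` columns).
#' @param exclude character vector of node identifiers to remove.
#' @return a `weighted_graph` object: list with `nodes` (sorted ids),
#'   `edges` (data frame `node_a`, `node_b`, `confidence`, `cost`) and a
#'   `report` of dropped loops / collapsed duplicates / excluded nodes.
#' @export
build_graph <- function(interactions, exclude = character()) {
  stopifnot(all(c("node_a", "node_b", "confidence") %in% names(interactions)))
  if (any(interactions$confidence <= 0 | interactions$confidence > 1))
    stop("confidences must lie in (0,1]")
  loops <- interactions$node_a == interactions$node_b
  df <- interactions[!loops, c("node_a", "node_b", "confidence")]
  # canonical unordered orientation, then max-confidence dedup
  a <- pmin(df$node_a, df$node_b)
  b <- pmax(df$node_a, df$node_b)
  key <- paste(a, b, sep = "\r")
  n_dups <- sum(duplicated(key))
  conf <- tapply(df$confidence, key, max)
  keys <- strsplit(names(conf), "\r", fixed = TRUE)
  edges <- data.frame(
    node_a = vapply(keys, `[[`, character(1), 1L),
    node_b = vapply(keys, `[[`, character(1), 2L),
    confidence = as.numeric(conf),
    stringsAsFactors = FALSE
  )
  keep <- !(edges$node_a %in% exclude | edges$node_b %in% exclude)
  n_excluded_nodes <- length(intersect(exclude,
                                       unique(c(df$node_a, df$node_b))))
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) == 0L) stop("graph is empty after exclusion")
  edges$cost <- -log(edges$confidence)
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(
      nodes = sort(unique(c(edges$node_a, edges$node_b))),
      edges = edges,
      report = list(dropped_self_loops = sum(loops),
                    collapsed_duplicates = n_dups,
                    excluded_nodes = n_excluded_nodes)
    ),
    class = "weighted_graph"
  )
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat("weighted_graph:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat(sprintf("  confidence range [%.4g, %.4g]; cost range [%.4g, %.4g]\n",
              min(x$edges$confidence), max(x$edges$confidence),
              min(x$edges$cost), max(x$edges$cost)))
  invisible(x)
}

# igraph view with cost as weight and confidence preserved
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "weighted_graph"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = graph$edges$node_a, to = graph$edges$node_b,
               weight = graph$edges$cost,
               confidence = graph$edges$confidence),
    directed = FALSE,
    vertices = data.frame(name = graph$nodes)
  )
  g
}

# rebuild a weighted_graph from an edge table (internal, used by IO and subsetting)
graph_from_edges <- function(edges) {
  build_graph(edges[, c("node_a", "node_b", "confidence")])
}

# drop a node set from a weighted_graph (used by the suboptimal machinery)
drop_nodes <- function(graph, nodes) {
  keep <- !(graph$edges$node_a %in% nodes | graph$edges$node_b %in% nodes)
  edges <- graph$edges[keep, , drop = FALSE]
  if (nrow(edges) == 0L) return(NULL)
  rownames(edges) <- NULL
  structure(
    list(nodes = sort(unique(c(edges$node_a, edges$node_b))),
         edges = edges,
         report = graph$report),
    class = "weighted_graph"
  )
}

#' Write the canonical edge table
#'
#' @param graph a `weighted_graph`.
#' @param path output path for the tab-delimited table
#'   (`node_a`, `node_b`, `confidence`, `cost`).
#' @return the path, invisibly.
#' @export
write_edge_table <- function(graph, path) {
  write.table(graph$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
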