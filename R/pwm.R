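#' Construct a position weight matrix object
#'
#' @param matrix_id identifier.
#' @param counts 4 x L numeric matrix of nonnegative base counts with rows
#'   in A, C, G, T order (rownames are set accordingly).
#' @param pseudocount positive regularizer added to every cell before
#'   column normalization (default 0.1).
#' @param background length-4 positive base frequencies summing to 1.
#' @return an object of class `pwm`.
#' @export
pwm <- function(matrix_id, counts, pseudocount = 0.1,
                background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 4L) stop("motif length must be >= 4")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8)
    stop("background must be 4 positive probabilities summing to 1")
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(matrix_id = matrix_id, counts = counts,
                 pseudocount = pseudocount,
                 background = as.numeric(background)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm", x$matrix_id, "- length", ncol(x$counts),
      "consensus", pwm_consensus(x), "\n")
  invisible(x)
}

# pseudocount-normalized column probabilities (4 x L, rows A,C,G,T)
pwm_probs <- function(x) {
  p <- x$counts + x$pseudocount
  sweep(p, 2, colSums(p), "/")
}

#' Motif length of a PWM
#' @param x a `pwm`.
#' @return integer number of columns.
#' @export
pwm_length <- function(x) ncol(x$counts)

#' Consensus sequence of a PWM (most probable base per column)
#' @param x a `pwm`.
#' @return character string of length `pwm_length(x)`.
#' @export
pwm_consensus <- function(x) {
  p <- pwm_probs(x)
  paste(rownames(p)[apply(p, 2, which.max)], collapse = "")
}

# maximum achievable single-window log-odds (same on either strand)
pwm_max_logodds <- function(x) {
  p <- pwm_probs(x)
  sum(apply(log(p / x$background), 2, max))
}

#' Read a TRANSFAC-format matrix library
#'
#' Parses the minimal TRANSFAC flat-file layout: records delimited by
#' `//`, an `ID` line, a `P0` (or `PO`) header giving the base column
#' order, numbered count rows and an `XX` terminator. Other record fields
#' are ignored.
#'
#' @param path path to the matrix file.
#' @param pseudocount,background passed to [pwm()] for every matrix.
#' @return named list of `pwm` objects.
#' @export
read_transfac <- function(path, pseudocount = 0.1,
                          background = rep(0.25, 4)) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path)
  pwms <- list()
  id <- NULL
  order_idx <- NULL
  rows <- list()
  flush <- function() {
    if (is.null(id)) return()
    if (length(rows) < 4L) stop("matrix ", id, " shorter than 4 positions")
    mat <- do.call(rbind, rows)           # positions x 4, file column order
    counts <- t(mat)[order_idx, , drop = FALSE] # -> 4 x L in A,C,G,T order
    pwms[[id]] <<- pwm(id, counts, pseudocount, background)
  }
  for (ln in lines) {
    tag <- substr(ln, 1, 2)
    if (tag == "ID") {
      id <- trimws(substr(ln, 3, nchar(ln)))
    } else if (tag %in% c("P0", "PO")) {
      bases <- toupper(strsplit(trimws(substr(ln, 3, nchar(ln))),
                                "[[:space:]]+")[[1]])
      if (!setequal(bases, c("A", "C", "G", "T")))
        stop("P0 header of ", id, " must list A C G T")
      order_idx <- match(c("A", "C", "G", "T"), bases)
      rows <- list()
    } else if (grepl("^[0-9]+", ln)) {
      f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      vals <- suppressWarnings(as.numeric(f[2:5]))
      if (any(is.na(vals))) stop("unparsable count row in ", id, ": ", ln)
      rows[[length(rows) + 1L]] <- vals
    } else if (tag == "//") {
      flush()
      id <- NULL
      order_idx <- NULL
      rows <- list()
    }
  }
  flush()
  if (length(pwms) == 0L) stop("no matrices found in ", path)
  pwms
}

#' Write PWMs in TRANSFAC format
#'
#' @param pwms list of `pwm` objects.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_transfac <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (x in pwms) {
    writeLines(c(paste("ID", x$matrix_id), "P0      A      C      G      T"),
               con)
    cons <- strsplit(pwm_consensus(x), "")[[1]]
    for (j in seq_len(ncol(x$counts))) {
      writeLines(sprintf("%02d %6g %6g %6g %6g %s", j,
                         x$counts["A", j], x$counts["C", j],
                         x$counts["G", j], x$counts["T", j], cons[j]), con)
    }
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}

# integer-encode a DNA string: A=1 C=2 G=3 T=4, anything else 0
encode_dna <- function(sequence) {
  m <- match(strsplit(toupper(as.character(sequence)), "")[[1]],
             c("A", "C", "G", "T"))
  m[is.na(m)] <- 0L
  as.integer(m)
}
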