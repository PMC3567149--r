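#' Motif match scores for a set of sequences
#'
#' Scores every sequence against every PWM by the maximum log-odds window
#' score over both strands (see [max_logodds_score()]). A binary "match"
#' call is also returned: a sequence matches a motif when its best window
#' reaches at least `match_fraction` of the motif's maximum achievable
#' log-odds.
#'
#' @param pwms list of [pwm()] objects.
#' @param sequences named character vector of DNA sequences.
#' @param match_fraction fraction of the maximum achievable log-odds
#'   required for a match call (default 0.8).
#' @return list with `scores` (sequences x motifs matrix of max log-odds)
#'   and `matches` (logical matrix of the same shape).
#' @export
motif_match_scores <- function(pwms, sequences, match_fraction = 0.8) {
  sc <- scan_pwm_set(pwms, sequences)$max_logodds
  maxlo <- vapply(pwms, pwm_max_logodds, numeric(1))
  thr <- match_fraction * maxlo
  matches <- sweep(sc, 2, thr, ">=")
  list(scores = sc, matches = matches)
}

#' Cross-validated motif discrimination of positive vs negative regions
#'
#' Ranks motifs by their ability to distinguish positive from negative
#' region sequences: within each of `folds` cross-validation iterations,
#' motifs are ordered by the Wilcoxon rank-sum p-value comparing their
#' match scores in the training positives against the training negatives,
#' and the `top_k` motifs of each iteration are recorded. Fold assignment
#' is seeded and reproducible.
#'
#' @param positives,negatives named character vectors of region sequences
#'   (at least `folds` of each).
#' @param pwms list of [pwm()] objects.
#' @param folds number of cross-validation folds (default 5).
#' @param top_k motifs recorded per fold (default 20).
#' @param seed integer seed for fold assignment.
#' @return list with `per_fold` (list of data frames `matrix_id`,
#'   `p_value`, `rank`), `top_motifs` (list of the per-fold top-`top_k`
#'   ids) and `fold_assignment`.
#' @export
motif_discrimination_cv <- function(positives, negatives, pwms, folds = 5L,
                                    top_k = 20L, seed = 1L) {
  if (length(positives) < folds || length(negatives) < folds)
    stop("need at least ", folds, " positive and negative regions")
  scores <- rbind(
    motif_match_scores(pwms, positives)$scores,
    motif_match_scores(pwms, negatives)$scores
  )
  is_pos <- c(rep(TRUE, length(positives)), rep(FALSE, length(negatives)))
  assignment <- local_seed(seed, {
    f <- integer(length(is_pos))
    f[is_pos] <- sample(rep_len(seq_len(folds), sum(is_pos)))
    f[!is_pos] <- sample(rep_len(seq_len(folds), sum(!is_pos)))
    f
  })
  per_fold <- lapply(seq_len(folds), function(fold) {
    train <- assignment != fold
    p <- vapply(seq_len(ncol(scores)), function(j) {
      suppressWarnings(
        wilcox.test(scores[train & is_pos, j], scores[train & !is_pos, j],
                    alternative = "greater", exact = FALSE)$p.value)
    }, numeric(1))
    ord <- order(p, colnames(scores))
    data.frame(matrix_id = colnames(scores)[ord], p_value = p[ord],
               rank = seq_along(ord), stringsAsFactors = FALSE)
  })
  list(per_fold = per_fold,
       top_motifs = lapply(per_fold, function(df)
         head(df$matrix_id, top_k)),
       fold_assignment = assignment)
}
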