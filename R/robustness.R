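#' Multiplicative Gaussian perturbation of nonnegative values
#'
#' Multiplies each value by an independent draw from `Normal(1, sd)`,
#' truncating negative factors at zero so that penalties and edge costs
#' stay in their valid domains. Seeded and reproducible.
#'
#' @param values nonnegative numeric vector.
#' @param sd standard deviation of the multiplicative factor (>= 0).
#' @param seed integer seed.
#' @return perturbed values.
#' @export
perturb_values <- function(values, sd, seed = 1L) {
  if (sd < 0) stop("sd must be nonnegative")
  if (sd == 0) return(values)
  local_seed(seed, values * pmax(0, rnorm(length(values), mean = 1, sd = sd)))
}

#' Noise-robustness analysis of a PCST solution
#'
#' Re-solves the instance `reps` times per noise level with either node
#' penalties or edge costs multiplied by `Normal(1, sd)` factors
#' (truncated at zero) and summarizes, against the unperturbed solution,
#' the node retention (fraction of original solution nodes recovered) and
#' the Jaccard index of the node sets.
#'
#' @param instance a [pcst_instance()].
#' @param sds noise standard deviations to evaluate.
#' @param reps perturbed replicates per noise level (default 100).
#' @param target `"penalties"` or `"costs"`.
#' @param seed integer base seed; replicate `r` at level `i` uses a seed
#'   derived deterministically from it.
#' @param solver,node_limit,n_roots solver settings, as in
#'   [solve_pcst()].
#' @return data frame with one row per sd: `sd`, `target`, `reps`,
#'   `mean_retention`, `se_retention`, `mean_jaccard`, `se_jaccard`
#'   (standard errors are `NA` when `reps == 1`).
#' @export
robustness_suite <- function(instance, sds, reps = 100L,
                             target = c("penalties", "costs"), seed = 1L,
                             solver = c("heuristic", "exact"),
                             node_limit = 18L, n_roots = 3L) {
  target <- match.arg(target)
  solver <- match.arg(solver)
  original <- solve_pcst(instance, solver, seed = seed,
                         node_limit = node_limit, n_roots = n_roots)
  orig_nodes <- original$nodes
  if (length(orig_nodes) == 0L)
    stop("original solution is empty; robustness undefined")
  rows <- lapply(seq_along(sds), function(i) {
    sd_i <- sds[i]
    ret <- jac <- numeric(reps)
    for (r in seq_len(reps)) {
      rep_seed <- seed + 7919L * i + r
      inst_r <- instance
      if (target == "penalties") {
        inst_r$penalty <- perturb_values(instance$penalty, sd_i, rep_seed)
        inst_r$termini <- names(inst_r$penalty)[inst_r$penalty > 0]
      } else {
        inst_r$graph$edges$cost <-
          perturb_values(instance$graph$edges$cost, sd_i, rep_seed)
      }
      sol <- solve_pcst(inst_r, solver, seed = seed,
                        node_limit = node_limit, n_roots = n_roots)
      inter <- length(intersect(sol$nodes, orig_nodes))
      ret[r] <- inter / length(orig_nodes)
      jac[r] <- inter / length(union(sol$nodes, orig_nodes))
    }
    se <- function(x) if (reps > 1L) sd(x) / sqrt(reps) else NA_real_
    data.frame(sd = sd_i, target = target, reps = reps,
               mean_retention = mean(ret), se_retention = se(ret),
               mean_jaccard = mean(jac), se_jaccard = se(jac))
  })
  do.call(rbind, rows)
}
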