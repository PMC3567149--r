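---
title: "Linking phosphoproteomic and transcriptional responses with prize-collecting Steiner trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking phosphoproteomic and transcriptional responses with prize-collecting Steiner trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Signaling and transcription respond to the same perturbation but are
measured by disconnected assays. `prizelink` treats both measurements as
*prizes* on proteins of a weighted interactome and asks for the cheapest
connected explanation. With edge confidences $s(e) \in (0,1]$ turned into
costs $c(e) = -\log s(e)$, node penalties $p(v) \ge 0$ and a scale
parameter $\beta > 0$, the prize-collecting Steiner tree objective is

$$ f(T) \;=\; \beta \sum_{v \notin T} p(v) \;+\; \sum_{e \in T} c(e), $$

minimized over subtrees $T$ of the interactome, with the empty tree and
all single-node trees admissible. Under the negative-log transform,
minimizing summed edge costs is exactly maximizing the product of the
interaction likelihoods along the tree — the reason this transform is
fixed rather than configurable (any other log base rescales all costs by a
constant that $\beta$ absorbs). Because a single-node tree pays one
penalty fewer than the empty tree at zero cost, the solution degenerates
to (at most) a singleton, never strictly to the empty set, as
$\beta \to 0$.

Confidences are either taken from the input (pass-through, the default) or
recomputed by a simplified evidence scorer: a weighted mean of a
publication count saturating at 5 publications, a method score and an
interaction-type score, clipped to $(10^{-6}, 1]$ so costs stay finite.
Duplicate edges keep the *maximum* confidence on the grounds that
consolidated interaction databases contain redundant records of the same
evidence; promiscuous hubs (classically ubiquitin) can be excluded by
identifier before solving.

## Node penalties

**Phosphoproteomic termini.** Peptides map to every protein containing
them as an exact substring (the conservative analogue of keeping only
perfect alignments), and a protein's penalty is $k \cdot \max |\log_2
\text{FC}|$ over its peptides. $k$ defaults to 1 so that both penalty
types share a single $\beta$; it exists as a knob for rebalancing the two
data levels.

**Transcription-factor termini.** For each position weight matrix $m$
(pseudocount 0.1 per cell, uniform background by default), the affinity of
a 200 bp summit-centered sequence is the TRAP-style sum over all windows
on both strands of the likelihood ratio of the window under the motif
versus background; windows containing `N` are skipped. Differential
hypersensitive regions are labeled by the condition in which they are more
accessible, mapped to genes by summit-to-TSS distance (inclusive at the
default 40 kb), and aggregated per gene as
$N[m,g] = \sum_{i \in H(g)} a_{m,i} - \sum_{i \in DK(g)} a_{m,i}$.
The *difference* form was chosen because the regressand is differential
expression, so the predictor must be differential too; a condition-wise
alternative can be assembled from the retained per-sequence scores, which
the affinity table keeps for audit. Ordinary least squares of expression
log2 fold change on $N[m,\cdot]$ (with intercept) is fitted per motif, the
slope tested with a two-sided $t$-test, and motifs selected at
Bonferroni-corrected $p < 0.01$. Every protein in a selected motif's
family receives penalty $|t|$; a protein reached by several selected
motifs keeps the largest $|t|$ (the most confident evidence, mirroring the
max rule for peptides; the tie case is not specified by the data and had
to be fixed somehow). When several expression rows map to one gene the
maximum-$|\log_2\text{FC}|$ row is used, with a mean option.

## Solvers

The **exact solver** observes that for a fixed node set the cheapest
spanning structure is the minimum spanning tree of the induced subgraph,
so it enumerates node subsets (in C++; refusing instances above
`node_limit = 18`) and returns a global optimum, breaking objective ties
toward the lexicographically smallest sorted node-id list so results are
stable under permutation of the input. The test suite checks it against an
independent brute force that enumerates *edge* subsets instead.

The **heuristic** targets interactome-scale instances: from each of a few
seeded root termini it greedily absorbs the terminus with the best
$\beta p - \text{path cost}$ gain along shortest cost paths, re-treeifies
the node set as an MST, and applies strong pruning (a subtree is dropped
when its collected prizes cannot pay for the edge attaching it). The best
result over roots, the empty tree and the best singleton is returned, so
its objective never exceeds the trivial closed-form bounds and, on
instances small enough to solve exactly, stays well inside the factor-2
band expected of Goemans–Williamson-style schemes (worst observed ratio on
200 random instances is reported by the acceptance script).

**Suboptimal solutions and composites.** Alternative explanations are
produced by forbidding a random subset of at least
$\lceil 0.15\,|V(T^*)| \rceil$ optimal nodes and re-solving; objectives
are always evaluated against the original instance, so every suboptimal
objective dominates the optimum. The "15 % different" constraint is read
as *exclusion* of optimal nodes (additions are unconstrained); the
alternative readings (symmetric difference, additions) would need a
constraint mechanism the re-solve approach cannot express. The composite
network is the union of all solutions with per-node and per-edge
multiplicities — multiplicity acts as a robustness weight.

**Choosing β.** `beta_sweep()` re-solves across a grid (default 10–120 in
steps of 10) and reports the efficiency ratio — included termini per
Steiner node — leaving the choice to inspection rather than automating it:
the ratio is deliberately a diagnostic, because "small network, high
efficiency" is a trade-off without a canonical scalarization.

## Validation statistics

`hypergeom_tail()` is the one-sided Fisher enrichment probability
$P(X \ge k)$ computed in log space. The minimum-hypergeometric (mHG)
statistic scans every prefix of a ranked 0/1 membership vector and takes
the minimal tail; its exact p-value is computed by the $O(NB)$
lattice-path dynamic program that propagates path probabilities over the
$(n, b)$ grid and absorbs mass at cells whose tail falls at or below the
observed minimum. Both are validated against exhaustive enumeration for
$N \le 12$, a 20,000-permutation estimate at $N = 50$, and a null
calibration check $P(p \le \alpha) \le \alpha$ at $\alpha \in \{0.01,
0.05, 0.1\}$. Directional tests reverse the ranking for down-regulation.

Region-overlap enrichment counts $\ge 1$ shared base on 0-based half-open
intervals (adjacent intervals do not overlap). Motif-discrimination CV
ranks motifs per fold by the Wilcoxon p-value of their best-window
log-odds scores in training positives vs negatives, recording the top 20
per fold; per-fold lists are emitted un-aggregated so any downstream
aggregation can be formed. A motif "match" is a window reaching 80 % of
the motif's maximum achievable log-odds — a transparent threshold standing
in for proprietary matrix-similarity cutoffs. Group comparisons of
enrichment p-values use Student's t-test on raw p-values by default (with
a $-\log_{10}$ flag, since t-tests on raw p-values are statistically
unusual but are the documented convention here); rank comparisons use a
Wilcoxon rank-sum on average-tie ranks, switching to exact enumeration
when both groups have at most 10 members.

## Robustness analysis

Penalties or edge costs are multiplied by $\mathcal N(1, \sigma)$ draws,
truncated at zero to keep both quantities in their domains (truncation,
not resampling, because at large $\sigma$ resampling would bias the factor
mean upward). Per noise level the instance is re-solved with identical
solver settings and the solution compared to the unperturbed one by node
retention and Jaccard index; means and standard errors over (default) 100
replicates are reported, with the standard error flagged `NA` for a single
replicate.

## What the synthetic generator emulates — and what it does not

The generator is the package's study-conditions definition, not a tuning
dial. Its defaults: a 300-node preferential-attachment interactome
(2 edges per new node) with a planted connected subtree covering a
uniformly drawn 8–15 % of nodes; planted-edge confidences
$\mathrm{Beta}(4,2) + 0.25$ (clipped) versus $\mathrm{Beta}(2,4)$
elsewhere, so true edges are cheaper but overlap the background; 20 true
phosphopeptides on distinct planted nodes with
$|\log_2\text{FC}| \sim \mathrm{Exp}(\text{mean }2) + 1$ against 8 noise
peptides at $\mathrm{Exp}(\text{mean }0.6)$ on random background nodes;
200 genes spaced 25 kb on a synthetic chromosome with
$\mathrm{Poisson}(2)$ hypersensitive regions per gene and condition;
30 PWMs of which 3 are active, their instances planted
$\mathrm{Poisson}(1.2)$ per H region versus $\mathrm{Poisson}(0.1)$ per DK
region under an occupancy mask so recorded sites are never overwritten.
Expression is generated from the package's *own* affinity computation
($\log_2\text{FC} = \sum_m \beta_m N[m,g] + \varepsilon$), which isolates
regression correctness from any ambiguity in the affinity definition:
noiseless recovery is exact by construction. Effect sizes default to
alternating-sign magnitudes scaled to unit per-motif signal SD, and the
noise SD to a quarter of the signal SD. The synthetic PCST uses
$\beta = 1$: penalties are $O(3)$ and planted edge costs $O(0.15)$, which
puts prize collection and connection costs on the same scale without any
sweep.

Passing the recovery suites therefore demonstrates internal consistency
and statistical power under scale-free topology, exponential-tailed
signals and Gaussian expression noise. It does **not** demonstrate
robustness to what real data add: mapping ambiguity between probes, genes
and proteins; correlated motif families sharing binding sites; chromatin
signal that is continuous rather than binary by condition; interactome
ascertainment bias; or batch structure. Sizes were chosen so the whole
suite runs at desk scale (the exact-solver oracles use 6–12-node
instances, the end-to-end checks 300-node interactomes), which the methods
here treat as a design choice of the benchmark, with real-data scale
handled by the heuristic solver.

## Numerical choices and degenerate inputs

- Confidence floor $10^{-6}$ (finite costs); objective comparisons at
  tolerance $10^{-9}$; mHG threshold comparisons use a $1 + 10^{-9}$
  relative guard so ties at the minimum are absorbed consistently with
  enumeration.
- Coordinates are 0-based half-open everywhere; summit slices truncate at
  chromosome ends with a recorded flag; the 40 kb gene window is inclusive
  at the boundary.
- Zero-variance affinity predictors are skipped with a warning and never
  selected; the Bonferroni factor counts only tested motifs.
- Degenerate mHG vectors (all ones / all zeros) and empty rank groups are
  rejected with errors rather than given conventional values.
- All generators and samplers run under `withr::with_seed`, so they are
  pure functions of (configuration, seed) and leave the caller's RNG
  untouched.

## Known limitations

The exact solver is exponential and hard-capped; the heuristic carries no
formal guarantee (its empirical factor is monitored instead). Suboptimal
solutions are found by node deletion, which cannot force *additions* of
new nodes. The evidence scorer is a transparent stand-in for full
ontology-weighted interaction scoring. Motif matching uses log-odds
thresholds, not curated per-matrix cutoffs. The regression is univariate
per motif by design — correlated motifs each earn their own penalty rather
than competing in a joint model.
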