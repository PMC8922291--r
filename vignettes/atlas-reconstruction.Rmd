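---
title: "Reconstructing gene interaction atlases by divide and conquer"
author: "netatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing gene interaction atlases by divide and conquer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bayesian-network structure learning recovers nonlinear, probabilistic
dependencies between genes, but its cost grows so quickly with the number of
nodes that whole-interactome reconstruction (tens of thousands of genes) is
out of reach in one shot. `netatlas` implements a divide-and-conquer
workflow: genes are first *clustered* by expression profile; an interaction
network is learned *within* each cluster; each cluster is summarized by one
*representative gene*; a network learned over the representatives (the
"network of clusters") decides which clusters to *merge*; every merge learns
a network over the union of the two clusters; and the strength values a gene
pair accumulates across these runs are *aggregated* into a single ranked
edge list, the reconstructed atlas.

## The model and its components

### Truth atlases from pathway graphs

The ground truth is an undirected gene–gene graph assembled from pathway
graphs. Pathways reference each other through "map" nodes; when pathways X
and Y reference each other, every gene of X linked (directly, or indirectly
through non-gene entries such as compounds or groups) to the map node for Y
is connected to every such gene of Y — the bipartite product of the two
linked gene sets. `readKGML()` extracts gene nodes, map nodes, gene edges
and gene–map links from KGML, and `mergePathways()` applies the rule. Two
readings of "indirect link" are possible; we take paths whose intermediate
entries are all non-gene, non-map entries, which matches the KGML entity
model without recruiting unrelated genes. One-sided references add no cross
edges: the linked gene sets are defined symmetrically, so we require
reciprocity.

### Knowledge prior (BNP)

External knowledge enters as a binary *evidence matrix*: rows are unordered
gene pairs, columns are evidence types (affinity capture, two-hybrid,
co-citation, ...). A pair supported by two or more knowledge-base types is
labeled as a gene interaction (GI = 1). A discrete Bayesian network — the
*Bayesian Network Prior* — is then learned over the evidence types plus the
GI node by hill climbing with the BIC score, with 1000-replicate bootstrap
model averaging at full scale (desk-scale runs here use 100–200), keeping
arcs whose strength exceeds a data-driven threshold (below). Instantiating
the evidence nodes for a pair and querying GI by exact inference yields
π(pair) = P(GI = 1 | evidence).

Expression data reach BNP inference through one *experimental* evidence
type: a coexpression indicator, 1 when |Pearson r| of the two genes'
profiles ≥ ρ₀ (default 0.5). The original description instantiates BNP
"with the expression profiles" without spelling out the mechanism; a
dichotomized coexpression node is the only channel compatible with a
binary-evidence network, and we flag it as experimental so it never counts
toward the GI labeling rule. This is a declared reconstruction, and ρ₀ is
configurable.

### MAP structure learning within gene sets

For a gene set, the learner's observations are *pairwise fold changes*: one
row per (test sample, control sample) pair, holding each gene's log2 ratio
(20 × 20 samples give 400 rows). Rows are discretized into
down / unchanged / up at ±τ (default τ = 1, i.e. two-fold change; the
convention is standard and the cited discretization is not restated in the
source). The structure-search objective is

  score(G) = BIC(G; data) + κ · log P(G),  log P(G) = Σ_pairs [log π if
  the skeleton joins the pair, else log(1 − π)]

with κ the prior weight (default 1; whether the original P(G) carries a
weight is not stated, so it is exposed as configuration). Both terms are
edge-decomposable, which the search exploits. π values are clamped to
[10⁻³, 1 − 10⁻³] so the log-prior is always finite.

Search is steepest-ascent hill climbing over add/delete/reverse single-arc
moves (Rcpp); among equal gains, delete is preferred over reverse over add,
then the first arc in scan order, so runs are reproducible. Default random
restarts: 2 for a single search; bootstrap replicates run without restarts,
since averaging across replicates already explores the space and this keeps
the 100–1000-replicate loops affordable. Bootstrap rows are resampled with
replacement from the fold-change observation table (not the underlying
samples), one child seed per replicate, so the replicate count can change
without reshuffling earlier replicates; rows are canonicalized first, making
strengths independent of input row order.

### Significance threshold

Arc strengths (the fraction of bootstrap networks containing a pair) are
thresholded by minimizing the L1 distance between their empirical CDF and
the ideal one-step CDF of a noise-free strength distribution,
g(t) = ∫₀^t F + ∫ₜ¹ (1 − F). g is piecewise linear with knots at observed
values; the midpoint of the minimizing interval is returned, and edges are
significant when strictly above it. When every strength is identical the
threshold sits just below that value (retaining all — the conservative
reading of "significant"), with a warning. Note one consequence: when most
strengths are exactly zero, the minimizer is t = 0 and any occasionally
recovered arc is retained; the aggregation and ranking downstream, not the
thresholded set, carry the headline evaluation.

### Representatives and merging

Each cluster's consensus network is summarized by its most central node.
A fixed battery of six centrality measures — degree, betweenness,
closeness, harmonic closeness, eigenvector, PageRank — is computed on the
largest connected component (the full ~50-measure catalogue of the original
toolkit mostly requires special structure; six covers the standard
centrality families and keeps selection deterministic). The measures are
standardized and the one with the largest absolute loading on the first
principal component is used to pick the representative; PC sign ambiguity
is irrelevant under absolute loadings. Degenerate clusters fall back as
follows: an edgeless network takes the gene with the highest total absolute
correlation to its cluster mates; a singleton cluster is its own
representative.

A network over the representatives is learned the same way; each
significant edge schedules a merge of the two clusters, and the merged
union is relearned in full. A cluster linked to k others participates in k
merges, so each of its within-cluster pairs accumulates 1 + k strength
values (the within-cluster "first" value plus one per merge); cross-cluster
pairs get one value per merge that examined them. Aggregation options:
first, min, max, mean, median, and the one-step Tukey biweight with c = 5,
ε = 10⁻⁴ (the convention established for expression summarization; the
source cites but does not restate the formula). Mean is the default, the
consistently best-performing rule. Pairs never co-examined are absent from
the table and count as score 0 at evaluation; the learner has expressed no
support for them, and the PR curve needs a total ranking.

### Evaluation

Reconstruction quality is the area under the precision–recall curve over
all n(n−1)/2 candidate pairs, computed as average precision with tie
groups: all pairs sharing a score enter at one threshold and contribute the
group's cumulative precision. This convention is forced by the dominant
all-zero group — its members must not be ordered arbitrarily — and makes a
constant scorer score exactly the class prevalence, which is also the
random-classifier baseline. ROC curves are deliberately not offered: with
~2.7 × 10⁻⁴ edge prevalence at full atlas scale they are uninformative.
A discrete final edge set is also emitted (aggregated scores above the same
L1 threshold), but the headline metric always uses the continuous ranking.

## The synthetic study system

Because the real inputs are database-derived, the package ships generators
that emulate them end to end; they are first-class, tested code.

* `generateAtlas()` — pathway sizes are rounded lognormals around the mean
  size; a fraction of each pathway's genes is reused from earlier pathways
  (overlap); within a pathway, round(size·d/2) edges grow by preferential
  attachment. Desk-scale defaults (10 pathways, mean size 30, overlap 0.1,
  mean degree 3) mirror the published per-pathway scale (~34 genes per
  pathway across 337 pathways) at about 1/34 of the atlas size.
* `simulateExpression()` — each component of the undirected truth is
  oriented by BFS from a random root (the truth itself is never altered);
  non-roots follow a saturating Hill response, child mean = basal · Π over
  parents of (v/K)ʰ/(1+(v/K)ʰ) for activators and 1/(1+(v/K)ʰ) for
  repressors, h = 2, K = the parent's noiseless reference value, signs
  random per edge. A 1% constitutive leak keeps all abundances positive and
  the cascade numerically stable. Lognormal biological noise (sd 0.3) acts
  per gene and sample during propagation; experimental noise (sd 0.1) is
  applied last; 30% of roots are shifted 4-fold in the test condition.
  The published simulator's parameter settings are not stated; these
  defaults are declared once, chosen as typical two-condition microarray
  behavior, and are not revisited. 20 test + 20 control samples match the
  published design.
* `generateEvidence()` — rows are all true edges plus 3 sampled non-edges
  per edge; each of 8 evidence types fires with sensitivity 0.8 on edges
  and false-positive rate 0.05 on non-edges (independently; correlated
  evidence is not modeled).

What the generators deliberately do not reproduce: the real simulator's
source-network subsampling and noise taxonomy, microarray probe effects,
correlated evidence types, and identifier mapping. Tests passing on this
system show the machinery is correct and the workflow's relative behavior
(e.g. better clustering → better atlases) transfers; absolute published
AUC values from the 11,454-gene system are not desk-reproducible.

## Numerical choices and edge cases

* Natural logarithms in all scores; BIC penalty (log N)/2 per free
  parameter; 0·log 0 = 0; parent-configuration tables are capped at 10⁶
  cells (a move past the cap is treated as illegal).
* Constant gene vectors have undefined correlations; clustering applies a
  zero-correlation convention with a warning.
* Cluster ids are relabeled by decreasing size; k-means uses k-means++
  seeding under the run's child seed.
* Consensus arc directions follow the majority among bootstrap networks
  containing the arc (ties point from the lexicographically smaller
  endpoint); an arc that would close a cycle is dropped, in decreasing
  strength order, with a warning.
* The biological-homogeneity index gives clusters with fewer than two
  annotated genes a contribution of 1 (the defining publication leaves the
  convention open); their count is reported.
* Every stage consumes a child seed derived arithmetically from the master
  seed, so stages can be rerun independently and merge results are
  independent of execution order.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the full workflow on the
desk-scale system above (≈280 genes, ≈460 edges) with B = 100 bootstrap
replicates per network, and the method-comparison checks (planted vs.
hierarchical clustering) at B = 50 over 3 seeds; BN-level properties are
checked against exhaustive enumeration on ≤3-variable datasets and
joint-table inference on ≤6-node networks. These sizes were chosen so a
complete run finishes in minutes on one CPU while still exercising every
stage, including merges.

## Known limitations

* The coexpression channel is the only way expression data influence the
  prior; richer experimental evidence types (e.g. differential-expression
  indicators) are not modeled.
* Hill climbing is a local search; with restarts it matches exhaustive
  enumeration on small systems, but global optimality is not guaranteed at
  cluster scale.
* The merge pass is single-round, as described; iterative remerging is out
  of scope.
* Only hierarchical and k-means clustering are provided (the two
  best-performing portable methods of the eight compared in the source);
  mixture-model and fuzzy alternatives are not reimplemented.
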