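---
title: "Methods: network inference and motif analysis for seed time-course RNA-seq"
author: "seedgrn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network inference and motif analysis for seed time-course RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedgrn)
```

## Scope and workflow

seedgrn implements a desk-scale version of a gene regulatory network (GRN)
analysis workflow for developmental time-course RNA-seq of seeds, with the
endosperm as the tissue of interest. The workflow has five stages:

1. **Gene-set construction.** Three routes: (a) endosperm-enrichment
   classification from a two-condition count contrast, followed by an
   entropy filter; (b) the entropy filter alone over all expressed genes;
   (c) annotation-driven selection of transcription factors.
2. **Network inference**, by two deliberately different engines: a
   per-target random-forest importance ranking with iteration consensus
   and correlation-based sign assignment, and a kernel-PCA boosting
   procedure whose edges are per-target posterior maxima.
3. **Motif enrichment**: counts of the 13 connected directed 3-node
   subgraph classes, compared with degree-preserving randomizations.
4. **Per-gene network motif scores** (NMS): how many enriched-motif
   occurrences contain each gene.
5. **Network comparison**: a gene-pair resampling permutation test of the
   edge overlap between the two engines' networks.

The package starts from expression and count matrices; read processing,
alignment and quantification are out of scope. Because the workflow's
statistical behavior cannot be validated on a single real data set with
unknown truth, the package ships a synthetic-data generator with planted
ground truth, and every downstream claim in the test suite is made against
that truth.

## The synthetic-data generator

`sample_ground_truth_network()` draws a sparse signed regulator-to-target
network: each ordered (regulator, gene) pair receives an edge with
probability `avg_out_degree / (n_genes - 1)`; a configurable fraction of
edges are repressing; strengths are uniform on [0.5, 2]. The benchmark
configuration used throughout the tests — 200 genes, 40 regulators,
average out-degree 2 (about 80 edges), 30% repressors — represents a
filtered gene set of the size the inference stage is meant to consume.

`simulate_time_course()` emulates a six-point developmental series (0, 2,
4, 6, 7, 8 days after pollination, three replicates), the sampling design
the analysis assumes. Its model:

* **Regulators** follow smooth exogenous trajectories: a softened softplus
  (`2 * log(1 + exp(x/2))`) of a random cubic in scaled time. Smoothness
  mirrors developmental trends; the softplus keeps expression
  non-negative without a hard floor.
* **Targets** respond through a signed, strength-weighted sum of their
  regulators' standardized expression, passed through the same softened
  softplus with a per-gene baseline and a coupling gain of 4 (regulation
  is strong relative to intrinsic noise). The *mean trend* of this drive
  acts with a one-time-step delay — a target's time-point mean at step
  k + 1 is a monotone function of its regulators' means at step k — while
  the *realized fluctuation* of a regulator acts within the same sample,
  on the view that transcriptional response is fast compared with a
  sampling grid that is days apart.
* **Noise** is replicate-structured: a persistent per-(gene, replicate)
  offset (seed-to-seed biological variability that follows a replicate
  across the course) plus independent per-value measurement noise, both
  with standard deviation 1 against a typical expression scale of 2-8.
  Values are clamped at zero.

The fluctuation-propagation point deserves emphasis. Six time points span
only a ~4-dimensional space of smooth curves, so with 40 regulators the
mean trajectories alone cannot identify which regulator drives a target —
many candidates fit any smooth profile. What real inference methods
exploit in such data is covariation of realized expression across samples;
the generator reproduces that channel explicitly. Conversely, the
generator does *not* emulate several properties of real RNA-seq: skewed
FPKM magnitude distributions across orders of magnitude,
expression-dependent variance, unmeasured confounders, indirect regulation
through proteins, or feedback onto regulators (regulator trajectories are
exogenous). Passing tests therefore demonstrate that the machinery ranks
planted direct effects correctly under honest noise, not that it would
achieve the same accuracy on biological data.

`simulate_two_condition_counts()` draws negative-binomial counts (variance
mu + phi mu^2) with log-normal baseline means (meanlog 4, sdlog 1, i.e.
median ~55 counts) for an endosperm vs whole-seed contrast with seven
replicates per group; a chosen set of genes has its endosperm mean
multiplied by 2^log2FC and is recorded as ground truth.

## Gene-set filters

**Enrichment classification.** Fold changes are computed from
library-size-normalized group means (CPM with a 0.5 pseudocount) and
tested per gene with a Welch t-test on log2(CPM + 1); p-values are
adjusted by the Benjamini-Hochberg step-up (`bh_adjust()`, a validated
wrapper over `stats::p.adjust`). A gene is endosperm-enriched when
log2FC > 1.5 strictly and adjusted p < 0.01 strictly. The t-test is a
documented lightweight stand-in for a negative-binomial framework: the
interface consumes plain (gene, log2fc, p) tables, so externally computed
differential results can be dropped in unchanged. One consequence of CPM
normalization worth knowing: when a sizeable fraction of the library is
truly enriched, fold changes are attenuated by the library-size ratio
(a planted 4x effect in 10% of a library reads as ~3.1x in CPM), which
caps the sensitivity of a strict 1.5 cutoff near 0.6 in the benchmark
while specificity stays at 1.0. The tests assert exactly those
composition-corrected values.

**Entropy filter.** For a gene's per-time-point means, each value's share
p_t of the profile total contributes entropy e_t = -p_t log2(p_t); the
score s_t = e_t / (log2(e)/e) normalizes by the maximum attainable
per-value entropy (at share 1/e), making the score scale-free in [0, 1].
A value scoring below 0.30 is an outlier — the profile is concentrated
at, or absent from, that time point — and a gene is retained if *any*
time point is an outlier. A perfectly flat six-point profile scores
~0.81 everywhere and is dropped; a single-spike profile scores 0
everywhere and is retained. The cited entropy-filtering literature does
not print a unique formula, and whether the original analysis scored
per-replicate values or per-time-point means is not stated; this package
scores means (the same summary used for sign assignment) and documents
the normalization so the 30% threshold has a fixed meaning. All-zero
profiles are excluded.

**TF selection** is a plain identifier intersection against a caller-
supplied list of GO/InterPro/PFam/PANTHER accessions associated with TF
activity or DNA binding; no annotation database search is performed.

## The tree-ensemble engine

For each target gene a random-forest regression (ranger, 500 trees by
default, single-threaded with a derived seed for determinism) predicts
its expression across samples from all candidate regulators (self
excluded); a regulator's importance is its impurity (variance) reduction,
normalized per target to sum to one. Per iteration, the top 2% of
non-self importances become candidate edges; the cut point is the order
statistic at ceiling((1 - f) n) with ties retained, so an all-equal
matrix keeps everything. Five iterations with different seeds are run by
default and edges kept by majority vote (the per-edge `support` column
records the count); with one iteration the consensus is the identity, the
configuration used for large gene sets where five forests per gene are
not worth the compute. Finally each edge is signed by the Pearson
correlation r of the source and target per-time-point mean profiles:
promoting if r > 0.3, repressing if r < -0.3, otherwise "regulating";
zero-variance profiles give "regulating". The importance threshold, the
consensus rule and the sign dead-zone are all exposed because no
published default exists for them; the defaults here were chosen once as
reasonable middles (2% keeps the expected edge count of the benchmark in
range; 0.3 is a conventional weak-correlation boundary).

## The kernel-boosting engine

For each target, candidates are scored by how well their kernel-PCA
features explain the current residual. A regulator's feature block is the
top eigenvectors (default min(5, n - 1)) of the double-centered RBF Gram
matrix over samples, scaled by root eigenvalue; the bandwidth defaults to
the median pairwise distance of that regulator's values. Each boosting
round fits every candidate by least squares, converts BIC scores to
posterior weights by Bayesian model averaging under a uniform prior (no
prior regulatory knowledge is assumed), then adds half (shrinkage 0.5) of
the best candidate's fit to the running prediction. A round's vote is
weighted by the share of the original variance its best model explains,
so later rounds — which mostly chase residual noise — cannot dilute a
decisive first round. After three rounds (default) the accumulated
weights are normalized to a per-target posterior column summing to one.
Edges are the per-target posterior argmaxes, ties included, unsigned.
The procedure ignores the time-course ordering entirely and has no random
element. Degenerate cases are defined explicitly: a zero-variance target
yields an all-zero column (and then no edge); a single-candidate target
yields posterior one; exact fits are floored at a 1e-10 relative residual
before the BIC log.

Because every target receives (ties aside) exactly one edge, the argmax
network is structurally sparser and less interconnected than the
tree-ensemble network on the same data — fewer high-in-degree genes and
far fewer 3-node motif instances — which the acceptance tests assert as a
qualitative contrast.

## Motif census, null model, and NMS

There are exactly 13 weakly connected directed 3-node graphs up to
isomorphism; the package canonicalizes a triad by minimizing its 6-bit
adjacency code over the 6 node permutations and labels classes by the
Holland-Leinhardt MAN convention (the feed-forward loop is 030T, the
3-cycle 030C). The census enumerates each connected unordered triple
exactly once (triangles are counted at their smallest node), ignoring
edge signs; reciprocal edge pairs are legal and distinguish classes. The
implementation is compiled; the test suite checks it exhaustively against
an all-triples R oracle and against igraph's triad census.

The null model is degree-preserving switching: 10 x |E| attempted
two-edge swaps, rejecting self-loops and duplicates, which preserves both
degree sequences exactly; an Erdos-Renyi same-n-same-m null is available
behind a flag. A class is enriched when its count exceeds the mean of
1000 randomized networks by more than 3 standard deviations (z > 3.0);
classes with zero null variance are reported with z = 0 and never called
enriched. Calibration is tested: feeding the detector a network that is
itself a randomization should produce no enriched class in ~95% of
trials. A gene's NMS is the number of enriched-class occurrences
containing it; genes in no occurrence are simply absent from the table.

## Overlap permutation test

To ask whether two networks inferred on the same gene set share more
edges than chance, each permutation draws |E_A| ordered gene pairs from
the universe — both genes distinct within a pair, no duplicate pairs
within a permutation — and counts how many land in network B. The
reported p-value uses add-one smoothing, p = (1 + #{null >= observed}) /
(1 + N), so it is never zero and its floor at N = 10,000 is just below
1e-4. Direction-respecting matching is the default; an undirected mode
collapses (s,t)/(t,s). Because the overlap count is a small integer, the
add-one p is discrete; the result object therefore also carries
`p_randomized`, the uniform tie-broken version, which is exactly uniform
under the null and is the right quantity for calibration diagnostics
(the suite verifies its uniformity by a Kolmogorov-Smirnov test over 200
independent network pairs, and the permuted-overlap mean against the
analytic expectation |E_A||E_B| / (U(U-1))).

## Numerical and design notes

* All randomness flows through explicit integer seeds; seeded operations
  save and restore the caller's RNG state. Forest seeds are derived per
  target and per iteration so whole networks are reproducible
  byte-for-byte.
* Problem sizes in tests and in the acceptance script (200-gene
  benchmarks, 5 repetitions, 200-1000 randomizations, 500-10,000
  permutations) were chosen to make every Monte-Carlo margin comfortable
  at interactive run times; all were fixed before the corresponding
  expectations were frozen.
* TSV writers emit 9-significant-digit text with '#'-prefixed provenance
  headers (package version, seed, parameters); readers skip comment
  lines and accept CRLF. SIF files carry the sign word as the relation.
* `run_pipeline()` binds the stages behind a single config object and
  writes the full artifact inventory (gene set, enrichment table, both
  edge lists in TSV and SIF, motif and NMS tables, overlap report); the
  exported functions are the interface, and reruns with an identical
  config are byte-identical.

## Known limitations

The differential test is a t-test stand-in, not a count model; with two
or three replicates per group its power is limited. The entropy filter's
formula is one defensible reading of an under-specified method. The
tree-engine importance cutoff and the sign rule are configuration
choices, not published constants. The generator's identifiability
argument (fast fluctuation propagation) is a modeling stance; data whose
replicate noise does not propagate would reduce both engines to
trajectory matching, which six time points cannot support at 40
candidate regulators. Motif analysis is limited to 3-node classes.
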