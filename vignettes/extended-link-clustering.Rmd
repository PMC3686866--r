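---
title: "Extended link clustering: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended link clustering: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elclust)
```

## The problem and the model

Community structure in a network is usually sought as a partition of the
*nodes*, but many systems — protein interaction maps, social networks —
place the same node in several functional groups at once. Link clustering
sidesteps the issue: links, not nodes, are partitioned, and a node inherits
membership in every community that one of its links belongs to. Overlap is
then not an exception to be patched in but the generic outcome.

The pipeline implemented here has four stages:

1. **Similarity.** Every pair of links gets a similarity from the inclusive
   neighborhoods n⁺(i) = {i} ∪ N(i) of their endpoints. Two kernels are
   available: the Jaccard similarity of the non-shared endpoints, defined
   only for links sharing a node (`mode = "LC"`), and the extended link
   similarity (`mode = "ELC"`), the ratio of summed intersection to summed
   union sizes over all four endpoint pairings, defined for every pair.
   ELS couples links up to two steps apart, so its transform matrix is
   denser than the Jaccard one on every network — the property that
   motivates the extended method.
2. **Single-linkage clustering** of the links over the transform matrix,
   recording all |M| − 1 merges.
3. **Cut selection** by maximizing a quality criterion over every merge
   level: extended modularity EQ (default for ELC) or partition density PD
   (default for LC). Either pairing can be requested.
4. **Induction and scoring** of the node communities, reported as EQ, PD,
   IGP, CN, CR and UN.

## Conventions that needed fixing

Several quantities in this area are stated in the literature at a level of
detail that leaves real choices open. The package fixes them as follows,
and the test suite pins each one with an independent oracle.

* **EQ includes the diagonal.** The double sum in EQ runs over ordered node
  pairs including i = j. Two consequences anchor the convention: the
  one-community cover of a connected network scores exactly 0 (the analogy
  with Newman's Q, where a random-chance division scores 0), and on any
  disjoint cover EQ equals Newman modularity exactly — both are asserted in
  the tests against a brute-force triple loop and against an independent
  modularity implementation.
* **D_c = 0 for two-node clusters.** The per-community link density has a
  0/0 denominator at n_c = 2; the degenerate case is defined as 0, so
  all-singleton partitions score PD = 0 and trees score 0 at any grouping.
* **Tie-breaking everywhere is lexicographic.** Node labels are opaque
  strings compared in C-locale byte order; links are ordered
  lexicographically on (min-label, max-label); equally similar cluster
  pairs merge by lowest contained link index (then second-lowest); equally
  good cut levels prefer fewer node communities, then the lower level. Two
  runs on the same input are byte-identical.
* **Zero-similarity merges are performed last.** The dendrogram is
  completed down to a single cluster even across similarity-0 gaps
  (e.g. disconnected components), but such unions can only be selected if
  they genuinely score best — for a connected criterion profile they never
  are.
* **Duplicate induced communities are merged.** Two link clusters with the
  same endpoint set describe one node community; membership counts O_i are
  recomputed after deduplication. Isolated nodes are appended as singleton
  communities, which is why the extended method always reports a 100%
  cover rate.
* **Nearest neighbor for IGP** is the adjacent node of maximal
  inclusive-neighborhood Jaccard similarity, smallest label on ties. On an
  unweighted graph "nearest" is otherwise undefined; this choice reuses
  the only node-level proximity already present in the method and is
  deterministic. The aggregate IGP weights communities by size
  (equivalently: the fraction of node-memberships whose nearest neighbor
  co-occurs); `weighting = "equal"` exposes the unweighted mean as an
  alternative reading.
* **ELS pools the four endpoint pairings in one ratio.** Among the forms
  consistent with the quadrangle family values (0.5, 0.75, 1.0) and the
  zero across components, the sum-of-intersections over sum-of-unions form
  is order-free and needs no pairing choice; it is also evaluated on
  neighbor links, which the definition does not exclude.

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `mode` / `method` | similarity, runner | `"ELC"` | similarity kernel: extended (all pairs) or Jaccard (neighbor links) |
| `cut` | runner | `EQ` for ELC, `PD` for LC | criterion maximized over merge levels |
| `igp_weighting` | IGP | `"membership"` | size-weighted vs plain mean of per-community IGP |
| `n_nodes`, `n_blocks` | generator | 128, 4 | planted design: equal blocks (32 nodes each) |
| `avg_degree` | generator | 4 | k̄; total links L = round(n k̄ / 2) |
| `p_inside` | generator | 0.9 | fraction of links placed within blocks |
| `seed`, `replicates` | generator | 1, 10 | replicate r uses seed `seed + r` |

## What the generator emulates — and what it does not

The generator reproduces a classical planted-partition design: equal-sized
disjoint blocks, a fixed total link budget, an inside quota
L_in = round(p_inside · L) split as evenly as possible across blocks
(remainder to the lowest-index blocks), a uniform random spanning tree per
block (drawn via Prüfer sequences, so all labeled trees are equally
likely) guaranteeing that every block's internal subgraph is connected,
uniform extra within-block links up to quota, and uniform cross-block
links for the remainder. Realized mean degree equals k̄ exactly up to the
single rounding of L, and the realized inside fraction is within one link
of p_inside.

It does **not** produce degree heterogeneity, skewed community sizes, or
planted *overlap* — blocks are disjoint by design, and any overlap in the
detected communities is created by the method, not the ground truth. Tests
passing on these networks therefore certify the mechanics of the method
under clean modular structure, not its behavior on heavy-tailed real
networks.

## Numerical and degenerate-input choices

* The transform matrix is stored sparsely with an explicit absent-equals-0
  contract; the diagonal is set to 1 by convention and never consulted by
  the clustering.
* `single_linkage()` symmetrizes its input ((C + Cᵀ)/2) before clustering
  so that custom kernels with last-bit floating asymmetry cannot derail
  the exact-equality maximum search; the built-in kernels are exactly
  symmetric.
* Self-loops are dropped with a warning (the model is a simple graph, but
  real files contain loops); parallel edges collapse silently.
* Networks without links are rejected by the runner; networks with
  isolated nodes are handled by keeping the isolates out of the link
  machinery and re-attaching them as singleton communities at reporting
  time.
* Cut-level indexing counts merges applied (0 = all singleton links),
  avoiding the ambiguity of height cuts at tied similarities; a dendrogram
  on |M| links has exactly |M| levels, 0 through |M| − 1.

## Problem sizes used in the checks

The analytic suites run on graphs of 4–25 nodes or links, where brute
force is exact: 100 random graphs for the one-community EQ identity, 200
for the Newman-modularity reduction, 100 random 20–25-link matrices for
the single-linkage/threshold-components equivalence. The benchmark
reproduction uses the design's own scale — 10 replicates of the
128-node, 4-block, k̄ = 4, p_inside = 0.9 condition — which keeps a full
run of the suite in the low minutes on one core. Larger condition grids
(k̄ ∈ {4, 8, 12} × p_inside ∈ {0.5, …, 0.9}) are a loop over
`synthetic_config()` away and scale linearly in replicates.

## Known limitations

* Single-linkage chaining is intrinsic: one strong cross-community link
  pair can bridge two otherwise distinct link clusters, and on sparse
  planted networks the EQ-optimal cut often retains many small residual
  communities around a few large ones. The community-count statistic is
  accordingly sensitive to this, much more than EQ itself.
* Only undirected, unweighted simple graphs are supported; weighted
  (Tanimoto-style) kernels and other linkage criteria are out of scope.
* The ELS matrix on dense networks approaches |M|² nonzero entries;
  memory, not time, is the practical ceiling (about 10⁴ links on a desk
  machine).
* Quality metrics beyond the suite above (NMI against ground truth,
  enrichment statistics) are deliberately not included; external covers
  can be scored with `evaluate_cover()` and compared offline.
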