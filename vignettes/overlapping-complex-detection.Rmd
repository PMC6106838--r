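---
title: "Detecting overlapping protein complexes with calmnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting overlapping protein complexes with calmnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calmnet)
```

## The problem

Protein complexes are groups of proteins that interact at the same time and
place. In a reliability-weighted protein–protein interaction network they
appear as subgraphs with more internal than external weight — but three
properties of real complexes defeat naive dense-subgraph mining. First,
complexes *overlap*: a substantial fraction of curated yeast complexes
share proteins, so hard partitions mislabel them. Second, complexes vary in
density; a size-8 complex with density 0.45 is perfectly real. Third,
interactome screens carry false positives and negatives at rates
approaching half the reported interactions, so any objective that takes the
observed weights at face value is brittle.

calmnet addresses the three together with a seed-and-extend design built
around the core-attachment organization of complexes: a dense **core**, a
handful of loosely attached **peripheral** proteins, and **overlapping**
proteins (modules) shared between complexes.

## The model

### Node taxonomy from local topology

For a node $v$ with neighborhood graph $GN_v$ (the subgraph induced by
$V_v = \{v\} \cup N(v)$), calmnet compares $v$ against the averages over
$V_v$ of plain degree, unweighted betweenness $B$, and the local weighted
clustering coefficient

$$LWCC_w(v) = \frac{\sum_{i \in V_v}\sum_{j \in N(i)\cap V_v} w_{ij}}
  {|V_v|\,(|V_v|-1)},$$

the weighted density of $GN_v$. A node is **overlapping** iff
$\deg(v) \ge Avdeg(GN_v)$ *and* $B(v) > AvgB(GN_v)$: proteins shared by
complexes are hubs *and* bottlenecks, because inter-complex shortest paths
funnel through them. A non-overlapping node is a **seed** when
$LWCC_w(v) \ge AvgLWCC_w(v)$ *or* $B(v) \le AvgB(GN_v)$ — locally dense,
or central to a complex interior where paths route around as well as
through. Withholding overlapping nodes from seeding is the crucial step:
grown from a shared protein, two complexes merge into one false
prediction.

Three conventions are worth stating because the quantities are only ever
*compared*, never reported in absolute terms. Betweenness is computed on
the unweighted topology (hop counts), each unordered pair counted once,
disconnected pairs contributing zero; any global scale convention cancels
in the comparison with its own neighborhood average. The neighborhood
average of degree uses plain degrees (the weighted counterpart enters the
pipeline elsewhere, through $LWCC_w$ and seed ordering). And all averaged
quantities ($\deg$, $B$, $LWCC_w$) are measured in the full network, then
averaged over $V_v$ — they are not recomputed inside the induced subgraph.

### Greedy growth

A cluster $C$ starts as one seed. At each step the **border** (non-members
adjacent to a member) is ranked by the support function

$$support(u, C) = \frac{\sum_{v \in C \cap N(u)} w_{uv}}
  {\sum_{v \in N(u)} w_{uv}},$$

the fraction of $u$'s incident weight that lands inside $C$. Support is
deliberately normalized per node: a peripheral protein attached by only
two edges still scores high if those edges are most of what it has,
whereas an overlapping hub scores low because its weight is split across
complexes. The top-support candidate (ties: higher weighted degree, then
lexicographic identifier, for determinism) is accepted iff the
local-modularity fitness does not decrease:

$$F(C) = \frac{weight_{in}(C)}
  {\left(weight_{in}(C) + weight_{out}(C) + \delta\,|C|\right)^{\alpha}}.$$

After every acceptance the border and all supports are recomputed against
the updated cluster; growth stops at the first rejection of the
top-ranked candidate (or when the border empties). Recomputing after each
acceptance, rather than freezing a ranking per sweep, is what makes the
trace on the shipped worked example behave as intended: when the cluster
reaches the core $\{0,1,2,3,4\}$, node 5 — not any of the stale earlier
candidates — is the top-ranked border node, and it is rejected on the
fitness test. With full recomputation a re-scan of an unchanged cluster
would re-reject the same candidate, so a single greedy loop already
reaches the fixed point.

Acceptance is non-strict ($F' \ge F$), so zero-gain additions extend the
cluster; the border is finite and never revisited within a step, so
growth terminates after at most $|V|$ acceptances. An optional
`fallback_next_best` mode keeps trying lower-ranked border nodes after a
rejection before giving up; it is off by default (the strict greedy
reading) and exists for exploration only.

### Parameters

* $\delta$ (`delta`, default `"auto"` = $|E|/|V|$, i.e. half the average
  node degree, unweighted): a per-node uncertainty correction representing
  interactions each cluster member may gain or lose to noise. It is
  computed once per network — not per cluster — so that fitness values are
  comparable across seeds. Unitless, like the weights.
* $\alpha$ (default 1): with $\alpha = 1$, $F$ is the ratio of internal to
  boundary-corrected total weight — the weak community definition. Larger
  values sharpen the penalty on large clusters; exposed but not varied.
* $\omega$ (`omega`, default 1): merge threshold on the overlap score
  $OS(A,B) = |A\cap B|^2/(|A||B|)$. At 1, merging is exact deduplication
  (OS = 1 iff equal sets); smaller values union near-duplicates in a
  single forward pass over the candidates in seed-queue order. The
  single-pass convention is only guaranteed idempotent at $\omega = 1$.
* `min_size` (default 3): a pair of proteins reaches OS = 0.25 against far
  too many references by chance; size-1/2 clusters are dropped.
* `match_threshold` (default 0.25): the evaluation-side OS threshold,
  meaning roughly "half the proteins shared on both sides". Fraction uses
  $OS \ge 0.25$ (as defined), MMR admits matching edges at $OS > 0.25$
  (as described for the matching graph); both are configurable.

### Evaluation

Given references $R$ and predictions $P$ with intersection counts
$t_{ij}$: $Sn = \sum_i \max_j t_{ij} / \sum_i |N_i|$,
$PPV = \sum_j \max_i t_{ij} / \sum_j\sum_i t_{ij}$,
$ACC = \sqrt{Sn \cdot PPV}$, $Fraction$ = share of references matched by
some prediction at $OS \ge 0.25$, and $MMR$ = total OS weight of a
maximum-weight one-to-one matching divided by $|R|$. PPV's denominator
counts a protein once per prediction containing it, a known bias against
overlapping prediction sets — which is exactly why Fraction and MMR sit
beside ACC in the composite score $ACC + Fraction + MMR$. Reference
catalogs are filtered to complexes of at least 3 members at load time;
proteins absent from the network are retained (the metrics are
catalog-level).

## What the synthetic benchmark emulates — and what it does not

`simulate_planted_network()` plants the structure the detector assumes:
per complex, a core clique with weights U(0.7, 1.0) of size 4–6 and 2–4
peripheral proteins each attached to 2–3 core nodes with weights
U(0.3, 0.6); three two-protein overlap modules, each shared by exactly two
complexes and attached to both cores; background noise edges at
probability 0.01 per unplanted pair with weights U(0.1, 0.3); and a 10%
false-negative deletion of planted edges (skipping deletions that would
isolate a protein, so the ground truth stays inside the network). Weights
are rounded to 3 decimals so edge lists round-trip through text exactly.
These defaults are the package's fixed picture of a moderately noisy
reliability-weighted interactome at bench scale (~80–90 proteins).

Passing recovery tests on this generator shows the pipeline finds planted
core-attachment structure under moderate, *independent* noise. It does not
show performance on real interactomes: the generator reproduces neither
the degree distribution nor the correlated error structure of
affinity-purification screens, its cores are cliques (real cores need not
be), and its overlap modules join exactly two complexes. Scores on real
data should be expected to be substantially lower.

## Numerical and design choices

* **Duplicate input edges keep the maximum weight** (reliability
  semantics); conflicting records of the same interaction are taken as
  evidence at least as strong as the best one. Two-column files load with
  `default_weight = 1` so unweighted networks run unchanged.
* **Weights of exactly 0 are rejected** rather than stored — a 0-weight
  edge is indistinguishable from absence in every formula.
* **Seed-queue order** is descending weighted degree with lexicographic
  tie-break. Degree-based ordering applied *after* the overlapping-node
  filter keeps the determinism of degree seeding without its failure mode.
* **Ties in growth** break by weighted degree then identifier;
  **candidate order** for merging is seed-queue order; **final output**
  is sorted by size (descending) then first member — every stage is
  deterministic, and end-to-end runs are byte-identical.
* **Degenerate inputs:** an empty border ends growth; a fitness
  denominator of zero defines $F = 0$; an empty seed queue yields an
  empty prediction set with a warning rather than an error.
* The worked-example network is one concrete reconstruction consistent
  with every constraint its description pins down (node 1's incident
  weights and weighted degree 3.32; node 5 with 9 neighbors, 6 internal;
  node 8 with 13 neighbors, 6 internal; the growth trace accepting
  1, 2, 3, 4 and rejecting 5). The unconstrained parts of the topology
  (the exact wiring of nodes 6, 7, 9 and the twelve outside nodes) are
  frozen in `fig2_network()` and shipped as
  `extdata/fig2_network.tsv`.

## Problem sizes in the test suite

The suite checks betweenness against an explicit all-shortest-paths
enumerator on 100 random graphs of up to 12 nodes, MMR against exhaustive
matching on 100 instances up to 6×6, and planted-complex recovery on 20
benchmark seeds at the default generator settings (10 complexes,
~85 proteins); these sizes keep the brute-force oracles exact and the
full suite comfortably fast on one CPU. Exact betweenness on networks of a
few thousand nodes is tractable (igraph's Brandes implementation), but the
pure-R per-node profiling loop makes interactome-scale runs a matter of
minutes, not seconds.

## Known limitations

* No node *removal* during growth: a mistakenly accepted zero-gain node is
  never evicted. The non-strict acceptance rule makes such plateau
  extensions possible in principle.
* $\omega < 1$ merging is order-dependent and single-pass; it is an
  exploratory mode, not the default pipeline.
* The method needs *some* weighting; on unweighted networks (all weights
  1) support degenerates to a fraction of neighbor counts and the
  noise-correction rationale for $\delta$ weakens.
* No statistical significance machinery for metric differences, and no
  GO/annotation-based validation — the evaluation is purely set-based.
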