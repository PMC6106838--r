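# calmnet

Detection of overlapping, variable-density protein complexes in weighted
protein–protein interaction (PPI) networks, with the CALM seed-and-extend
strategy, plus the standard evaluation suite for complex prediction and a
planted core-attachment benchmark generator.

## Who this is for

Computational biologists who have a reliability-weighted interactome (an
edge list `protein_a protein_b weight`, weights in (0, 1]) and want to
predict protein complexes — including complexes that *share* proteins and
complexes that are not dense cliques — and to score predictions against a
reference catalog such as CYC2008 or MIPS-derived sets.

## The method

A PPI network is an undirected weighted graph *G = (V, E, W)*. CALM exploits
the core-attachment organization of complexes: a dense core, loosely
attached peripheral proteins, and *overlapping* proteins shared between
complexes.

1. **Overlapping-node identification.** A node is flagged as overlapping
   (hub-bottleneck) iff `deg(v) ≥ Avdeg(GN_v)` **and** `B(v) > AvgB(GN_v)`,
   where `GN_v` is the subgraph induced by `v` and its neighbors, `B` is
   unweighted betweenness, and the averages run over `V_v = {v} ∪ N(v)`.
   Overlapping nodes are never used as seeds — growing from a shared node
   fuses two complexes into one false prediction.
2. **Seed selection.** A non-overlapping node becomes a seed if
   `LWCC_w(v) ≥ AvgLWCC_w(v)` (locally dense) **or** `B(v) ≤ AvgB(GN_v)`
   (hub-nonbottleneck). `LWCC_w` is the weighted density of `GN_v`. The
   queue is ordered by descending weighted degree.
3. **Greedy growth.** From each seed, the border node with maximum
   *support* — `support(u, C) = Σ_{v∈C∩N(u)} w(u,v) / Σ_{v∈N(u)} w(u,v)` —
   is accepted iff the local-modularity fitness does not decrease:

   `F(C) = weight_in / (weight_in + weight_out + δ·|C|)^α`

   with `α = 1` and `δ` = half the network's average degree, a per-node
   correction for the ~50% noise typical of interactome screens.
4. **Merge/filter.** Candidates with overlap score
   `OS(A,B) = |A∩B|² / (|A|·|B|) ≥ ω` are merged (default `ω = 1`:
   deduplication) and complexes with fewer than 3 members are dropped.

Evaluation: clustering-wise sensitivity `Sn`, positive predictive value
`PPV`, geometric accuracy `ACC = √(Sn·PPV)`, the `Fraction` of references
matched at `OS ≥ 0.25`, the maximum matching ratio `MMR` (maximum-weight
one-to-one matching of predictions to references), and the composite score
`ACC + Fraction + MMR`.

## Worked example

The package ships a fixed 22-node, 51-edge network (`fig2_network()`) whose
nodes 0–9 form a complex with core {0,1,2,3,4}, peripherals {5,6,7} and
overlapping nodes {8,9}:

```r
library(calmnet)
net <- fig2_network()
grow_cluster(net, "0")$trace
#>   step node   support fitness_before fitness_after accepted
#> 1    1    1 0.2951807     0.00000000    0.08776358     TRUE
#> 2    2    2 0.4642857     0.08776358    0.17966517     TRUE
#> 3    3    3 0.6753247     0.17966517    0.28194418     TRUE
#> 4    4    4 0.8051948     0.28194418    0.35703106     TRUE
#> 5    5    5 0.4444444     0.35703106    0.34187912    FALSE
```

Node 1 has the highest support for the seed cluster {0}
(0.98/3.32 = 0.295); nodes 2, 3, 4 follow as the fitness climbs from 0 to
0.357; node 5 is rejected because adding it would drop the fitness to
0.342 — the grown cluster is exactly the complex core {0,1,2,3,4}.

On a simulated benchmark with 10 planted core-attachment complexes,
moderate background noise and 10% false-negative edge deletion:

```r
bench <- simulate_planted_network(seed = 42)
pred <- detect_complexes(bench$network)
evaluate_complexes(bench$truth, pred)
#> Sn 0.8876  PPV 0.9323  ACC 0.9097  Fraction 1.0000  MMR 0.9005  composite 2.8101
```

Every planted complex is matched at OS ≥ 0.25 (`Fraction = 1`), and the
one-to-one matching recovers 90% of the maximum possible OS weight per
reference (`MMR = 0.90`).

A command-line front end is installed at
`system.file("scripts", "calm.R", package = "calmnet")` with `detect`,
`eval` and `simulate` subcommands.

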