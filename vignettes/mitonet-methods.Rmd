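---
title: "Methods: network topology and evolutionary conservation of mitotic phenotype genes"
author: "mitonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network topology and evolutionary conservation of mitotic phenotype genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitonet)
```

## The scientific setting

Genome-wide RNAi screening in HeLa cells identified a set of *mitotic hit*
(MH) genes: genes whose silencing produces phenotypic aberrations of
mitosis, recorded per gene as a *phenoprint* — the time course of the cell
population's distribution over seven phenotype classes (mitotic delay,
binuclear, polylobed, grape, large, dynamic, cell death). `mitonet`
implements the network-level characterization of these genes on a signed
molecular interaction network (MIN) assembled from curated mitosis-related
pathways: how network proximity relates to phenotypic similarity, whether
MH genes and their interactions are preferentially conserved across a
metazoan species panel, whether conserved MH interactions are load-bearing
for network integrity, and whether MH genes concentrate in conserved
bistable regulatory motifs.

Every analysis consumes plain tabular inputs (an edge list, an MH
annotation, an orthology presence table, per-species interaction catalogs,
a phenoprint CSV), so the pipeline is agnostic about where the data came
from; the package's synthetic generators produce inputs with the same
statistical structure for testing and demonstration.

## Networks and distances

An `interaction_network` stores a typed edge list over opaque gene ids.
Types map to regulatory signs through a closed vocabulary — activation,
expression and positive indirect effect are +1; inhibition, repression and
negative indirect effect are −1; binding and unrecognized types are
unsigned. The *regulatory* subnetwork keeps only signed edges, all treated
as directed.

Network distance is the unit-weight shortest path on the **undirected
projection**. The source material reports a single "shortest path" over a
network that mixes undirected physical interactions with directed
regulatory relations, so the undirected projection is the only reading
that treats both uniformly; a direction-respecting variant is available
via `shortest_path_distances(..., directed = TRUE)` for sensitivity
analysis. Unreachable pairs are `Inf` and are excluded from threshold
analyses (the observed distance range is finite by construction).

Self-loops are stored but excluded from motif enumeration and from
clustering coefficients, the standard census convention. Opposite-sign
edges between the same ordered pair are kept as distinct colored edges for
conservation counting, but a motif containing such a pair is excluded from
bistability classification: no sign-priority rule is defensible, so its
dynamics are treated as undefined.

## Phenoprint distances and the sliding-threshold test

Trajectories are compared with the symmetric Hausdorff distance between
their point sets in 7-space under the Euclidean base metric. Time stamps
do not enter the metric: the underlying multidimensional-series approach
operates on point sets, and no time-warping rule is given in the source
material, so ordering information is deliberately ignored. The base
distance computation is delegated to `pracma::hausdorff_dist()`; tests
verify it against an exhaustive min/max oracle over all point pairs.

For each observed finite network distance *d*, MH gene pairs split into
group I (network distance ≤ *d*) and group II (the remainder), and
`wilcoxon_one_sided_less()` tests whether group I phenotypic distances are
stochastically smaller. The Wilcoxon implementation is `stats::wilcox.test`,
which uses the exact permutation distribution for small untied samples and
the normal approximation with tie and continuity correction otherwise —
the package's tests verify the exact branch against full rank-assignment
enumeration up to samples of 8 + 8. At the maximal threshold group II is
empty; the record is emitted with `p_value = NA` and a `group2_empty` flag
rather than an error, so downstream tabulation stays rectangular.

The mirrored trees min–max scale both distance matrices to [0, 1] and
cluster each with Ward linkage. We use `hclust(method = "ward.D2")` (the
Ward criterion applied to the scaled dissimilarities; the squared-update
Lance–Williams variant); the method string is a parameter, since the
source names "Ward hierarchical clustering" without specifying the
variant. The per-leaf *correspondence depth* counts, starting from the
root (k = 1 clusters) and descending one level at a time, how many
successive levels place the leaf in clusters with identical gene content
on both trees, stopping at the first mismatch; identical inputs therefore
give every leaf the maximal depth n. Genes at non-finite network distance
from any other leaf cannot be placed on the network tree and are dropped
with a warning.

## Conservation and enrichment

A gene is conserved when present in at least ⌈f·S⌉ of the S panel species;
an interaction is conserved when its unordered endpoint pair is retained
in at least ⌈f·S⌉ per-species catalogs. The ceiling rule makes the default
f = 0.7 give 7 of 9 species (6 at f = 0.6, 8 at f = 0.8, and 5 of the 7
species available in the secondary interaction resource). Edge
conservation is pair-level, undirected and type-agnostic, because
orthologous interactions in pathway databases are inferred from the
conservation of the interacting genes, not of the interaction annotation.

Enrichment of MH entities among conserved ones is the one-sided
("greater") Fisher exact test on the 2×2 table; the sidedness is fixed by
the published values themselves — near-1 p-values (0.989, 0.536) for
under-represented rows only arise under a one-sided enrichment test. The
test is `stats::fisher.test`, verified in the test suite against
enumeration over all tables with fixed margins. Degenerate tables (an
all-zero margin) report p = 1 with a flag instead of erroring. For
per-category tests (`set_enrichment()`), Benjamini–Hochberg q-values are
reported alongside the raw p-values, which remain primary since single
Fisher p-values are what the reference analysis reports.

## Fragmentation

`fragmentation_analysis()` removes the complete set of conserved MH genes
(or distinct MH interactions) from a conserved network, records the giant
component size, and compares it to 5000 equal-count uniform random
removals drawn from **all** entities of the network — MH included, since
the reference procedure draws "randomly chosen conserved genes or
interactions" without exclusion. Removing an interaction removes all
parallel typed edges between the endpoint pair. The test is one-sided for
a *decrease*, p = Φ((obs − mean)/sd); this direction reproduces the
published 0.35 and 0.71 from the printed observed/mean/sd triples. A
zero-sd null (e.g. k = 0, or a vertex-transitive graph) is flagged and
resolved by direct comparison. Each stage of the pipeline derives its own
seed from the master seed, so stages are independently reproducible.

## Motif census, null model and bistability

The census is an ESU enumeration (implemented in C++ for the inner loop):
every weakly connected induced subgraph of size 3 or 4 is visited exactly
once and assigned a canonical label — the lexicographically minimal
row-major encoding of its signed adjacency over all k! relabelings, with
pair codes 0/+/−/both. Exhaustive tests confirm the label partition equals
brute-force isomorphism classes for all size-2 signed digraphs and that
census counts equal subset enumeration on networks of up to 15 nodes.

The null model randomizes edges **within each sign class** by repeated
two-edge swaps (3 swap trials per edge, up to 3 attempts each, the
defaults of standard motif-detection software), which preserves every
node's in- and out-degree per sign exactly and never introduces
self-loops or duplicate same-sign edges. Significance uses 1000
randomized networks, z ≥ 2 and empirical p ≤ 0.05 (the ≥-tail, i.e.
over-representation); classes with more nodes than directed interactions
are discarded as simplistic. A zero null sd leaves z undefined and the
class non-significant, flagged rather than inflated.

**Boolean bistability.** The bistability criterion referenced by the
source material is cited there only by pointer, so the update rule is this
package's own documented choice, isolated behind
`boolean_fixed_points()` so alternatives can be swapped in. We use the
synchronous logic rule: a node is ON in the next step iff (it has no
activators or at least one activator is ON) and no inhibitor is ON;
input-free nodes are clamped OFF. Two properties motivated this rule over
a threshold-sum rule with retain-on-zero:

1. It reproduces the textbook fixed points — toggle switch {10, 01},
   mutual activation {00, 11}, a lone edge A→B only {00}, and no
   bistability for a negative 3-cycle.
2. It is a pure Boolean function of the state whose interaction graph
   matches the motif's signs, so the Thomas positive-circuit condition
   applies: multistationarity requires a positive circuit. A
   retain-on-zero rule implicitly adds a positive self-loop to every node
   and manufactures spurious bistability in feed-forward chains; under the
   logic rule the package's exhaustive test over all connected signed
   digraphs of size ≤ 3 (and samples at size 4) confirms every bistable
   class contains a positive feedback circuit, mirroring the empirical
   finding that conserved bistable MH motifs are exclusively
   positive-feedback motifs.

A motif instance is *conserved* when the intersection of its edges'
species presence sets has at least 7 species — a common set, which is
strictly stronger than each edge being 7-species conserved separately.
Significance is computed on the full regulatory network and conservation
filtering applied afterwards (both orders are possible by passing a
conserved subnetwork to the census). MH enrichment within conserved
bistable motifs is the same one-sided Fisher machinery over the genes of
the conserved regulatory network, and the motif-cluster test compares
local clustering coefficients of motif genes versus all other genes with
a one-sided Wilcoxon rank-sum test.

## The synthetic study conditions

`synthetic_spec()` fixes the generator conditions; the defaults are the
package's standing study conditions and all analyses, tests and the
acceptance script run against them unchanged:

- **Network**: 500 genes, 30 MH genes (6 %, matching the proportion of MH
  genes in the reference conserved network), ~1500 edges
  (`edge_density = 0.006`), 70 % of signed edges positive, 30 % of edges
  unsigned binding edges. Genes are assigned round-robin to 25
  communities; intra-community edges are Bernoulli at a density that
  meets the overall target, and the communities are tied together by a
  random spanning tree plus an equal number of extra bridges. Each bridge
  is anchored at an MH gene with probability 0.9 (partner uniform among
  non-MH genes), so inter-community connectivity runs through MH
  interactions — the load-bearing role the fragmentation analysis is
  designed to detect. Setting `n_communities = 1` gives a homogeneous
  G(n, p) graph for calibration tests.
- **Orthology**: per-species presence 0.9 (MH) vs 0.6 (other) — effect
  sizes large enough to be detectable at this scaled-down n, unlike the
  small-effect/large-n regime of the genome-wide data.
- **Interaction retention**: 0.8 (MH interactions) vs 0.7 (other) per
  species, independent across species. Real orthology calls are
  phylogenetically correlated; since all downstream analyses consume only
  per-species presence counts and sets, this independence does not affect
  correctness tests, but it is a realism limitation.
- **Phenoprints**: MH genes are partitioned greedily into network balls of
  radius d0 = 2; each community's archetype is a linear trajectory between
  two random points of the 7-class simplex over 8 time points; each gene
  adds Gaussian noise (sd 0.03, small relative to typical inter-archetype
  separation) and clips at zero.
- **Planted motifs**: 15 node-disjoint toggle-switch triads (A ⊣ B, B ⊣ A,
  A → C: bistable, positive 2-circuit) planted preferentially on MH genes,
  with their edges forced present in a common 7-species set so they are
  motif-conserved by construction.

With these conditions the pipeline recovers every planted structure:
proximity–phenotype coupling at p < 0.001 for all thresholds up to d0,
gene- and interaction-conservation enrichment, a strongly significant GCS
decrease under MH-interaction removal, and the planted motif class as
significant, conserved, bistable and MH-enriched. Problem sizes were
chosen so a full default run (5000 fragmentation resamples, 1000 motif
randomizations, sizes 3 and 4) completes in about a minute on a single
CPU.

**What the generator does not emulate.** Degree heterogeneity: curated
pathway networks are hub-heavy, and that structure is what makes random
*gene* removal as damaging as targeted MH-gene removal in the real data
(the published gene-removal tests are non-significant at p = 0.35/0.71).
In the synthetic communities-and-bridges topology, MH genes are
themselves structurally distinguished, so targeted MH *gene* removal is
also significant; the package therefore treats only the
interaction-removal arm as the planted fragmentation effect. Passing
tests on synthetic data demonstrate the machinery is correct and the
planted effects recoverable — not that real mitosis networks have these
effect sizes.

## Numerical choices and degenerate inputs

- Fisher tests run through the hypergeometric machinery of
  `fisher.test`, exact at all table sizes used here; p-values are
  reported unrounded.
- Empirical motif p-values use the plain fraction of null counts ≥
  observed (resolution 1/n_random); z-scores use the (n−1)-denominator
  null sd.
- Min–max scaling of a constant distance matrix maps everything to 0
  rather than dividing by zero; mirrored trees then degenerate gracefully.
- `read_network()` reports malformed rows by line number; edges referring
  to unannotated genes auto-create non-MH nodes with a warning, so a
  partial annotation is usable but never silent.
- All randomized stages (null draws, edge swaps, generators) are
  deterministic under their seed; the pipeline derives per-stage seeds
  from one master seed.

## Known limitations

- Boolean dynamics are synchronous-logic fixed points only; asynchronous
  attractors and ODE-level bistability are out of scope, and the rule is
  a documented stand-in for the criterion cited by pointer in the source
  material.
- Conservation treats species independently (no phylogenetic weighting).
- The correspondence-depth statistic is a transparent set-comparison
  heuristic for tanglegram line thickness, not an optimal leaf-matching
  algorithm.
- Gene identifiers are opaque strings; no identifier conversion is
  performed.
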