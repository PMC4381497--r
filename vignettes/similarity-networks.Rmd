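---
title: "Thresholded sequence similarity networks: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thresholded sequence similarity networks: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqsimnet)
```

## The model

`seqsimnet` treats an amplicon survey as a weighted undirected graph. Nodes
are dereplicated sequences carrying categorical labels — molecule (DNA or
cDNA), epoch (cultured isolate, earlier environmental project, new survey),
sampling site and habitat (subsurface, deep chlorophyll maximum, sediment).
An edge joins two nodes when their local-alignment percent identity reaches a
threshold τ, and carries that identity as its weight. Varying τ from 85% to
99% sweeps the clustering from family-like groupings to conspecific ones:
connected components (CCs) at high τ play the role of species-level OTUs,
while at low τ they grow into giant components whose internal structure is
resolved by level-1 Louvain communities (LCs).

Three analysis layers sit on the partitions:

* **Novelty.** An LC at the most inclusive threshold is *novel* when every
  member is a new-survey sequence and the mean, over members, of each
  member's best identity to any cultured reference falls below 95%. Members
  with no qualifying hit against the reference pool contribute identity 0.
  Complementary node-level measures are the unweighted shortest-path
  distance to the nearest cultured node (infinite when unreachable) and
  per-component closeness, `(n_c − 1) / Σ d(v, ·)`. Closeness distributions
  of cultured versus environmental nodes are compared with a one-sided
  two-sample Kolmogorov–Smirnov test ("cultured stochastically greater"),
  reported at α = 0.05 and 0.01.
* **Biogeography.** For every cluster and every site/habitat value, Newman's
  two-category assortativity r is computed on the cluster's induced
  subgraph from the unweighted edge endpoint mixing matrix. Significance
  comes from a topology-preserving null: the node-label multiset is
  permuted over the cluster's nodes (category counts preserved, edges
  untouched), r is recomputed per permutation, and the observed distribution
  across clusters is compared to the pooled null with a one-sided KS test.
  Per-cluster profiles report abundance (node count), occurrence (distinct
  sites among environmental members) and Simpson evenness
  `SI = 1 − Σ p_i²` of the per-site counts, which ranges from 0 (single
  site) to `1 − 1/N`.

## Assumptions

* Identity is computed in the BLAST `pident` convention: matches divided by
  alignment columns, gap columns included. The denominator choice matters
  at the thresholds; it matches the tabular format the package reads and
  writes.
* Assortativity is unweighted: Newman's categorical coefficient is defined
  on edge counts, and weighting by identity has no support in that
  definition. A cluster in which only one category appears among the edge
  endpoints has an undefined r (denominator 0); such cluster–label pairs are
  excluded from observed *and* null distributions symmetrically.
* Closeness is per component. The surveyed networks are deliberately
  disconnected, so cross-component distances are undefined; harmonic or
  global closeness variants were rejected to keep the centre/periphery
  reading within a cluster.
* The novelty rule averages *best-per-member* identity (the "closest
  cultured reference" reading). The alternative — mean over all
  member-by-reference hits — is available via `mean_over = "all_pairs"`.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| hit E-value | < 1e-5 | — | strict inequality; classical BLAST cut-off |
| hit identity | ≥ 60 | % | inclusive ("minimum") |
| hit coverage | ≥ 40% of shorter sequence | — | inclusive; evaluated with 1e-9 slack because 0.40 × 300 is not exactly representable in floating point |
| record length | ≥ 300 | bp | amplicon quality filter |
| thresholds τ | 85, 90, 95, 96, 97, 98, 99 | % identity | the analysis sweep |
| novelty threshold | 85 | % identity | most inclusive graph, where detached lineages are visible |
| novelty cutoff | 95 | % mean identity | the reference-free rule |
| permutations | 100 per cluster–label | — | seeded; raise for publication-grade p-values |
| α | 0.05 and 0.01 | — | both reported |
| Louvain restarts | 4 | — | see "Numerical choices" |

Alignment scoring is match +1, mismatch −2, gap open −5, gap extend −2
(BLASTN-like). E-values use the Karlin–Altschul formula
`E = K·m·n·exp(−λS)`; λ solves the score-generating equation under uniform
base composition (for +1/−2, `exp(λ) = (3 + √21)/2`), and K defaults to
0.46, the standard ungapped value for this score pair. Both are
configurable through `align_params()`.

## What the synthetic generator emulates — and what it does not

`scenario_config()` plants `n_species` species as radiations from a small
number of family ancestors. Members of a species are i.i.d. per-site
substitution mutants of its centroid (`within_species_divergence`, default
0.005/site, giving ~99% expected within-species identity — the exact
expectation is `(1−p)² + p²/3` per site). Anchored species radiate at
`radiation_divergence` (0.085/site, so sibling species sit at ~84–86%
identity: their cross edges straddle the 85% threshold, merging families
into multi-species components there while separating species cleanly at
90%+). Planted-novel species radiate further (`novel_divergence`,
0.13/site, ~76% identity to siblings): they stay detached at every
threshold, like genuinely divergent lineages, yet remain alignable to the
cultured pool so the 95% rule can measure them. Rejection sampling enforces
the minimum between-species divergence and verifies each novel centroid is
below 95% identity to every cultured centroid. Cultured references are
emitted as unmutated centroids — they anchor their species clusters the way
reference sequences from isolates anchor real networks — and each anchored
species also contributes prior-environmental sequences without site labels.

Dispersal modes set the ground truth the biogeography layer must recover:

* *endemic* — each species' members carry one site;
* *cosmopolitan* — each species occurs at **every** site. Member sites are a
  random surjection (a random permutation of all sites plus uniform extras,
  shuffled), so each member's marginal site distribution is uniform while
  presence-everywhere is guaranteed. A fully i.i.d. assignment was rejected:
  with 20 draws over 8 sites, full coverage would hold for only ~53% of
  species, making "cosmopolitan" a coin flip rather than a planted property;
* *habitat_structured* — a configured fraction of species (default 0.5) is
  confined to one habitat (default sediment), the rest mix uniformly.

Every species is either anchored by a cultured reference or planted-novel
(`frac_cultured + frac_novel = 1`); an unanchored non-novel species would be
indistinguishable from a planted novel one, leaving novelty precision and
recall ill-defined.

The generator's substitution-only mutation model keeps percent identity in
closed form (an indel rate exists but defaults to 0). It does **not**
emulate rDNA secondary structure, chimeras, sequencing-platform error
profiles or abundance-skewed read counts. Consequently, passing the
parameter-recovery tests shows the statistics recover planted structure
under idealised noise; it does not certify behaviour on raw reads, which
should be quality-filtered and chimera-checked upstream as usual.

## Numerical choices

* **Conspecific threshold.** Cluster profiles default to τ = 97. With
  within-species divergence 0.005/site, mean within-species pairwise
  identity is ~99.0% — right at the 99 threshold — so at τ = 99 roughly a
  tenth of members lose all their edges and drop out as singletons, eroding
  occurrence. The generator's planted-species partition is exactly the
  ≥ 97% components, making 97 its conspecific scale; τ = 99 remains
  available.
* **Louvain level 1.** The community stage runs local moves only (including
  the split-into-fresh-singleton move), iterated until no single-node move
  increases modularity, with no aggregation — the most fine-grained Louvain
  resolution. The phase is order-dependent and can stall in single-move
  local optima (reference implementations show the same behaviour), so the
  visiting order is seeded and the phase is restarted (default 4, seeds
  derived from the user seed) keeping the best-modularity partition; the
  whole procedure is deterministic for a given seed. Ties between equally
  good target communities break to the smallest community index.
* **Deterministic naming and tie-breaks.** Clusters are named after their
  lexicographically smallest member (`CC_<id>`, `LC_<id>`); the giant
  component tie-breaks lexicographically; per-pair hit reduction keeps the
  greatest identity, then greatest alignment length, then lowest E-value.
* **Candidate pairs.** The all-vs-all stage aligns only pairs sharing at
  least one exact 12-nucleotide word (found via a sparse sequence-by-word
  incidence matrix). Unrelated sequences (~25% identity) essentially never
  share a 12-mer, which also realises the "no hit → identity 0" branch of
  the novelty rule. This is seed-based candidate selection, not a BLAST
  reimplementation: all scoring is full Smith–Waterman (compiled, affine
  gaps), cross-checked against `Biostrings::pairwiseAlignment` in the test
  suite.
* **Degenerate inputs.** Edgeless networks have undefined modularity
  (error); single-category subgraphs have undefined r (excluded, recorded
  with a reason); empty cultured pools are a configuration error for the
  novelty rule; clusters with no sited member get occurrence 0 and `NA`
  evenness.
* **Exclusivity denominator.** The fraction of clusters exclusive to a
  habitat uses the *total* cluster count as denominator (not only clusters
  containing that habitat); both readings are defensible and the choice is
  stated here so results are comparable.

## Problem sizes used by the test suite

The parameter-recovery tests run the default scenario — 40 species × 20
sequences plus references (~860 records, ~46k candidate pairs) — once per
dispersal mode, which keeps the whole suite within a few minutes on one
core while leaving every statistic with comfortable margins (novelty
precision and recall are exactly 1.0, endemic site-assortativity p ≈ 3e-4,
cosmopolitan p ≈ 0.9). The exhaustive-search oracles (all partitions of
n ≤ 8 nodes; brute-force mixing matrices; union-find) cover the
combinatorial primitives at sizes where enumeration is exact.

## Known limitations

* Level-1 Louvain inherits the resolution limit: when cross-cluster edge
  weight is dense, merged communities can be the true modularity optimum, so
  "LC = species" should not be assumed on permissive thresholds; the
  conspecific claims in this package rest on components at stringent
  thresholds.
* The Karlin–Altschul K is a tabulated constant, not estimated from the
  score distribution; E-values are therefore calibrated only to the default
  scoring. Changing the scoring changes λ automatically but K only via
  `align_params(K = ...)`.
* Dereplication keys on exact (case-folded) sequence strings, with
  reverse-complement collapsing behind a flag; amplicons are assumed
  same-stranded.
* The multiplicity recovered by dereplication is carried through but not
  used as abundance: cluster abundance counts dereplicated nodes.
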