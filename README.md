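# seqsimnet

Sequence similarity networks for microbial diversity and biogeography.

## The problem

Environmental surveys of microbial eukaryotes (for example ciliates sampled
with the V4 region of the SSU-rDNA gene) produce tens of thousands of
amplicon sequences from many sites and habitats. Two recurring questions
are:

1. **How much of this diversity is new?** How far do environmental
   sequences sit from everything already known from cultured, morphologically
   identified organisms?
2. **Is the diversity endemic or cosmopolitan?** Are groups of near-identical
   sequences confined to single sites and habitats, or found everywhere?

`seqsimnet` answers both with *sequence similarity networks*: every
(dereplicated) sequence is a node, and two nodes are joined by an edge when
their pairwise identity is at least a chosen threshold τ (85–99%). The graph
at each τ partitions into **connected components (CCs)** — clusters of
mutually similar sequences — which can be refined into **level-1 Louvain
communities (LCs)**, the most fine-grained modularity communities, by
maximising

    Q = Σ_c [ W_c / W − (S_c / 2W)² ]

where `W` is the total edge weight (%identity), `W_c` the intra-community
weight and `S_c` the community's total strength. On top of the partitions the
package computes:

* **Novelty** — LCs consisting exclusively of new-survey sequences whose
  members are on average less than 95% identical to any cultured reference;
  per-node shortest-path distance to the nearest cultured node; per-component
  closeness centrality `(n−1) / Σ d(v,·)`, with one-sided Kolmogorov–Smirnov
  contrasts between cultured and environmental closeness.
* **Biogeography** — Newman's two-category assortativity
  `r = (Σ e_ii − Σ a_i²) / (1 − Σ a_i²)` per cluster and label (site or
  habitat), tested against a topology-preserving label-shuffle null with a
  one-sided KS test; per-cluster abundance, site occurrence (of 8 sites) and
  Simpson evenness `SI = 1 − Σ p_i²`.

Edges come from BLAST-style filtered pairwise hits (E-value < 1e-5, identity
≥ 60%, alignment length ≥ 40% of the shorter sequence; records ≥ 300 bp,
dereplicated per site) produced either by the built-in compiled
Smith–Waterman aligner (match +1, mismatch −2, gap open −5, gap extend −2,
Karlin–Altschul E-values) or imported from standard 12-column BLAST tabular
files.

A seeded synthetic-community generator plants species with known dispersal
patterns (endemic, cosmopolitan, habitat-structured) and known novelty
status, so every stage can be validated against ground truth.

## Worked example

Twelve planted species (10 sequences each, one site per species — an endemic
scenario), through the whole pipeline:

```r
library(seqsimnet)

cfg <- scenario_config(n_species = 12, seqs_per_species = 10,
                       dispersal_mode = "endemic", seed = 42)
sim <- generate_dataset(cfg)
hits <- filter_hits(all_vs_all_hits(sim$records), sim$records)

net85 <- build_network(hits, sim$records, 85)
net97 <- build_network(hits, sim$records, 97)
cc85  <- connected_components(net85)
lc85  <- louvain_level1(net85, seed = 1)

cultured <- sim$records[sim$records$epoch == "cultured", ]
novel_lcs(lc85, sim$records, cultured, hits = hits)

scan <- assortativity_scan(net85, cc85, "site", n_perm = 100, seed = 5)
dispersal_test(scan)
```

Output (abridged):

```
138 records; 3 planted novel species
3468 filtered hits
85%: 138 nodes, 1276 edges, 8 CCs, 9 LCs
97%: 12 CCs

          cluster  n mean_identity
1 LC_ENV_sp01_001 10      80.92820
2 LC_ENV_sp05_001 10      80.12383
3 LC_ENV_sp10_001 10      81.64784

site assortativity: D = 0.51, p = 3.34e-03, significant: TRUE
restricted (<=4 sites): 100%; median abundance 12
```

Reading this: at the permissive 85% threshold related species merge into 8
components, while at 97% the 12 components recover the planted species
exactly. The three communities flagged novel are precisely the three planted
reference-free species (members ~80% identical to their closest cultured
relative, below the 95% rule). Site assortativity across the 85% components
is far above its label-shuffle null (one-sided KS, p ≈ 0.003), and every
97% cluster is restricted to ≤ 4 sites — the signature of endemism, as
planted.

The same analysis runs from the shell:

```sh
Rscript inst/cli/ssn-pipeline.R pipeline --simulate-mode endemic --seed 7 --out run1
```

which writes networks (GraphML + edge lists), partitions, novelty and
biogeography tables, the resolved configuration and a JSON manifest of
per-stage counts under `run1/`. Subcommands `simulate`, `similarity`,
`network`, `novelty` and `biogeo` run each stage standalone on the previous
stage's files.

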