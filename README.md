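# panbreve

Comparative pan-genomics of bacterial strain panels, built around the
*Bifidobacterium breve* taxon. Given per-strain gene tables, all-vs-all
protein similarity hits, carbohydrate growth phenotypes and per-orthologue
gene trees, the package:

- builds **gene families** by bidirectional-hit filtering (E ≤ 1e-4,
  identity ≥ 50%, coverage ≥ 50% of either protein) followed by Markov
  clustering (MCL) of the −log10(E)-weighted similarity graph;
- partitions families into **core** (all strains), **dispensable**
  (some strains) and **unique** (one strain), and extracts single-copy,
  mobilome-free **orthologues**;
- computes **pan-/core-genome accumulation curves** over genome orderings
  and fits `new(N) = κ·N^−α` (Heaps' law), `pan(N) = κ·N^γ` and
  `core(N) = A·e^−(N−1)/τ + ω`, calling the pan-genome **closed** iff
  α > 1;
- flags ORFs with **deviant G+C** (> 68% or < 49% against a ~58%
  background) and aggregates them into candidate **HGT regions**;
- **matches gene presence/absence clusters to growth phenotypes**
  (OD600 ≥ 0.3 = growth) by Hamming distance, ranking candidate causal
  clusters per carbohydrate;
- computes **majority-rule consensus trees** from gene trees via
  bipartition counting, with per-edge support percentages.

A seeded synthetic strain-panel generator (`simulate_panel()`) with full
ground truth (family membership, HGT blocks, causal trait clusters,
species tree) makes every stage testable end to end without downloading
any accession.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the
bundled synthetic demo (eight strains, 300 core + 150 dispensable +
80 unique families, five deviated-G+C blocks, eight traits; seed 42):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_families.R
Rscript analysis/03_pangenome.R
Rscript analysis/04_gc_regions.R
Rscript analysis/05_traits.R
Rscript analysis/06_consensus.R
Rscript analysis/07_genome_stats.R
```

Output (abridged) and what it means:

```
panel: 8 strains, 3172 genes, 19910 similarity hits
families: 530 (core 300, dispensable 150, unique 80); single-copy orthologues: 224
adjusted Rand index vs ground truth: 1
```

The clustering recovers the generator's 530 true families exactly
(ARI = 1); 224 of the 300 core families are single-copy and
mobilome-free, the orthologue pool.

```
pan(G) = 530, core(G) = 300 over 8 genomes (1000 orderings)
new-gene fit: new(N) = 99.64 * N^-1.185 -> alpha = 1.185, pan-genome called closed
```

The fitted decay exponent α = 1.19 > 1 classifies this synthetic
pan-genome as closed — new-gene discovery dies off faster than 1/N.

```
399 of 3172 genes carry deviant G+C (157 high, 242 low)
40 variable regions across 8 genomes
9.8% of gene families contain a deviant gene; 99.5% of deviant genes lie inside the regions
```

The five planted HGT blocks per strain surface as 40 regions (5 × 8), and
the deviant-family fraction matches the generator's ~10% setting.

```
trait01 <- Cluster111 (d = 0) ... trait08 <- Cluster4 (d = 0)
consensus of 165 gene trees: 5 majority splits (supports 94-100%)
consensus identical to the species tree: TRUE
inversion spans: JCM 7017 169 Kb; ACS-071-V-Sch8b 1041 Kb
```

Every trait's best-matching cluster sits at Hamming distance 0 (the causal
cluster or an exact-pattern tie), the consensus of the 165 perturbed gene
trees reproduces the species tree, and the interval arithmetic on the two
published inversion coordinate pairs gives their printed spans.

All stage tables land under `results/` (`families/`, `pangenome/`,
`gc_regions/`, `traits/`, `consensus/`, `stats/`), with stable column
orders as written by the scripts. `run_pipeline()` runs the same sequence
as one call from a YAML config (see
`inst/extdata/demo_config.yaml`) and writes an MD5-checksummed manifest;
identical configurations reproduce identical checksums.

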