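---
title: "Methods: comparative pan-genomics of a B. breve strain panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative pan-genomics of a B. breve strain panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`panbreve` implements the comparative-genomics workflow used to
characterize the *Bifidobacterium breve* taxon from a panel of strain
genomes: gene-family construction from all-vs-all protein similarity,
core/dispensable/unique partitioning, pan- and core-genome accumulation
with Heaps'-law classification, G+C-based detection of putative
horizontally transferred (HGT) regions, gene-trait matching against
carbohydrate growth phenotypes, and a majority-rule consensus tree over
per-orthologue gene trees. Sequencing, assembly, ORF prediction,
annotation, and the BLAST runs themselves are upstream of this package:
gene tables, similarity hits, phenotypes and gene trees are consumed as
inputs.

# Gene families

Similarity hits (14-column extended BLAST tabular: the standard 12 columns
plus query and subject lengths) are filtered at E-value <= 1e-4, percent
identity >= 50, and alignment coverage of at least 50% of *either*
protein, read as `aln_length >= 0.5 * min(q_len, s_len)` — the permissive
interpretation of "either". The extended dialect is required rather than
optional because the coverage rule needs both sequence lengths.

An undirected similarity graph keeps an edge only when passing hits exist
in *both* directions; the edge weight is `min(200, -log10(E_best))` with
E = 0 capped at 200. The Markov Cluster algorithm then alternates
expansion (matrix squaring) and inflation (entrywise power 1.8 with column
renormalization) with pruning at 1e-8 until the largest entry change falls
below 1e-6 (cap: 100 iterations). Clusters are connected components of the
limit matrix's support. Inflation 1.8 and the convergence constants follow
common MCL practice; the original pipeline's parameters are not published,
so all are exposed in configuration. An identity-based edge weighting is
not provided because the E-value transform is the conventional
`mclblastline`-style scheme.

Families present in all panel genomes are core, in 2..(G-1) genomes
dispensable, in one genome unique; genes with no surviving hits become
singleton unique families rather than being dropped, so the families
always partition the gene set. A core family with exactly one member per
genome and no mobilome member (annotation keyword match: transposase, IS
element, insertion sequence, integrase, phage, mobile element) is a
single-copy orthologue. Mobilome exclusion applies only to the orthologue
pool — pan-genome accounting keeps mobile families, since mobile elements
dominate the unique-gene class in real panels.

# Pan-genome accumulation and openness

Presence is copy count >= 1 (paralogues do not inflate counts). For each
genome ordering, pan(N) and core(N) are counted over prefixes; orderings
are exhaustive up to G = 8 and seeded uniform samples (default 1000)
beyond. Per-N summaries use the *lower-middle* median so count data stay
integral; the original pipeline's summary convention is unpublished.

Fits: `new(N) = kappa * N^-alpha` and `pan(N) = kappa * N^gamma` by least
squares in log space (N = 1 and zero medians excluded from the new-gene
fit, which is undefined there), and
`core(N) = A * exp(-(N-1)/tau) + omega` by Levenberg-Marquardt nonlinear
least squares initialized at `omega = core(G)`, `A = core(1) - omega`,
`tau = 2`. The pan-genome is called *closed* iff `alpha > 1`, the standard
Heaps'-law criterion; the source analysis reports only a qualitative
"essentially closed trend", so the quantitative rule is this package's
choice.

# G+C deviation and variable regions

Per-ORF G+C is `100 * (G+C) / (A+C+G+T)` with N bases excluded from both
numerator and denominator; an all-N sequence is an error, not 0. Genes are
flagged at *strict* thresholds > 68% or < 49% (boundary values unflagged),
mirroring the published wording. Flagged genes at most 5 unflagged genes
apart (per contig, gene-order based rather than bp-based) join one region;
regions need at least 5 flagged members. The published analysis gives only
the outcome (eight regions holding 85% of deviant genes), not the
aggregation rule, so both parameters are exposed. The family-level
deviation fraction counts families with at least one flagged member.

# Gene-trait matching

OD600 endpoint readings binarize at 0.3 with the boundary counting as
growth (the boundary direction is unstated upstream; inclusive was chosen
once). Families constant across the assayed strains cannot carry signal
and are set aside. The default clustering mode groups families by
*identical* presence pattern; an average-linkage agglomeration on Hamming
distance (`mode = "hcl"`, cut height in Hamming units, majority consensus
pattern with ties resolving to present) is available as an opt-in
coarsening, since the published 51-cluster analysis does not state its
metric, linkage or cut. Matching distance is the plain Hamming distance
between a cluster's pattern and a trait's growth column; per trait,
clusters rank ascending by distance with ties sharing the lower rank. The
anti-match distance (n_strains - d) is reported in its own column but
never enters the ranking, because the published matches are all
presence-positive. Carbohydrates with constant growth are unmatchable and
reported as such.

# Consensus trees

Each gene tree is decomposed into non-trivial unrooted bipartitions,
canonicalized as the side not containing the lexicographically smallest
taxon. Splits present in strictly more than half the trees (exactly half
is excluded, matching Consense's majority-rule default) are assembled into
a tree by laminar-family nesting, with each internal edge labelled by its
integer-percent support; unresolved parts remain polytomies. A greedy
extended-majority mode (adding compatible minority splits by decreasing
support) is available behind a flag, default off.

# The synthetic panel generator

The generator emulates the statistical structure of the real panel so each
stage is testable against known ground truth: S strains sharing a core
family set (default 13 strains, 1300 core families), dispensable families
with per-strain Bernoulli presence conditioned to land in 2..(S-1) strains
(so realized classes match the catalogue exactly), 50 strain-unique
families per genome, a 14% paralogue fraction, a 2% mobilome fraction,
background G+C drawn at 58 +/- 2% (the taxon's average), and eight
contiguous HGT blocks of 36 families at deviated targets 40% / 72%,
jointly covering ~10% of families — the published deviant fraction. Genes
are laid out consecutively on one contig per strain with uniform 50-200 bp
gaps; start codons draw from ATG 87%, GTG 9.53%, TTG 3.24%, CTG 0.08%
(renormalized); sequences are iid per position at the gene's target G+C
(no codon model — sequence realism is not needed by any in-scope
computation beyond G+C and start codons). Within-family hits are emitted
in both directions at identity U(60, 100), coverage >= 0.8 of the shorter
protein and E <= 1e-20; spurious cross-family hits (per-gene probability,
identity U(25, 45), E in U(1e-3, 1)) sit entirely below the filter
cut-offs, so this noise class is absorbed by the hit filter rather than by
MCL — passing the spurious-hit test demonstrates the filter contract, not
clustering robustness. Growth ODs draw from [0.5, 1.2] for growth and
[0.05, 0.25] otherwise, straddling the 0.3 cut-off unambiguously; label
noise enters only through an explicit flip probability. One global seed
drives per-component sub-streams (layout, sequences, hits, phenotypes,
species tree), so adding a component does not perturb the others, and
fixed seeds fix every output byte.

HGT blocks occupy non-adjacent slots of the shared core-family layout and
are applied in every strain, mirroring panel-level variable regions; block
separation of at least one block-length of background genes keeps distinct
blocks separable as regions under the default gap rule. What the generator
does *not* emulate: phylogenetically correlated presence patterns,
rearrangements, plasmids/prophages, codon usage, assembly artifacts, and
hit-score structure beyond the identity/E-value envelopes. Recovery tests
on this generator therefore validate the pipeline's logic and contracts,
not its behavior on real sequence data.

# Validation-panel sizes and numerical choices

Tests run on reduced panels chosen to keep each property sharp:

- Family-recovery uses the full 13-strain, 1300 + 900 + 650-family panel
  (~23,600 genes, ~240,000 hits), which clusters in well under a minute.
- The trait-recovery panel under label noise (flip probability 0.1, 9
  strains, 8 traits) uses 30 dispensable families (8 causal clusters of 3
  plus 6 free) and no strain-unique families. This is a power decision:
  over 9 strains there are only 512 possible presence patterns, so every
  additional non-causal pattern cluster adds a chance that a trait with a
  flipped label is "defeated" by a coincidental exact match. At ~44
  competing clusters the defeat probability is ~14% per trait and the
  >= 7/8 recovery property holds for barely half of random seeds — the
  test would measure collision luck, not the matching machinery. Keeping
  competing clusters near a dozen holds the collision defeat rate under
  ~5% per trait, so a failure would actually indicate a defect.
- Heaps-exponent recovery uses curves generated directly from the model
  with multiplicative U(0.9, 1.1) noise over 500 orderings at G = 13,
  which isolates the fitting step from the clustering stages.
- G+C recovery uses a 200-family panel with 2 x 10 block families, making
  the expected deviant-family fraction exactly 10%.

Degenerate inputs are handled explicitly: empty hit sets give
singleton-only clusterings; an all-core presence matrix refuses the
new-gene fit (log of zero); trees with fewer than four leaves have no
non-trivial splits; all-N sequences are errors. Ties are deterministic
throughout (lower-middle medians, lower shared ranks ordered by cluster
id, consensus ties impossible at strict majority).

# Known limitations

Published headline numbers that require the thirteen GenBank accessions
and a version-matched BLAST (pan 3667, core 1307, 1141 orthologues) are
out of desk-scale reach and are represented here by the recovery
properties above, not reproduced. The G+C region finder assigns no
identity to specific published regions (REG1-8); it reports coordinates
and membership only. Matching distances carry no significance testing, as
none is defined upstream.
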