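# Bundled synthetic demo: an eight-strain panel with core, dispensable and
# strain-unique families, five deviated-G+C blocks, eight carbohydrate
# traits with causal clusters, and 165 gene trees from the species tree.
seed: 42
outdir: results/demo
panel:
  n_strains: 8
  n_core: 300
  n_dispensable: 150
  n_unique_per_strain: 10
  hgt_block_count: 5
  hgt_block_size: 10
  n_traits: 8
n_gene_trees: 165
exhaustive_max: 6
n_permutations: 1000
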