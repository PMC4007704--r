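#!/usr/bin/env Rscript
# Stage 6: majority-rule consensus of the per-orthologue gene trees, with
# per-edge support percentages, compared against the generating species tree.

suppressMessages(library(panbreve))

trees <- read_newick("results/inputs/gene_trees.nwk")
cons <- majority_consensus(trees)
message("consensus of ", cons$n_trees, " gene trees: ",
        sum(cons$splits$retained), " majority splits (supports ",
        paste(range(round(cons$splits$support[cons$splits$retained])),
              collapse = "-"), "%)")

truth <- jsonlite::read_json("results/inputs/ground_truth.json")
sp <- ape::read.tree(text = truth$species_tree)
message("consensus identical to the species tree: ",
        same_topology(cons$tree, sp))

dir.create("results/consensus", showWarnings = FALSE, recursive = TRUE)
write_newick(cons$tree, "results/consensus/consensus.nwk")
write.table(cons$splits, "results/consensus/splits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
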