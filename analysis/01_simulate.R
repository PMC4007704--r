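#!/usr/bin/env Rscript
# Stage 1: generate the synthetic eight-strain demo panel with known ground
# truth, plus 165 gene trees perturbed from the species tree, and write all
# pipeline input files under results/inputs/.

suppressMessages(library(panbreve))

cfg <- pipeline_config(yaml = system.file("extdata", "demo_config.yaml",
                                          package = "panbreve"))
pcfg <- do.call(panel_config,
                utils::modifyList(list(seed = cfg$seed), cfg$panel))
panel <- simulate_panel(pcfg)
paths <- write_panel(panel, "results/inputs")
trees <- simulate_gene_trees(panel$truth$species_tree, cfg$n_gene_trees,
                             cfg$perturb_prob, seed = cfg$seed)
write_newick(trees, "results/inputs/gene_trees.nwk")

message("panel: ", length(unique(panel$genes$genome_id)), " strains, ",
        nrow(panel$genes), " genes, ", nrow(panel$hits), " similarity hits")
message("true families: ",
        paste(names(table(panel$truth$class_of)),
              table(panel$truth$class_of), collapse = ", ", sep = "="))
message("wrote ", length(paths) + 1, " input files under results/inputs/")
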