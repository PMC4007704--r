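#!/usr/bin/env Rscript
# Stage 4: per-ORF G+C, deviant-gene flagging (>68% / <49%), aggregation of
# flagged genes into variable regions, and the panel-level deviation summary.

suppressMessages(library(panbreve))

genes <- read_gene_table("results/inputs/genes.tsv")
seqs <- read_gene_fasta("results/inputs/genes.fna")
genes$nt_seq <- unname(seqs[genes$gene_id])

profiles <- flag_deviant(genes$gene_id, gc_percent(genes$nt_seq))
message(sum(profiles$flag != "none"), " of ", nrow(genes),
        " genes carry deviant G+C (",
        sum(profiles$flag == "high"), " high, ",
        sum(profiles$flag == "low"), " low)")

regions <- aggregate_regions(genes, profiles)
message(nrow(regions), " variable regions across ",
        length(unique(regions$genome_id)), " genomes")

members <- read.delim("results/families/families.tsv")
fams <- list(families = data.frame(family_id = unique(members$family_id)),
             members = members)
ds <- deviation_summary(fams, profiles, regions)
message(round(100 * ds$family_deviant_fraction, 1),
        "% of gene families contain a deviant gene; ",
        round(100 * ds$flagged_in_region_fraction, 1),
        "% of deviant genes lie inside the regions")

dir.create("results/gc_regions", showWarnings = FALSE, recursive = TRUE)
write.table(profiles, "results/gc_regions/gc_per_gene.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(regions, "results/gc_regions/regions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(family_deviant_fraction = ds$family_deviant_fraction,
       flagged_in_region_fraction = ds$flagged_in_region_fraction,
       n_flagged_genes = ds$n_flagged_genes),
  "results/gc_regions/summary.json", auto_unbox = TRUE, digits = 10)
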