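#!/usr/bin/env Rscript
# Stage 7: per-genome descriptive statistics for the synthetic panel, the
# published eight-genome feature averages, and the inversion interval
# arithmetic.

suppressMessages(library(panbreve))

genes <- read_gene_table("results/inputs/genes.tsv")
seqs <- read_gene_fasta("results/inputs/genes.fna")
genes$nt_seq <- unname(seqs[genes$gene_id])
summaries <- do.call(rbind, lapply(split(genes, genes$genome_id),
                                   function(g) summarize_genome(g, max(g$end))))
avg <- panel_averages(summaries)
message("synthetic panel: mean ", avg$mean_n_genes, " genes per genome, ",
        "ATG start codon ", round(mean(summaries$pct_start_ATG), 1), "%")

feats <- breve_panel_features()
pub <- panel_averages(feats)
message("published eight-genome averages: length ",
        pub$mean_genome_length_bp, " bp, ", pub$mean_n_genes, " genes, ",
        pub$mean_n_trna, " tRNA, ", pub$mean_n_is, " IS elements, ",
        pub$mean_pct_hypothetical, "% hypothetical / ",
        pub$mean_pct_assigned, "% assigned")

inv1 <- interval_length(1181452, 1350961)
inv2 <- interval_length(611964, 1653404)
message("inversion spans: JCM 7017 ", inv1$kb_floor, " Kb; ",
        "ACS-071-V-Sch8b ", inv2$kb_floor, " Kb")

dir.create("results/stats", showWarnings = FALSE, recursive = TRUE)
write.table(summaries, "results/stats/genome_summaries.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(synthetic_panel = avg, published_panel = pub,
                          inversions_kb = c(jcm7017 = inv1$kb_floor,
                                            acs071 = inv2$kb_floor)),
                     "results/stats/panel_averages.json", auto_unbox = TRUE,
                     digits = 10)
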