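#!/usr/bin/env Rscript
# Stage 5: binarize carbohydrate growth at OD 0.3, group dispensable
# families into presence/absence clusters, and rank clusters against each
# trait by Hamming matching distance.

suppressMessages(library(panbreve))

od <- read_phenotypes("results/inputs/phenotypes.csv")
gm <- binarize_growth(od)
message("growth calls: ", sum(gm$growth), " of ", length(gm$growth),
        " strain x carbohydrate combinations at OD >= ", gm$cutoff)

pm_df <- read.delim("results/families/presence_matrix.tsv",
                    check.names = FALSE)
pm <- as.matrix(pm_df[, -1]); rownames(pm) <- pm_df$family_id
cl <- cluster_patterns(pm[, rownames(od), drop = FALSE])
message(length(unique(cl$clusters$cluster_id)),
        " presence/absence clusters over ",
        nrow(cl$clusters), " variable families (",
        length(cl$constant_families), " constant families set aside)")

mt <- match_traits(cl, gm)
genes <- read_gene_table("results/inputs/genes.tsv")
members <- read.delim("results/families/families.tsv")
ann <- setNames(genes$annotation, genes$gene_id)
fam_ann <- vapply(split(members$gene_id, members$family_id), function(g)
  names(sort(table(ann[g]), decreasing = TRUE))[1], character(1))
cand <- candidate_report(mt, cl, fam_ann)
best <- do.call(rbind, lapply(names(cand), function(s)
  data.frame(carbohydrate = s, cand[[s]][1, c("cluster_id", "distance")])))
message("best cluster per carbohydrate (distance 0 = perfect match):")
for (i in seq_len(nrow(best))) {
  message("  ", best$carbohydrate[i], " <- ", best$cluster_id[i],
          " (d = ", best$distance[i], ")")
}

dir.create("results/traits", showWarnings = FALSE, recursive = TRUE)
write.table(data.frame(strain = rownames(gm$growth), gm$growth,
                       check.names = FALSE),
            "results/traits/growth_matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cl$clusters, "results/traits/clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(cluster_id = rownames(mt$distance_matrix),
                       mt$distance_matrix, check.names = FALSE),
            "results/traits/distance_matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(cand, "results/traits/candidates.json",
                     auto_unbox = TRUE, digits = 10)
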