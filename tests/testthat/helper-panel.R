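# Shared fixtures, built in code.

# A small deterministic panel used across module tests.
small_panel <- function(seed = 7, ...) {
  cfg <- panel_config(n_strains = 4, n_core = 60, n_dispensable = 20,
                      n_unique_per_strain = 3, hgt_block_count = 2,
                      hgt_block_size = 6, n_traits = 3, seed = seed, ...)
  simulate_panel(cfg)
}

# Hand-written gene table TSV.
write_toy_gene_table <- function(path, rows) {
  header <- "genome_id\tgene_id\tcontig_id\tstart\tend\tstrand\tannotation"
  writeLines(c(header, rows), path)
  path
}

# One 14-column hit row.
hit_row <- function(q, s, pident, len, evalue, qlen, slen) {
  paste(q, s, pident, len, 0, 0, 1, len, 1, len, evalue, 100, qlen, slen,
        sep = "\t")
}

make_hit <- function(q, s, pident, len, evalue, qlen, slen) {
  data.frame(query_id = q, subject_id = s, pct_identity = pident,
             aln_length = len, e_value = evalue, q_len = qlen, s_len = slen,
             stringsAsFactors = FALSE)
}

# All permutations of 1..n as a list (independent of the package's own
# ordering generator: different algorithm, used as an enumeration oracle).
perms_list <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_list(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Brute-force accumulation oracle on a list of per-genome gene-family sets:
# unions/intersections via Reduce, lower-middle medians by hand.
oracle_accumulation <- function(sets) {
  G <- length(sets)
  lower_median <- function(x) sort(x)[ceiling(length(x) / 2)]
  pan <- core <- matrix(0L, 0, G)
  for (ord in perms_list(G)) {
    pan_row <- core_row <- integer(G)
    for (N in seq_len(G)) {
      prefix <- sets[ord[seq_len(N)]]
      pan_row[N] <- length(Reduce(union, prefix))
      core_row[N] <- length(Reduce(intersect, prefix))
    }
    pan <- rbind(pan, pan_row)
    core <- rbind(core, core_row)
  }
  list(median_pan = apply(pan, 2, lower_median),
       median_core = apply(core, 2, lower_median))
}

# Assemble a pangenome_curve object directly from a per-permutation matrix
# of new-gene counts (column 1 = pan(1) sizes).
curve_from_new <- function(new_mat, core_mat) {
  pan <- t(apply(new_mat, 1, cumsum))
  G <- ncol(pan)
  lower_median <- function(x) sort(x)[ceiling(length(x) / 2)]
  structure(list(
    n_genomes = G, pan = pan, core = core_mat,
    new = cbind(NA, new_mat[, -1, drop = FALSE]),
    median_pan = apply(pan, 2, lower_median),
    median_core = apply(core_mat, 2, lower_median),
    median_new = c(NA, apply(new_mat[, -1, drop = FALSE], 2, lower_median)),
    n_permutations = nrow(pan), exhaustive = FALSE, seed = NA
  ), class = "pangenome_curve")
}
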