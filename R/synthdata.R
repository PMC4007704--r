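# Start-codon sampling distribution (renormalized before use).
START_CODON_PROBS <- c(ATG = 0.87, GTG = 0.0953, TTG = 0.0324, CTG = 0.0008)

#' Configuration for a synthetic strain panel
#'
#' Builds and validates the parameter set for [simulate_panel()]. Defaults
#' emulate the structure of a 13-strain *B. breve* panel: ~1300 core
#' families, ~900 dispensable families, ~50 strain-unique families per
#' genome, a background G+C of 58% and eight contiguous HGT blocks whose
#' member genes carry strongly deviated G+C (40% or 72%), together covering
#' about 10% of all gene families.
#'
#' @param n_strains number of strains (>= 3).
#' @param n_core number of core gene families (present in every strain).
#' @param n_dispensable number of dispensable families (present in >= 2 but
#'   not all strains).
#' @param presence_prob per-strain presence probability for dispensable
#'   families.
#' @param n_unique_per_strain strain-unique families per genome.
#' @param paralog_frac fraction of core families given a duplicate copy in
#'   one strain.
#' @param mobile_frac fraction of genes annotated as mobilome members.
#' @param gc_mean,gc_sd background per-family G+C percent (normal draw).
#' @param hgt_block_count,hgt_block_size number and size (in families) of
#'   contiguous deviated-G+C blocks placed in the shared core-family layout.
#' @param hgt_gc_low,hgt_gc_high deviated G+C targets; blocks alternate
#'   between the two.
#' @param n_traits number of carbohydrate-growth phenotypes.
#' @param causal_cluster_size dispensable families per causal trait cluster.
#' @param pheno_flip_prob probability that a strain's growth call contradicts
#'   its causal-cluster presence.
#' @param od_growth_range,od_nogrowth_range OD600 sampling intervals for
#'   growth / no-growth calls; the defaults straddle the 0.3 cut-off.
#' @param hit_identity_range percent-identity interval for within-family hits.
#' @param spurious_hit_rate per-gene probability of emitting one spurious
#'   cross-family hit pair (identity U(25,45), E-value U(1e-3,1)).
#' @param gene_len_range gene length interval in bp (rounded to codons).
#' @param intergenic_range intergenic gap interval in bp.
#' @param generate_sequences whether to synthesize nucleotide sequences.
#' @param seed integer seed; fixes every output byte.
#' @return a validated \code{panel_config} list.
#' @export
panel_config <- function(n_strains = 13, n_core = 1300, n_dispensable = 900,
                         presence_prob = 0.5, n_unique_per_strain = 50,
                         paralog_frac = 0.14, mobile_frac = 0.02,
                         gc_mean = 58, gc_sd = 2,
                         hgt_block_count = 8, hgt_block_size = 36,
                         hgt_gc_low = 40, hgt_gc_high = 72,
                         n_traits = 8, causal_cluster_size = 3,
                         pheno_flip_prob = 0,
                         od_growth_range = c(0.5, 1.2),
                         od_nogrowth_range = c(0.05, 0.25),
                         hit_identity_range = c(60, 100),
                         spurious_hit_rate = 0,
                         gene_len_range = c(300, 1500),
                         intergenic_range = c(50, 200),
                         generate_sequences = TRUE,
                         seed = 1) {
  cfg <- as.list(environment())
  if (n_strains < 3) stop("n_strains must be >= 3")
  if (n_core < 1) stop("n_core must be >= 1")
  probs <- c(presence_prob, mobile_frac, paralog_frac, pheno_flip_prob,
             spurious_hit_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (hgt_block_count * hgt_block_size > n_core) {
    stop("HGT blocks do not fit: hgt_block_count * hgt_block_size (",
         hgt_block_count * hgt_block_size, ") exceeds n_core (", n_core, ")")
  }
  if (n_traits > 0 && n_dispensable < n_traits * causal_cluster_size) {
    stop("not enough dispensable families for the requested causal clusters")
  }
  if (max(od_nogrowth_range) >= 0.3 || min(od_growth_range) <= 0.3) {
    stop("OD ranges must straddle the 0.3 growth cut-off")
  }
  class(cfg) <- "panel_config"
  cfg
}

# Component-specific sub-seed so adding a component never perturbs others.
sub_seed <- function(seed, offset) {
  set.seed((as.integer(seed) + offset) %% .Machine$integer.max)
}

#' Simulate a strain panel with known ground truth
#'
#' Generates the full input set for the pipeline: per-strain gene tables
#' (one synthetic contig per strain, genes laid out consecutively with
#' uniform intergenic gaps), nucleotide sequences with per-position G+C
#' probability equal to each gene's target G+C and start codons drawn from
#' the ATG/GTG/TTG/CTG distribution, all-vs-all similarity hits consistent
#' with family membership (plus optional spurious cross-family hits), a
#' strains-by-carbohydrates OD phenotype table driven by designated causal
#' gene clusters, and the ground truth needed to score every downstream
#' stage.
#'
#' @param config a [panel_config()].
#' @return list with elements \code{genes} (gene table), \code{hits},
#'   \code{phenotypes} (OD matrix), and \code{truth} (list: \code{family_of},
#'   \code{class_of}, \code{hgt_genes}, \code{causal_cluster_of},
#'   \code{species_tree}, \code{presence}).
#' @export
simulate_panel <- function(config = panel_config()) {
  stopifnot(inherits(config, "panel_config"))
  cfg <- config
  strains <- sprintf("S%02d", seq_len(cfg$n_strains))

  ## -- layout stream: family catalogue, presence, paralogs, HGT blocks -----
  sub_seed(cfg$seed, 1L)
  core_ids <- sprintf("C%04d", seq_len(cfg$n_core))
  disp_ids <- if (cfg$n_dispensable > 0) {
    sprintf("D%04d", seq_len(cfg$n_dispensable))
  } else character(0)

  # Dispensable presence: Bernoulli per strain, conditioned on being present
  # in >= 2 but not all strains so realized classes match the catalogue.
  presence_disp <- matrix(0L, nrow = cfg$n_dispensable, ncol = cfg$n_strains,
                          dimnames = list(disp_ids, strains))
  for (i in seq_len(cfg$n_dispensable)) {
    repeat {
      v <- stats::rbinom(cfg$n_strains, 1L, cfg$presence_prob)
      s <- sum(v)
      if (s >= 2L && s < cfg$n_strains) break
    }
    presence_disp[i, ] <- v
  }

  # Causal trait clusters: disjoint groups of dispensable families forced to
  # share one non-constant presence pattern.
  causal <- list()
  if (cfg$n_traits > 0) {
    idx <- seq_len(cfg$n_traits * cfg$causal_cluster_size)
    for (t in seq_len(cfg$n_traits)) {
      repeat {
        v <- stats::rbinom(cfg$n_strains, 1L, cfg$presence_prob)
        if (sum(v) >= 2L && sum(v) < cfg$n_strains) break
      }
      rows <- idx[((t - 1) * cfg$causal_cluster_size + 1):(t * cfg$causal_cluster_size)]
      presence_disp[rows, ] <- rep(v, each = length(rows))
      causal[[sprintf("trait%02d", t)]] <- disp_ids[rows]
    }
  }

  unique_ids <- character(0)
  unique_strain <- character(0)
  if (cfg$n_unique_per_strain > 0) {
    for (s in strains) {
      ids <- sprintf("U_%s_%03d", s, seq_len(cfg$n_unique_per_strain))
      unique_ids <- c(unique_ids, ids)
      unique_strain <- c(unique_strain, rep(s, length(ids)))
    }
  }

  all_fams <- c(core_ids, disp_ids, unique_ids)
  fam_class <- c(rep("core", length(core_ids)),
                 rep("dispensable", length(disp_ids)),
                 rep("unique", length(unique_ids)))
  names(fam_class) <- all_fams

  # Family-level attributes: gene length (codon multiple), background G+C.
  fam_len <- 3L * sample(seq(cfg$gene_len_range[1] %/% 3,
                             cfg$gene_len_range[2] %/% 3),
                         length(all_fams), replace = TRUE)
  names(fam_len) <- all_fams
  fam_gc <- stats::rnorm(length(all_fams), cfg$gc_mean, cfg$gc_sd)
  fam_gc <- pmin(pmax(fam_gc, 25), 75)
  names(fam_gc) <- all_fams

  # HGT blocks: non-overlapping contiguous runs in the core-family layout,
  # applied in every strain; blocks alternate low/high G+C targets.
  hgt_fams <- character(0)
  block_of <- integer(0)
  if (cfg$hgt_block_count > 0 && cfg$hgt_block_size > 0) {
    n_slots <- cfg$n_core %/% cfg$hgt_block_size
    if (cfg$hgt_block_count > ceiling(n_slots / 2)) {
      stop("cannot place ", cfg$hgt_block_count,
           " non-adjacent HGT blocks in ", n_slots, " slots")
    }
    # Non-adjacent slots so separate blocks stay separable as regions.
    repeat {
      slots <- sort(sample(n_slots, cfg$hgt_block_count))
      if (cfg$hgt_block_count < 2 || all(diff(slots) >= 2)) break
    }
    starts <- (slots - 1L) * cfg$hgt_block_size + 1L
    for (b in seq_along(starts)) {
      fams <- core_ids[starts[b]:(starts[b] + cfg$hgt_block_size - 1L)]
      hgt_fams <- c(hgt_fams, fams)
      block_of <- c(block_of, rep(b, length(fams)))
      fam_gc[fams] <- if (b %% 2 == 1) cfg$hgt_gc_low else cfg$hgt_gc_high
    }
  }

  # Paralogs: a fraction of (non-HGT) core families duplicated in one strain.
  paralog_pool <- setdiff(core_ids, hgt_fams)
  n_para <- round(cfg$paralog_frac * cfg$n_core)
  n_para <- min(n_para, length(paralog_pool))
  para_fams <- if (n_para > 0) sample(paralog_pool, n_para) else character(0)
  para_strain <- if (n_para > 0) sample(strains, n_para, replace = TRUE) else character(0)
  names(para_strain) <- para_fams

  ## -- gene records --------------------------------------------------------
  rows <- vector("list", cfg$n_strains)
  for (si in seq_along(strains)) {
    s <- strains[si]
    fams <- c(core_ids,
              disp_ids[presence_disp[, si] == 1L],
              unique_ids[unique_strain == s])
    copies <- rep(1L, length(fams))
    copies[match(para_fams[para_strain == s], fams)] <- 2L
    fam_rep <- rep(fams, copies)
    copy_no <- unlist(lapply(copies, seq_len), use.names = FALSE)
    gene_ids <- paste0(s, "|", fam_rep, "|", copy_no)
    lens <- fam_len[fam_rep]
    gaps <- sample(cfg$intergenic_range[1]:cfg$intergenic_range[2],
                   length(fam_rep), replace = TRUE)
    starts <- cumsum(c(1L, (lens + gaps)[-length(lens)]))
    rows[[si]] <- data.frame(
      genome_id = s, gene_id = gene_ids, contig_id = paste0(s, "_contig1"),
      start = as.integer(starts), end = as.integer(starts + lens - 1L),
      strand = "+", family_id = fam_rep, stringsAsFactors = FALSE
    )
  }
  genes <- do.call(rbind, rows)

  mobile <- stats::runif(nrow(genes)) < cfg$mobile_frac
  annotation <- ifelse(fam_class[genes$family_id] == "core",
                       "conserved housekeeping protein",
                       "hypothetical protein")
  causal_fams <- unlist(causal, use.names = FALSE)
  annotation[genes$family_id %in% causal_fams] <-
    "carbohydrate utilization cluster protein"
  annotation[mobile] <- "IS30 family transposase"
  genes$annotation <- annotation
  genes$is_mobile <- is_mobilome(annotation)
  genes$strand <- rep(c("+", "-"), length.out = nrow(genes))

  ## -- sequence stream -----------------------------------------------------
  if (cfg$generate_sequences) {
    sub_seed(cfg$seed, 2L)
    genes$nt_seq <- synth_sequences(fam_len[genes$family_id],
                                    fam_gc[genes$family_id])
  }
  genes$aa_len <- as.integer(fam_len[genes$family_id] %/% 3L)

  ## -- hit stream ----------------------------------------------------------
  sub_seed(cfg$seed, 3L)
  hits <- synth_hits(genes, cfg)

  ## -- phenotype stream ----------------------------------------------------
  sub_seed(cfg$seed, 4L)
  pheno <- NULL
  if (cfg$n_traits > 0) {
    growth <- matrix(0L, cfg$n_strains, cfg$n_traits,
                     dimnames = list(strains,
                                     sprintf("trait%02d", seq_len(cfg$n_traits))))
    for (t in seq_len(cfg$n_traits)) {
      fam1 <- causal[[t]][1]
      present <- presence_disp[fam1, ]
      flip <- stats::runif(cfg$n_strains) < cfg$pheno_flip_prob
      growth[, t] <- ifelse(flip, 1L - present, present)
    }
    od <- matrix(stats::runif(length(growth),
                              cfg$od_nogrowth_range[1], cfg$od_nogrowth_range[2]),
                 nrow = nrow(growth), dimnames = dimnames(growth))
    gi <- growth == 1L
    od[gi] <- stats::runif(sum(gi), cfg$od_growth_range[1], cfg$od_growth_range[2])
    pheno <- od
  }

  ## -- species tree stream -------------------------------------------------
  sub_seed(cfg$seed, 5L)
  species_tree <- ape::rtree(cfg$n_strains, tip.label = strains)

  presence_all <- rbind(
    matrix(1L, length(core_ids), cfg$n_strains,
           dimnames = list(core_ids, strains)),
    presence_disp,
    t(vapply(seq_along(unique_ids), function(i) as.integer(strains == unique_strain[i]),
             integer(cfg$n_strains)))
  )
  rownames(presence_all) <- all_fams
  colnames(presence_all) <- strains

  truth <- list(
    family_of = stats::setNames(genes$family_id, genes$gene_id),
    class_of = fam_class,
    hgt_genes = genes$gene_id[genes$family_id %in% hgt_fams],
    hgt_families = hgt_fams,
    hgt_block_of = stats::setNames(block_of, hgt_fams),
    causal_cluster_of = causal,
    species_tree = species_tree,
    presence = presence_all
  )
  genes$family_id <- NULL
  genes <- genes[order(genes$genome_id, genes$contig_id, genes$start), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  list(genes = genes, hits = hits, phenotypes = pheno, truth = truth)
}

# Vectorized sequence synthesis: start codon from the renormalized codon
# distribution, remaining positions iid with P(G or C) = target G+C.
synth_sequences <- function(lens, gcs) {
  n <- length(lens)
  probs <- START_CODON_PROBS / sum(START_CODON_PROBS)
  starts <- sample(names(probs), n, replace = TRUE, prob = probs)
  total <- sum(lens - 3L)
  is_gc <- stats::runif(total) < rep(gcs / 100, lens - 3L)
  pick_strong <- sample(c("G", "C"), total, replace = TRUE)
  pick_weak <- sample(c("A", "T"), total, replace = TRUE)
  bases <- ifelse(is_gc, pick_strong, pick_weak)
  idx_end <- cumsum(lens - 3L)
  idx_start <- c(1L, idx_end[-n] + 1L)
  body <- substring(paste(bases, collapse = ""), idx_start, idx_end)
  paste0(starts, body)
}

synth_hits <- function(genes, cfg) {
  fam <- sub("^[^|]+\\|([^|]+)\\|.*$", "\\1", genes$gene_id)
  aa <- genes$aa_len
  names(aa) <- genes$gene_id
  out <- list()
  add <- function(df) out[[length(out) + 1L]] <<- df
  for (members in split(genes$gene_id, fam)) {
    k <- length(members)
    if (k < 2) next
    pair <- expand.grid(q = seq_len(k), s = seq_len(k))
    pair <- pair[pair$q != pair$s, , drop = FALSE]
    q <- members[pair$q]; s <- members[pair$s]
    mlen <- pmin(aa[q], aa[s])
    add(data.frame(
      query_id = q, subject_id = s,
      pct_identity = round(stats::runif(length(q), cfg$hit_identity_range[1],
                                        cfg$hit_identity_range[2]), 1),
      aln_length = as.integer(ceiling(stats::runif(length(q), 0.8, 1) * mlen)),
      e_value = 10^(-stats::runif(length(q), 20, 100)),
      q_len = as.integer(aa[q]), s_len = as.integer(aa[s]),
      stringsAsFactors = FALSE
    ))
  }
  if (cfg$spurious_hit_rate > 0) {
    pick <- which(stats::runif(nrow(genes)) < cfg$spurious_hit_rate)
    if (length(pick) > 0) {
      partner <- vapply(pick, function(i) {
        cand <- which(fam != fam[i])
        cand[sample.int(length(cand), 1L)]
      }, integer(1))
      q <- genes$gene_id[pick]; s <- genes$gene_id[partner]
      mlen <- pmin(aa[q], aa[s])
      sp <- data.frame(
        query_id = c(q, s), subject_id = c(s, q),
        pct_identity = rep(round(stats::runif(length(q), 25, 45), 1), 2),
        aln_length = rep(as.integer(ceiling(stats::runif(length(q), 0.3, 0.6) * mlen)), 2),
        e_value = rep(stats::runif(length(q), 1e-3, 1), 2),
        q_len = as.integer(c(aa[q], aa[s])), s_len = as.integer(c(aa[s], aa[q])),
        stringsAsFactors = FALSE
      )
      add(sp)
    }
  }
  hits <- do.call(rbind, out)
  if (is.null(hits)) hits <- empty_hits()
  rownames(hits) <- NULL
  hits
}

#' Simulate gene trees from a species tree
#'
#' Produces \code{n_trees} copies of the species tree, each independently
#' subjected to one random nearest-neighbour interchange with probability
#' \code{perturb_prob}; emulates per-orthologue gene trees whose topologies
#' mostly agree with the species tree.
#'
#' @param species_tree a \code{phylo} with >= 4 leaves.
#' @param n_trees number of gene trees.
#' @param perturb_prob probability of applying one NNI move to a tree.
#' @param seed integer seed.
#' @return list of \code{phylo} objects.
#' @export
simulate_gene_trees <- function(species_tree, n_trees, perturb_prob = 0.2,
                                seed = 1) {
  if (perturb_prob < 0 || perturb_prob > 1) {
    stop("perturb_prob must lie in [0, 1]")
  }
  if (length(species_tree$tip.label) < 4) {
    stop("species_tree must have >= 4 leaves")
  }
  if (n_trees == 0) return(list())
  set.seed(as.integer(seed))
  lapply(seq_len(n_trees), function(i) {
    if (stats::runif(1) < perturb_prob) {
      phangorn::rNNI(species_tree, moves = 1)
    } else {
      species_tree
    }
  })
}

#' Write a simulated panel to pipeline input files
#'
#' @param panel result of [simulate_panel()].
#' @param dir output directory (created if absent).
#' @return named character vector of written paths.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genes = file.path(dir, "genes.tsv"),
    hits = file.path(dir, "hits.tsv"),
    fasta = file.path(dir, "genes.fna"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_gene_table(panel$genes, paths["genes"])
  write_hits(panel$hits, paths["hits"])
  if (!is.null(panel$genes$nt_seq)) {
    write_gene_fasta(panel$genes, paths["fasta"])
  } else {
    paths <- paths[names(paths) != "fasta"]
  }
  if (!is.null(panel$phenotypes)) {
    write_phenotypes(panel$phenotypes, paths["phenotypes"])
  } else {
    paths <- paths[names(paths) != "phenotypes"]
  }
  truth <- panel$truth
  truth_json <- list(
    family_of = as.list(truth$family_of),
    class_of = as.list(truth$class_of),
    hgt_genes = truth$hgt_genes,
    causal_cluster_of = truth$causal_cluster_of,
    species_tree = ape::write.tree(truth$species_tree)
  )
  jsonlite::write_json(truth_json, paths["truth"], auto_unbox = TRUE)
  invisible(paths)
}
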