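#' Default pipeline configuration
#'
#' Returns the full parameter list for [run_pipeline()], optionally
#' overridden from a YAML file and/or a named list (list overrides file,
#' file overrides defaults). When \code{simulate} is TRUE the pipeline
#' generates its own synthetic panel; otherwise the \code{paths} entries
#' must point to existing input files.
#'
#' @param yaml optional path to a YAML configuration file.
#' @param overrides optional named list of overrides.
#' @return named list of pipeline parameters.
#' @export
pipeline_config <- function(yaml = NULL, overrides = NULL) {
  cfg <- list(
    simulate = TRUE,
    seed = 42,
    outdir = "pipeline_out",
    panel = list(),                 # panel_config() overrides
    paths = list(genes = NULL, hits = NULL, phenotypes = NULL, trees = NULL),
    max_evalue = 1e-4, min_identity = 50, min_cov_frac = 0.5,
    inflation = 1.8,
    n_permutations = 1000, exhaustive_max = 8,
    gc_high = 68, gc_low = 49, max_gap_genes = 5, min_region_genes = 5,
    od_cutoff = 0.3, cluster_mode = "exact", cut_height = 0, top_k = 3,
    n_gene_trees = 165, perturb_prob = 0.2,
    consensus_threshold = 0.5
  )
  if (!is.null(yaml)) {
    cfg <- utils::modifyList(cfg, yaml::read_yaml(yaml))
  }
  if (!is.null(overrides)) {
    cfg <- utils::modifyList(cfg, overrides)
  }
  cfg
}

log_stage <- function(...) {
  message(format(Sys.time(), "%H:%M:%S"), " [panbreve] ", ...)
}

#' Run the full comparative pan-genomics pipeline
#'
#' Executes the stage sequence simulate (optional) -> families -> pangenome
#' -> gc-scan -> traits -> consensus -> stats over a directory layout,
#' writing one subdirectory of outputs per stage plus a manifest JSON
#' listing every output file with its MD5 checksum. All randomness flows
#' from the configured seed, so re-running with an identical configuration
#' and inputs reproduces identical checksums.
#'
#' @param config list from [pipeline_config()].
#' @return invisibly, the manifest as a named list (file -> checksum); also
#'   written to \code{<outdir>/manifest.json}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  result <- tryCatch({
    ## inputs ---------------------------------------------------------------
    if (isTRUE(config$simulate)) {
      stage <- "simulate"
      log_stage("simulating synthetic panel (seed ", config$seed, ")")
      pcfg <- do.call(panel_config,
                      utils::modifyList(list(seed = config$seed),
                                        config$panel))
      panel <- simulate_panel(pcfg)
      write_panel(panel, file.path(outdir, "inputs"))
      genes <- panel$genes
      hits <- panel$hits
      pheno <- panel$phenotypes
      gene_trees <- simulate_gene_trees(panel$truth$species_tree,
                                        config$n_gene_trees,
                                        config$perturb_prob,
                                        seed = config$seed)
      write_newick(gene_trees, file.path(outdir, "inputs", "gene_trees.nwk"))
    } else {
      stage <- "read-inputs"
      for (p in c("genes", "hits")) {
        if (is.null(config$paths[[p]]) || !file.exists(config$paths[[p]])) {
          stop("missing input file for '", p, "': ",
               if (is.null(config$paths[[p]])) "(not set)" else
                 config$paths[[p]])
        }
      }
      genes <- read_gene_table(config$paths$genes)
      hits <- read_hits(config$paths$hits)
      pheno <- if (!is.null(config$paths$phenotypes))
        read_phenotypes(config$paths$phenotypes) else NULL
      gene_trees <- if (!is.null(config$paths$trees))
        read_newick(config$paths$trees) else NULL
    }
    genomes <- sort(unique(genes$genome_id))

    ## families -------------------------------------------------------------
    stage <- "families"
    log_stage("clustering ", nrow(hits), " hits into gene families")
    kept <- filter_hits(hits, config$max_evalue, config$min_identity,
                        config$min_cov_frac)
    graph <- build_graph(kept)
    clusters <- mcl_cluster(graph, inflation = config$inflation)
    fams <- classify_families(clusters, genomes, genes)
    fam_dir <- file.path(outdir, "families")
    dir.create(fam_dir, showWarnings = FALSE)
    utils::write.table(fams$members, file.path(fam_dir, "families.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(fams$summary, file.path(fam_dir, "summary.json"),
                         auto_unbox = TRUE)
    pm <- presence_matrix(fams, genomes)
    utils::write.table(data.frame(family_id = rownames(pm), pm,
                                  check.names = FALSE),
                       file.path(fam_dir, "presence_matrix.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    ## pangenome ------------------------------------------------------------
    stage <- "pangenome"
    log_stage("accumulation curves over ", ncol(pm), " genomes")
    curve <- accumulation_curves(pm, n_permutations = config$n_permutations,
                                 exhaustive_max = config$exhaustive_max,
                                 seed = config$seed)
    fit <- fit_models(curve)
    report <- curve_report(curve, fit)
    pan_dir <- file.path(outdir, "pangenome")
    dir.create(pan_dir, showWarnings = FALSE)
    utils::write.table(
      data.frame(N = seq_len(curve$n_genomes),
                 median_pan = curve$median_pan,
                 median_core = curve$median_core,
                 median_new = curve$median_new),
      file.path(pan_dir, "curves.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(pan_dir, "fit.json"),
                         auto_unbox = TRUE, digits = 10)

    ## gc-scan ----------------------------------------------------------------
    stage <- "gc-scan"
    gc_dir <- file.path(outdir, "gc_regions")
    dir.create(gc_dir, showWarnings = FALSE)
    if (!is.null(genes$nt_seq)) {
      log_stage("G+C scan over ", nrow(genes), " genes")
      profiles <- flag_deviant(genes$gene_id, gc_percent(genes$nt_seq),
                               config$gc_high, config$gc_low)
      regions <- aggregate_regions(genes, profiles, config$max_gap_genes,
                                   config$min_region_genes)
      gc_summary <- deviation_summary(fams, profiles, regions)
      utils::write.table(profiles, file.path(gc_dir, "gc_per_gene.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(regions, file.path(gc_dir, "regions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(family_deviant_fraction = gc_summary$family_deviant_fraction,
             flagged_in_region_fraction = gc_summary$flagged_in_region_fraction,
             n_flagged_genes = gc_summary$n_flagged_genes),
        file.path(gc_dir, "summary.json"), auto_unbox = TRUE, digits = 10)
    }

    ## traits ---------------------------------------------------------------
    stage <- "traits"
    tr_dir <- file.path(outdir, "traits")
    dir.create(tr_dir, showWarnings = FALSE)
    if (!is.null(pheno)) {
      log_stage("gene-trait matching over ", ncol(pheno), " phenotypes")
      gm <- binarize_growth(pheno, config$od_cutoff)
      pm_assayed <- pm[, rownames(pheno), drop = FALSE]
      cl <- cluster_patterns(pm_assayed, mode = config$cluster_mode,
                             cut_height = config$cut_height)
      mt <- match_traits(cl, gm)
      ann <- annotation_of_families(fams, genes)
      cand <- candidate_report(mt, cl, ann, k = config$top_k)
      utils::write.table(data.frame(strain = rownames(gm$growth), gm$growth,
                                    check.names = FALSE),
                         file.path(tr_dir, "growth_matrix.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(cl$clusters, file.path(tr_dir, "clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(cluster_id = rownames(mt$distance_matrix),
                   mt$distance_matrix, check.names = FALSE),
        file.path(tr_dir, "distance_matrix.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(cand, file.path(tr_dir, "candidates.json"),
                           auto_unbox = TRUE, digits = 10)
    }

    ## consensus ------------------------------------------------------------
    stage <- "consensus"
    co_dir <- file.path(outdir, "consensus")
    dir.create(co_dir, showWarnings = FALSE)
    if (!is.null(gene_trees) && length(gene_trees) > 0) {
      log_stage("majority consensus of ", length(gene_trees), " gene trees")
      cons <- majority_consensus(gene_trees, config$consensus_threshold)
      write_newick(cons$tree, file.path(co_dir, "consensus.nwk"))
      utils::write.table(cons$splits, file.path(co_dir, "splits.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    ## stats ----------------------------------------------------------------
    stage <- "stats"
    log_stage("per-genome summary statistics")
    st_dir <- file.path(outdir, "stats")
    dir.create(st_dir, showWarnings = FALSE)
    summaries <- do.call(rbind, lapply(genomes, function(g) {
      sub <- genes[genes$genome_id == g, , drop = FALSE]
      summarize_genome(sub, genome_length = max(sub$end))
    }))
    utils::write.table(summaries, file.path(st_dir, "genome_summaries.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(panel_averages(summaries),
                         file.path(st_dir, "panel_averages.json"),
                         auto_unbox = TRUE, digits = 10)

    ## manifest -------------------------------------------------------------
    stage <- "manifest"
    files <- sort(list.files(outdir, recursive = TRUE, full.names = TRUE))
    files <- files[basename(files) != "manifest.json"]
    sums <- tools::md5sum(files)
    manifest <- list(
      seed = config$seed,
      files = as.list(stats::setNames(unname(sums),
                                      sub(paste0("^", outdir, "/?"), "",
                                          files)))
    )
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE)
    manifest
  }, error = function(e) {
    # Preserve partial outputs for post-mortem under failed/.
    failed <- file.path(outdir, "failed")
    dir.create(failed, showWarnings = FALSE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  log_stage("pipeline complete: ", length(result$files), " output files")
  invisible(result)
}

# Family-level annotation: most frequent member annotation.
annotation_of_families <- function(fams, genes) {
  ann_of <- stats::setNames(genes$annotation, genes$gene_id)
  vapply(split(fams$members$gene_id, fams$members$family_id), function(g) {
    names(sort(table(ann_of[g]), decreasing = TRUE))[1]
  }, character(1))
}
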