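#' Per-sequence G+C percent
#'
#' 100 * (G + C) / (A + C + G + T), case-insensitive; N bases are excluded
#' from both numerator and denominator.
#'
#' @param seq character vector of nucleotide sequences over {A,C,G,T,N}.
#' @return numeric vector of percentages.
#' @export
gc_percent <- function(seq) {
  if (any(is.na(seq)) || any(!nzchar(seq))) stop("empty sequence")
  up <- toupper(seq)
  n_total <- nchar(up)
  n_bad <- nchar(gsub("[ACGTN]", "", up))
  if (any(n_bad > 0)) {
    stop("invalid base in sequence ", which(n_bad > 0)[1])
  }
  n_gc <- n_total - nchar(gsub("[GC]", "", up))
  n_counted <- nchar(gsub("N", "", up, fixed = TRUE))
  if (any(n_counted == 0)) stop("all-N sequence: G+C undefined")
  100 * n_gc / n_counted
}

#' Flag genes with deviant G+C content
#'
#' Strict inequalities: a gene is flagged \code{high} when its G+C exceeds
#' \code{high_threshold} and \code{low} when below \code{low_threshold};
#' boundary values are unflagged. Defaults (>68, <49) are the significance
#' thresholds used to call putative horizontally transferred ORFs against a
#' ~58% background.
#'
#' @param gene_id character vector of gene ids.
#' @param gc numeric vector of G+C percentages.
#' @param high_threshold,low_threshold flagging thresholds (low < high).
#' @return data.frame \code{gene_id, gc_percent, flag} with flag in
#'   \{none, high, low\}.
#' @export
flag_deviant <- function(gene_id, gc, high_threshold = 68.0,
                         low_threshold = 49.0) {
  if (low_threshold >= high_threshold) stop("low_threshold must be < high_threshold")
  flag <- rep("none", length(gc))
  flag[gc > high_threshold] <- "high"
  flag[gc < low_threshold] <- "low"
  data.frame(gene_id = gene_id, gc_percent = gc, flag = flag,
             stringsAsFactors = FALSE)
}

#' Aggregate flagged genes into variable genomic regions
#'
#' Scans each contig in gene order: flagged genes separated by at most
#' \code{max_gap_genes} unflagged genes join one region; regions with fewer
#' than \code{min_genes} flagged members are discarded. The region span
#' runs from the first member's start to the last member's end; unflagged
#' genes inside the span are listed as members but not counted as flagged.
#'
#' @param genes gene table sorted by (genome_id, contig_id, start).
#' @param profiles data.frame from [flag_deviant()].
#' @param max_gap_genes largest run of unflagged genes bridged by a region.
#' @param min_genes minimum flagged members per reported region.
#' @return data.frame with one row per region: \code{region_id, genome_id,
#'   contig_id, start, end, n_flagged, n_members, gene_ids}
#'   (comma-separated, ordered by start).
#' @export
aggregate_regions <- function(genes, profiles, max_gap_genes = 5,
                              min_genes = 5) {
  flag_of <- stats::setNames(profiles$flag, profiles$gene_id)
  out <- list()
  rid <- 0L
  for (key in unique(paste(genes$genome_id, genes$contig_id, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- genes[genes$genome_id == parts[1] & genes$contig_id == parts[2], ,
                 drop = FALSE]
    if (is.unsorted(sub$start)) {
      stop("genes not sorted by start within contig ", parts[2])
    }
    flagged <- which(flag_of[sub$gene_id] != "none")
    if (length(flagged) == 0) next
    # Group flagged genes whose index gap leaves <= max_gap_genes unflagged.
    brk <- c(0L, cumsum(diff(flagged) > max_gap_genes + 1L))
    for (grp in split(flagged, brk)) {
      if (length(grp) < min_genes) next
      rid <- rid + 1L
      span <- grp[1]:grp[length(grp)]
      out[[rid]] <- data.frame(
        region_id = sprintf("REG%03d", rid),
        genome_id = parts[1], contig_id = parts[2],
        start = sub$start[grp[1]], end = sub$end[grp[length(grp)]],
        n_flagged = length(grp), n_members = length(span),
        gene_ids = paste(sub$gene_id[span], collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  if (rid == 0L) {
    return(data.frame(region_id = character(), genome_id = character(),
                      contig_id = character(), start = integer(),
                      end = integer(), n_flagged = integer(),
                      n_members = integer(), gene_ids = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Panel-level G+C deviation summary
#'
#' Reports the fraction of gene families containing at least one flagged
#' gene, the fraction of flagged genes lying inside variable regions, and
#' a per-genome region table.
#'
#' @param fams result of [classify_families()].
#' @param profiles data.frame from [flag_deviant()].
#' @param regions data.frame from [aggregate_regions()].
#' @return list with \code{family_deviant_fraction},
#'   \code{flagged_in_region_fraction}, \code{n_flagged_genes},
#'   \code{regions_per_genome}.
#' @export
deviation_summary <- function(fams, profiles, regions) {
  flagged <- profiles$gene_id[profiles$flag != "none"]
  fam_of <- stats::setNames(fams$members$family_id, fams$members$gene_id)
  deviant_fams <- unique(fam_of[flagged])
  deviant_fams <- deviant_fams[!is.na(deviant_fams)]
  region_genes <- unlist(strsplit(regions$gene_ids, ",", fixed = TRUE),
                         use.names = FALSE)
  list(
    family_deviant_fraction =
      length(deviant_fams) / nrow(fams$families),
    flagged_in_region_fraction =
      if (length(flagged) == 0) 0 else mean(flagged %in% region_genes),
    n_flagged_genes = length(flagged),
    regions_per_genome = table(factor(regions$genome_id))
  )
}
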