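# Round half away from zero at integer precision; matches the convention of
# printed per-panel average values (e.g. 1816.625 -> 1817).
round_half_up <- function(x) floor(x + 0.5)

#' Summarize one genome's general features
#'
#' Tallies gene counts, tRNA and mobilome annotations, hypothetical-protein
#' fraction, and start-codon usage. Start codons are the first three
#' nucleotides of each coding-strand-oriented gene sequence.
#'
#' @param genes gene table rows for a single genome.
#' @param genome_length genome length in bp; must be at least the largest
#'   gene end coordinate.
#' @return one-row data.frame with columns \code{genome_id,
#'   genome_length_bp, n_genes, n_trna, n_is_elements, pct_hypothetical,
#'   pct_assigned} and start-codon percentage columns
#'   \code{pct_start_ATG/GTG/TTG/CTG/other}.
#' @export
summarize_genome <- function(genes, genome_length) {
  gid <- unique(genes$genome_id)
  if (length(gid) != 1) stop("genes must all come from one genome")
  if (genome_length < max(genes$end)) {
    stop("genome_length is smaller than the largest gene end coordinate")
  }
  hyp <- grepl("hypothetical", genes$annotation, ignore.case = TRUE)
  pct_hyp <- 100 * mean(hyp)
  codon_pct <- c(ATG = NA_real_, GTG = NA_real_, TTG = NA_real_,
                 CTG = NA_real_, other = NA_real_)
  if (!is.null(genes$nt_seq)) {
    starts <- toupper(substr(genes$nt_seq, 1, 3))
    starts[!starts %in% c("ATG", "GTG", "TTG", "CTG")] <- "other"
    tab <- table(factor(starts, levels = names(codon_pct)))
    codon_pct[] <- 100 * as.numeric(tab) / length(starts)
  }
  out <- data.frame(
    genome_id = gid,
    genome_length_bp = genome_length,
    n_genes = nrow(genes),
    n_trna = sum(grepl("tRNA", genes$annotation, ignore.case = TRUE)),
    n_is_elements = sum(genes$is_mobile),
    pct_hypothetical = pct_hyp,
    pct_assigned = 100 - pct_hyp,
    stringsAsFactors = FALSE
  )
  for (cn in names(codon_pct)) out[[paste0("pct_start_", cn)]] <- codon_pct[[cn]]
  out
}

#' Panel-average genome features
#'
#' Arithmetic means of the per-genome feature values, rounded half-up at
#' integer precision (lengths and counts to whole units, percentages to
#' whole percent), the convention of printed "average value" columns.
#'
#' @param summaries data.frame of per-genome rows (as from
#'   [summarize_genome()], row-bound), requiring columns
#'   \code{genome_length_bp, n_genes, n_trna, n_is_elements,
#'   pct_hypothetical, pct_assigned}.
#' @return list of rounded panel means.
#' @export
panel_averages <- function(summaries) {
  if (nrow(summaries) == 0) stop("no genome summaries supplied")
  list(
    mean_genome_length_bp = round_half_up(mean(summaries$genome_length_bp)),
    mean_n_genes = round_half_up(mean(summaries$n_genes)),
    mean_n_trna = round_half_up(mean(summaries$n_trna)),
    mean_n_is = round_half_up(mean(summaries$n_is_elements)),
    mean_pct_hypothetical = round_half_up(mean(summaries$pct_hypothetical)),
    mean_pct_assigned = round_half_up(mean(summaries$pct_assigned))
  )
}

#' Span of a reported coordinate interval
#'
#' For genomic intervals reported as coordinate pairs (e.g. inversions),
#' the span is \code{end - start} bp and the Kb figure is the span
#' integer-divided by 1000 (truncation, not rounding) - the convention
#' under which coordinates 1,181,452-1,350,961 print as 169 Kb. Note this
#' differs from the inclusive gene-length convention
#' (\code{end - start + 1}) used for ORF coordinates.
#'
#' @param start,end 1-based coordinates, end >= start.
#' @return list with \code{bp_length} and \code{kb_floor}.
#' @export
interval_length <- function(start, end) {
  if (any(end < start)) stop("end must be >= start")
  bp <- end - start
  list(bp_length = bp, kb_floor = bp %/% 1000)
}

#' Reference panel features of the eight complete B. breve genomes
#'
#' Returns the published general-feature values (genome length, gene,
#' tRNA and IS-element counts, hypothetical/assigned percentages) for the
#' eight completely sequenced B. breve genomes, as bundled in
#' \code{extdata/breve_panel_features.tsv}. These are inputs for
#' panel-average computations, not values computed by this package.
#'
#' @return data.frame with one row per genome.
#' @export
breve_panel_features <- function() {
  path <- system.file("extdata", "breve_panel_features.tsv",
                      package = "panbreve", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
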