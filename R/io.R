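# Default mobilome keywords: annotation substrings (case-insensitive) that mark
# a gene as part of the mobile element complement.
MOBILOME_KEYWORDS <- c("transposase", "IS element", "insertion sequence",
                       "integrase", "phage", "mobile element")

GENE_TABLE_COLS <- c("genome_id", "gene_id", "contig_id", "start", "end",
                     "strand", "annotation")

#' Flag mobilome genes from annotation text
#'
#' A gene is considered part of the mobilome when its annotation contains any
#' of the keywords as a case-insensitive substring.
#'
#' @param annotation character vector of product annotations.
#' @param keywords character vector of mobilome keywords.
#' @return logical vector.
#' @export
is_mobilome <- function(annotation, keywords = MOBILOME_KEYWORDS) {
  hit <- rep(FALSE, length(annotation))
  ann <- tolower(annotation)
  for (kw in tolower(keywords)) {
    hit <- hit | grepl(kw, ann, fixed = TRUE)
  }
  hit
}

#' Read a per-strain gene table
#'
#' Reads a TSV of ORF records (one row per gene) with header columns
#' \code{genome_id, gene_id, contig_id, start, end, strand, annotation}.
#' Coordinates are 1-based fully inclusive; gene length is
#' \code{end - start + 1}. Rows are returned sorted by
#' (genome_id, contig_id, start), and an \code{is_mobile} column is added by
#' keyword matching on the annotation.
#'
#' @param path path to the TSV file.
#' @param mobilome_keywords keywords passed to [is_mobilome()].
#' @return data.frame of gene records.
#' @export
read_gene_table <- function(path, mobilome_keywords = MOBILOME_KEYWORDS) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          check.names = FALSE)
  missing <- setdiff(GENE_TABLE_COLS, names(df))
  if (length(missing) > 0) {
    stop("gene table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[, GENE_TABLE_COLS, drop = FALSE]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  validate_gene_table(df)
  df$is_mobile <- is_mobilome(df$annotation, mobilome_keywords)
  df <- df[order(df$genome_id, df$contig_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

validate_gene_table <- function(df) {
  if (any(is.na(df$start)) || any(is.na(df$end))) {
    stop("non-numeric start/end coordinate in gene table")
  }
  bad <- which(df$end < df$start)
  if (length(bad) > 0) {
    stop("end < start at row ", bad[1], " (gene ", df$gene_id[bad[1]], ")")
  }
  if (any(df$start < 1)) stop("start coordinates must be >= 1")
  if (!all(df$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup) > 0) {
    stop("duplicate gene_id: ", dup[1])
  }
  invisible(df)
}

#' Write a gene table TSV
#' @param df gene table data.frame.
#' @param path output path.
#' @export
write_gene_table <- function(df, path) {
  out <- df[, GENE_TABLE_COLS, drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore",
              "qlen", "slen")

#' Read extended BLAST tabular hits
#'
#' Parses the 14-column "std qlen slen" tabular dialect (the standard
#' 12 columns plus query and subject lengths); the coverage filter needs both
#' sequence lengths, which the 12-column format lacks. Self-hits
#' (query == subject) are dropped.
#'
#' @param path path to the headerless tabular file.
#' @return data.frame with columns \code{query_id, subject_id, pct_identity,
#'   aln_length, e_value, q_len, s_len}.
#' @export
read_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(empty_hits())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 14L)
  if (length(bad) > 0) {
    stop("hit row ", bad[1], " has ", nf[bad[1]],
         " columns; expected 14 (std qlen slen)")
  }
  m <- matrix(unlist(fields), ncol = 14L, byrow = TRUE)
  pident <- suppressWarnings(as.numeric(m[, 3]))
  evalue <- suppressWarnings(as.numeric(m[, 11]))
  if (any(is.na(pident)) || any(is.na(evalue))) {
    bad <- which(is.na(pident) | is.na(evalue))[1]
    stop("non-numeric pident/evalue at hit row ", bad)
  }
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = pident,
    aln_length = as.integer(m[, 4]),
    e_value = evalue,
    q_len = as.integer(m[, 13]),
    s_len = as.integer(m[, 14]),
    stringsAsFactors = FALSE
  )
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  rownames(hits) <- NULL
  validate_hits(hits)
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pct_identity = numeric(), aln_length = integer(),
             e_value = numeric(), q_len = integer(), s_len = integer(),
             stringsAsFactors = FALSE)
}

validate_hits <- function(hits) {
  if (any(hits$aln_length < 1) || any(hits$q_len < 1) || any(hits$s_len < 1)) {
    stop("alignment and sequence lengths must be >= 1")
  }
  if (any(hits$e_value < 0)) stop("e_value must be non-negative")
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100)) {
    stop("pct_identity must lie in [0, 100]")
  }
  invisible(hits)
}

#' Write hits in 14-column extended BLAST tabular form
#'
#' Columns not represented in memory (mismatch, gapopen, coordinates,
#' bitscore) are emitted as placeholder values consistent with the alignment
#' length.
#'
#' @param hits hits data.frame as from [read_hits()].
#' @param path output path.
#' @export
write_hits <- function(hits, path) {
  n <- nrow(hits)
  m <- cbind(hits$query_id, hits$subject_id,
             format_num(hits$pct_identity), hits$aln_length,
             rep(0L, n), rep(0L, n),
             rep(1L, n), hits$aln_length, rep(1L, n), hits$aln_length,
             format_num(hits$e_value), rep(0L, n),
             hits$q_len, hits$s_len)
  writeLines(apply(m, 1, paste, collapse = "\t"), path)
  invisible(path)
}

format_num <- function(x) {
  formatC(x, format = "g", digits = 6)
}

#' Read a strains-by-carbohydrates phenotype table
#'
#' CSV with first column \code{strain} and one column per carbohydrate;
#' cells are final 24-h OD600 readings.
#'
#' @param path path to the CSV.
#' @return numeric matrix (strains in rows, carbohydrates in columns).
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (names(df)[1] != "strain") {
    stop("phenotype CSV must have 'strain' as its first column")
  }
  strains <- as.character(df[[1]])
  if (anyDuplicated(strains)) {
    stop("duplicate strain: ", strains[duplicated(strains)][1])
  }
  od <- as.matrix(df[, -1, drop = FALSE])
  mode(od) <- "numeric"
  if (any(is.na(od))) stop("non-numeric OD value in phenotype table")
  if (any(od < 0)) stop("negative OD value in phenotype table")
  rownames(od) <- strains
  od
}

#' Write a phenotype table CSV
#' @param od numeric matrix with strain rownames and carbohydrate colnames.
#' @param path output path.
#' @export
write_phenotypes <- function(od, path) {
  df <- data.frame(strain = rownames(od), od, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read one or more Newick trees
#'
#' Accepts one tree per line or several semicolon-terminated trees per line.
#' Trees are interpreted as unrooted for bipartition purposes downstream.
#'
#' @param path path to the Newick file.
#' @return list of \code{phylo} objects (a \code{multiPhylo}-like list).
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path), collapse = "\n")
  check_newick_balance(txt)
  trees <- ape::read.tree(text = txt)
  if (is.null(trees)) stop("could not parse any Newick tree from ", path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  for (i in seq_along(trees)) {
    labs <- trees[[i]]$tip.label
    if (anyDuplicated(labs)) {
      stop("duplicate leaf label '", labs[duplicated(labs)][1],
           "' in tree ", i)
    }
  }
  trees
}

check_newick_balance <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop("unbalanced parentheses at position ", i)
    if (chars[i] == ";" && depth != 0L) {
      stop("unbalanced parentheses before position ", i)
    }
  }
  if (depth != 0L) stop("unbalanced parentheses at end of input")
  invisible(TRUE)
}

#' Write trees to a Newick file
#' @param trees list of \code{phylo} objects.
#' @param path output path.
#' @export
write_newick <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  lines <- vapply(trees, function(t) ape::write.tree(t), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write gene nucleotide sequences as FASTA
#' @param gene_table gene table with a \code{nt_seq} column.
#' @param path output path.
#' @export
write_gene_fasta <- function(gene_table, path) {
  if (is.null(gene_table$nt_seq)) stop("gene table has no nt_seq column")
  lines <- character(2L * nrow(gene_table))
  lines[c(TRUE, FALSE)] <- paste0(">", gene_table$gene_id)
  lines[c(FALSE, TRUE)] <- gene_table$nt_seq
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sequences from FASTA
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_gene_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA records in ", path)
  ids <- sub("^>", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  names(seqs) <- ids[as.integer(names(seqs))]
  seqs[ids]
}
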