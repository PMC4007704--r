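#' Filter similarity hits at the comparative-genomics cut-offs
#'
#' Keeps a hit iff its E-value is at most \code{max_evalue}, its percent
#' identity is at least \code{min_identity}, and the alignment covers at
#' least \code{min_cov_frac} of either protein, i.e.
#' \code{aln_length >= min_cov_frac * min(q_len, s_len)}. Defaults are the
#' standard all-vs-all BLASTP cut-offs for family building: E 1e-4, 50%
#' identity over 50% of either sequence.
#'
#' @param hits hits data.frame (see [read_hits()]).
#' @param max_evalue E-value ceiling.
#' @param min_identity percent-identity floor.
#' @param min_cov_frac minimum covered fraction of the shorter protein.
#' @return filtered hits data.frame.
#' @export
filter_hits <- function(hits, max_evalue = 1e-4, min_identity = 50.0,
                        min_cov_frac = 0.5) {
  keep <- hits$e_value <= max_evalue &
    hits$pct_identity >= min_identity &
    hits$aln_length >= min_cov_frac * pmin(hits$q_len, hits$s_len)
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the bidirectional similarity graph
#'
#' An undirected edge (a, b) exists iff a passing hit a->b AND a passing hit
#' b->a both exist. The edge weight is \code{min(200, -log10(E_best))} where
#' \code{E_best} is the smaller of the two directions' E-values; E = 0 maps
#' to the 200 cap.
#'
#' @param filtered hits that already passed [filter_hits()].
#' @return list with \code{nodes} (character) and \code{edges} (data.frame
#'   \code{from, to, weight}).
#' @export
build_graph <- function(filtered) {
  nodes <- sort(unique(c(filtered$query_id, filtered$subject_id)))
  if (nrow(filtered) == 0) {
    return(list(nodes = nodes,
                edges = data.frame(from = character(), to = character(),
                                   weight = numeric(),
                                   stringsAsFactors = FALSE)))
  }
  a <- pmin(filtered$query_id, filtered$subject_id)
  b <- pmax(filtered$query_id, filtered$subject_id)
  key <- paste(a, b, sep = "\r")
  fwd <- filtered$query_id == a
  # An unordered pair is an edge only when both directions are present.
  has_fwd <- tapply(fwd, key, any)
  has_rev <- tapply(!fwd, key, any)
  best_e <- tapply(filtered$e_value, key, min)
  both <- has_fwd & has_rev
  keys <- names(best_e)[both]
  parts <- strsplit(keys, "\r", fixed = TRUE)
  w <- pmin(200, -log10(best_e[both]))
  w[!is.finite(w)] <- 200
  edges <- data.frame(
    from = vapply(parts, `[`, character(1), 1L),
    to = vapply(parts, `[`, character(1), 2L),
    weight = as.numeric(w),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

#' Markov clustering of the similarity graph
#'
#' Implements MCL on the weighted adjacency matrix: self-loops are added
#' (weight = each node's maximum incident edge weight; 1 for isolated
#' nodes), columns are normalized to a stochastic matrix, then expansion
#' (matrix squaring) alternates with inflation (entrywise power and column
#' renormalization) and pruning of entries below \code{prune} until the
#' largest absolute entry change falls below \code{tol} or \code{max_iter}
#' iterations elapse. Clusters are the connected components of the non-zero
#' pattern of the limit matrix; isolated nodes become singletons.
#'
#' @param graph result of [build_graph()].
#' @param inflation inflation exponent (granularity; > 1).
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the maximum entry change.
#' @param prune entries below this value are zeroed each iteration.
#' @return list of character vectors, one per cluster, each sorted;
#'   clusters ordered by their lexicographically smallest member.
#' @export
mcl_cluster <- function(graph, inflation = 1.8, max_iter = 100, tol = 1e-6,
                        prune = 1e-8) {
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0) return(list())
  edges <- graph$edges
  i <- match(edges$from, nodes)
  j <- match(edges$to, nodes)
  # Symmetric adjacency with self-loops at each node's max incident weight.
  loop <- rep(1, n)
  if (nrow(edges) > 0) {
    mx <- tapply(c(edges$weight, edges$weight), c(i, j), max)
    loop[as.integer(names(mx))] <- mx
  }
  M <- Matrix::sparseMatrix(
    i = c(i, j, seq_len(n)), j = c(j, i, seq_len(n)),
    x = c(edges$weight, edges$weight, loop), dims = c(n, n)
  )
  M <- normalize_cols(M)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    M_new <- M %*% M                       # expansion
    M_new@x <- M_new@x^inflation           # inflation
    M_new <- normalize_cols(M_new)
    M_new@x[M_new@x < prune] <- 0          # pruning
    M_new <- Matrix::drop0(M_new)
    M_new <- normalize_cols(M_new)
    delta <- max(abs(M_new - M))
    M <- M_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge within ", max_iter,
            " iterations; returning the current partition")
  }
  # Clusters = connected components of the non-zero pattern.
  Tm <- as(Matrix::drop0(M), "TsparseMatrix")
  g <- igraph::graph_from_data_frame(
    data.frame(from = nodes[Tm@i + 1L], to = nodes[Tm@j + 1L]),
    directed = FALSE, vertices = nodes
  )
  comp <- igraph::components(g)$membership
  clusters <- split(names(comp), comp)
  clusters <- lapply(clusters, function(x) sort(unname(x)))
  clusters <- unname(clusters)
  clusters[order(vapply(clusters, `[`, character(1), 1L))]
}

normalize_cols <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(x = 1 / cs)
}

#' Classify gene families as core, dispensable or unique
#'
#' Families present in every genome of the panel are core; in a strict
#' subset of >= 2 genomes, dispensable; in exactly one genome, unique.
#' Genes absent from every cluster become singleton (unique-class)
#' families. A core family is a single-copy orthologue when every genome
#' holds exactly one copy and no member belongs to the mobilome; mobilome
#' exclusion applies only to the orthologue pool, not to the class counts.
#'
#' @param clusters list of gene_id vectors (one per cluster), e.g. from
#'   [mcl_cluster()].
#' @param genomes character vector of all panel genome_ids.
#' @param gene_index gene table indexed by \code{gene_id} (columns
#'   \code{gene_id, genome_id, is_mobile} required).
#' @return list with \code{families} (one row per family: family_id, size,
#'   n_genomes, family_class, contains_mobile, is_single_copy_orthologue),
#'   \code{members} (family_id, gene_id, genome_id, family_class,
#'   is_single_copy_orthologue), and \code{summary} (class and orthologue
#'   counts).
#' @export
classify_families <- function(clusters, genomes, gene_index) {
  unknown <- setdiff(unlist(clusters, use.names = FALSE), gene_index$gene_id)
  if (length(unknown) > 0) {
    stop("cluster references unknown gene_id: ", unknown[1])
  }
  leftover <- setdiff(gene_index$gene_id, unlist(clusters, use.names = FALSE))
  clusters <- c(clusters, as.list(leftover))
  genome_of <- stats::setNames(gene_index$genome_id, gene_index$gene_id)
  mobile_of <- stats::setNames(gene_index$is_mobile, gene_index$gene_id)
  n_panel <- length(genomes)

  fam_ids <- sprintf("FAM%05d", seq_along(clusters))
  rows <- lapply(seq_along(clusters), function(k) {
    members <- clusters[[k]]
    gms <- genome_of[members]
    ng <- length(unique(gms))
    cls <- if (ng == n_panel) "core" else if (ng == 1L) "unique" else "dispensable"
    mob <- any(mobile_of[members])
    single <- cls == "core" && !mob && all(table(gms) == 1L)
    data.frame(family_id = fam_ids[k], size = length(members),
               n_genomes = ng, family_class = cls, contains_mobile = mob,
               is_single_copy_orthologue = single, stringsAsFactors = FALSE)
  })
  families <- do.call(rbind, rows)
  members <- data.frame(
    family_id = rep(fam_ids, lengths(clusters)),
    gene_id = unlist(clusters, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  members$genome_id <- unname(genome_of[members$gene_id])
  members$family_class <- families$family_class[match(members$family_id,
                                                      families$family_id)]
  members$is_single_copy_orthologue <-
    families$is_single_copy_orthologue[match(members$family_id,
                                             families$family_id)]
  n_core <- sum(families$family_class == "core")
  n_orth <- sum(families$is_single_copy_orthologue)
  summary <- list(
    n_families = nrow(families),
    n_core = n_core,
    n_dispensable = sum(families$family_class == "dispensable"),
    n_unique = sum(families$family_class == "unique"),
    n_orthologues = n_orth,
    n_core_paralogues = sum(families$family_class == "core" &
                              !families$is_single_copy_orthologue &
                              !families$contains_mobile),
    n_core_mobile = sum(families$family_class == "core" &
                          families$contains_mobile)
  )
  list(families = families, members = members, summary = summary)
}

#' Family-by-genome copy-count matrix
#'
#' @param fams result of [classify_families()].
#' @param genomes panel genome_ids (column order).
#' @return integer matrix, families in rows, genomes in columns, entries =
#'   copy counts.
#' @export
presence_matrix <- function(fams, genomes) {
  tab <- table(factor(fams$members$family_id,
                      levels = fams$families$family_id),
               factor(fams$members$genome_id, levels = genomes))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}

#' Adjusted Rand index between two partitions
#'
#' Used to score cluster recovery against a known ground truth.
#'
#' @param labels_a,labels_b named or aligned label vectors over the same
#'   elements (names are used for alignment when present).
#' @return ARI in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    common <- intersect(names(labels_a), names(labels_b))
    labels_a <- labels_a[common]
    labels_b <- labels_b[common]
  }
  stopifnot(length(labels_a) == length(labels_b))
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
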