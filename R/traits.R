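#' Binarize growth phenotypes at the OD cut-off
#'
#' Growth = 1 iff the final OD600 reading is at least \code{cutoff}
#' (boundary inclusive). The default 0.3 is the lower-limit OD used to
#' discriminate carbohydrates that did or did not support growth.
#'
#' @param od numeric OD matrix (strains x carbohydrates).
#' @param cutoff OD threshold.
#' @return list with \code{growth} (binary matrix) and \code{cutoff}.
#' @export
binarize_growth <- function(od, cutoff = 0.3) {
  if (any(od < 0)) stop("OD values must be non-negative")
  growth <- (od >= cutoff) * 1L
  mode(growth) <- "integer"
  list(growth = growth, cutoff = cutoff)
}

#' Group gene families into presence/absence clusters
#'
#' Copy counts are binarized (>= 1 present), families whose pattern is
#' constant across the assayed strains (all-present core, all-absent) are
#' set aside, and the remaining families are grouped. \code{mode = "exact"}
#' groups families with identical patterns; \code{mode = "hcl"}
#' additionally merges patterns by average-linkage agglomeration on Hamming
#' distance, cut at \code{cut_height} (0 reproduces exact grouping), with
#' each merged cluster's pattern taken as the majority consensus (ties to
#' present). Clusters are numbered Cluster1..ClusterK in order of first
#' family appearance.
#'
#' @param m copy-count matrix (families x genomes) restricted to the
#'   assayed strains.
#' @param mode "exact" or "hcl".
#' @param cut_height dendrogram cut height for hcl mode (Hamming units).
#' @return list with \code{clusters} (data.frame \code{cluster_id,
#'   family_id}), \code{patterns} (binary matrix, clusters x strains),
#'   \code{constant_families} (set-aside family_ids).
#' @export
cluster_patterns <- function(m, mode = c("exact", "hcl"), cut_height = 0) {
  mode <- match.arg(mode)
  if (ncol(m) < 2) stop("need at least 2 assayed strains")
  pres <- (m >= 1) * 1L
  sums <- rowSums(pres)
  constant <- sums == 0 | sums == ncol(pres)
  const_fams <- rownames(pres)[constant]
  pres <- pres[!constant, , drop = FALSE]
  if (nrow(pres) == 0) {
    return(list(clusters = data.frame(cluster_id = character(),
                                      family_id = character(),
                                      stringsAsFactors = FALSE),
                patterns = matrix(0L, 0, ncol(m),
                                  dimnames = list(NULL, colnames(m))),
                constant_families = const_fams))
  }
  key <- apply(pres, 1, paste, collapse = "")
  if (mode == "exact" || cut_height <= 0) {
    grp <- match(key, unique(key))
  } else {
    ukey <- unique(key)
    upat <- pres[match(ukey, key), , drop = FALSE]
    if (length(ukey) == 1) {
      ugrp <- 1L
    } else {
      hc <- stats::hclust(stats::dist(upat, method = "manhattan"),
                          method = "average")
      ugrp <- stats::cutree(hc, h = cut_height)
    }
    grp <- ugrp[match(key, ukey)]
  }
  # Number clusters in order of first family appearance.
  first <- match(unique(grp), grp)
  renum <- match(grp, grp[sort(first)])
  ids <- sprintf("Cluster%d", renum)
  patterns <- matrix(0L, length(unique(renum)), ncol(pres),
                     dimnames = list(sprintf("Cluster%d",
                                             seq_along(unique(renum))),
                                     colnames(pres)))
  for (k in seq_len(nrow(patterns))) {
    block <- pres[renum == k, , drop = FALSE]
    # Majority consensus; ties resolve to present.
    patterns[k, ] <- as.integer(colMeans(block) >= 0.5)
  }
  list(clusters = data.frame(cluster_id = ids, family_id = rownames(pres),
                             stringsAsFactors = FALSE),
       patterns = patterns,
       constant_families = const_fams)
}

#' Match presence/absence clusters against growth phenotypes
#'
#' For every (cluster, carbohydrate) pair the matching distance is the
#' Hamming distance between the cluster's presence pattern and the
#' carbohydrate's binary growth column. Carbohydrates with constant growth
#' across strains are unmatchable and reported separately. Per carbohydrate
#' the clusters are ranked ascending by distance (ties share the lower
#' rank, ordered deterministically by cluster_id); the anti-match distance
#' (n_strains - d) is reported as its own column and never ranked.
#'
#' @param cl result of [cluster_patterns()].
#' @param gm result of [binarize_growth()].
#' @return list with \code{matches} (data.frame \code{cluster_id,
#'   carbohydrate, distance, anti_distance, rank}), \code{distance_matrix}
#'   (clusters x carbohydrates), \code{unmatchable} (constant-growth
#'   carbohydrates).
#' @export
match_traits <- function(cl, gm) {
  growth <- gm$growth
  if (!identical(colnames(cl$patterns), rownames(growth))) {
    stop("strain lists of clusters and growth matrix differ")
  }
  csums <- colSums(growth)
  unmatchable <- colnames(growth)[csums == 0 | csums == nrow(growth)]
  usable <- setdiff(colnames(growth), unmatchable)
  pat <- cl$patterns
  n_strains <- ncol(pat)
  dm <- matrix(NA_integer_, nrow(pat), length(usable),
               dimnames = list(rownames(pat), usable))
  for (s in usable) {
    dm[, s] <- as.integer(rowSums(abs(sweep(pat, 2, growth[, s]))))
  }
  rows <- list()
  for (s in usable) {
    d <- dm[, s]
    ord <- order(d, cluster_number(rownames(dm)))
    rk <- rank(d, ties.method = "min")
    rows[[s]] <- data.frame(
      cluster_id = rownames(dm)[ord],
      carbohydrate = s,
      distance = unname(d[ord]),
      anti_distance = n_strains - unname(d[ord]),
      rank = unname(rk[ord]),
      stringsAsFactors = FALSE
    )
  }
  matches <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(cluster_id = character(), carbohydrate = character(),
               distance = integer(), anti_distance = integer(),
               rank = integer(), stringsAsFactors = FALSE)
  rownames(matches) <- NULL
  list(matches = matches, distance_matrix = dm, unmatchable = unmatchable)
}

cluster_number <- function(ids) {
  as.integer(sub("^Cluster", "", ids))
}

#' Ranked candidate clusters per carbohydrate
#'
#' For each matchable carbohydrate, reports the top-k clusters by matching
#' distance together with their member families and (when provided) the
#' member gene annotations, mirroring a gene-trait matching table.
#'
#' @param mt result of [match_traits()].
#' @param cl result of [cluster_patterns()].
#' @param annotations optional named character vector mapping family_id to
#'   an annotation string.
#' @param k number of top clusters per carbohydrate.
#' @return list keyed by carbohydrate; each element a data.frame
#'   \code{cluster_id, distance, rank, families, annotations}.
#' @export
candidate_report <- function(mt, cl, annotations = NULL, k = 3) {
  fams_of <- split(cl$clusters$family_id, cl$clusters$cluster_id)
  out <- list()
  for (s in unique(mt$matches$carbohydrate)) {
    sub <- mt$matches[mt$matches$carbohydrate == s, , drop = FALSE]
    sub <- sub[seq_len(min(k, nrow(sub))), , drop = FALSE]
    fams <- vapply(sub$cluster_id,
                   function(cid) paste(fams_of[[cid]], collapse = ","),
                   character(1))
    ann <- if (is.null(annotations)) NA_character_ else
      vapply(sub$cluster_id, function(cid) {
        paste(unique(stats::na.omit(annotations[fams_of[[cid]]])),
              collapse = "; ")
      }, character(1))
    out[[s]] <- data.frame(
      cluster_id = sub$cluster_id, distance = sub$distance, rank = sub$rank,
      families = unname(fams), annotations = unname(ann),
      stringsAsFactors = FALSE
    )
  }
  out
}
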