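test_that("G+C percent counts only unambiguous bases", {
  expect_equal(gc_percent("GGCC"), 100)
  expect_equal(gc_percent("ATGC"), 50)
  expect_equal(gc_percent("ATGNC"), 50)     # N excluded from both sides
  expect_equal(gc_percent("atgc"), 50)      # case-insensitive
  expect_error(gc_percent(""), "empty")
  expect_error(gc_percent("NNN"), "all-N")
  expect_error(gc_percent("ATGX"), "invalid base")
})

test_that("G+C of a concatenation is the counted-base-weighted mean", {
  set.seed(12)
  for (i in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T", "N"), 40, replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
               collapse = "")
    na <- nchar(gsub("N", "", a)); nb <- nchar(gsub("N", "", b))
    expect_equal(gc_percent(paste0(a, b)),
                 (gc_percent(a) * na + gc_percent(b) * nb) / (na + nb))
  }
})

test_that("deviance flags use strict thresholds", {
  prof <- flag_deviant(c("g1", "g2", "g3", "g4", "g5"),
                       c(72, 68, 40, 49, 58))
  expect_equal(prof$flag, c("high", "none", "low", "none", "none"))
  expect_error(flag_deviant("g", 50, high_threshold = 40, low_threshold = 49),
               "low_threshold")
})

region_fixture <- function(flags) {
  n <- length(flags)
  genes <- data.frame(
    genome_id = "gA", contig_id = "c1",
    gene_id = sprintf("g%03d", seq_len(n)),
    start = seq(1, by = 1000, length.out = n),
    end = seq(900, by = 1000, length.out = n),
    stringsAsFactors = FALSE
  )
  prof <- data.frame(gene_id = genes$gene_id,
                     gc_percent = ifelse(flags, 72, 58),
                     flag = ifelse(flags, "high", "none"),
                     stringsAsFactors = FALSE)
  list(genes = genes, prof = prof)
}

test_that("flagged genes aggregate into regions under the gap rule", {
  # 10 consecutive flagged genes -> one region
  fx <- region_fixture(rep(TRUE, 10))
  reg <- aggregate_regions(fx$genes, fx$prof)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$n_flagged, 10)
  expect_equal(reg$start, fx$genes$start[1])
  expect_equal(reg$end, fx$genes$end[10])

  # runs of 6 and 6 separated by 20 unflagged genes -> two regions
  fx <- region_fixture(c(rep(TRUE, 6), rep(FALSE, 20), rep(TRUE, 6)))
  reg <- aggregate_regions(fx$genes, fx$prof, max_gap_genes = 5)
  expect_equal(nrow(reg), 2)
  expect_equal(reg$n_flagged, c(6, 6))

  # a gap of exactly max_gap_genes joins; one more splits
  fx <- region_fixture(c(rep(TRUE, 5), rep(FALSE, 5), rep(TRUE, 5)))
  expect_equal(nrow(aggregate_regions(fx$genes, fx$prof, max_gap_genes = 5)), 1)
  expect_equal(nrow(aggregate_regions(fx$genes, fx$prof, max_gap_genes = 4)), 2)

  # below min_genes nothing is reported
  fx <- region_fixture(c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(nrow(aggregate_regions(fx$genes, fx$prof, min_genes = 5)), 0)

  # unsorted input is an integrity error
  fx <- region_fixture(rep(TRUE, 6))
  expect_error(aggregate_regions(fx$genes[6:1, ], fx$prof), "sorted")
})

test_that("raising min_genes never increases the region count", {
  set.seed(77)
  flags <- runif(200) < 0.3
  fx <- region_fixture(flags)
  counts <- vapply(1:8, function(mg)
    nrow(aggregate_regions(fx$genes, fx$prof, min_genes = mg)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("regions are disjoint and flagged genes belong to at most one", {
  set.seed(5)
  flags <- runif(300) < 0.4
  fx <- region_fixture(flags)
  reg <- aggregate_regions(fx$genes, fx$prof, max_gap_genes = 3, min_genes = 3)
  if (nrow(reg) > 1) {
    expect_true(all(reg$start[-1] > reg$end[-nrow(reg)]))
  }
  members <- unlist(strsplit(reg$gene_ids, ","))
  expect_false(any(duplicated(members)))
})

test_that("synthetic HGT blocks are each recovered as exactly one region", {
  panel <- small_panel(seed = 41)
  genomes <- sort(unique(panel$genes$genome_id))
  prof <- flag_deviant(panel$genes$gene_id, gc_percent(panel$genes$nt_seq))
  reg <- aggregate_regions(panel$genes, prof)
  # 2 blocks per genome, 4 genomes
  expect_equal(nrow(reg), 2 * length(genomes))
  expect_equal(as.integer(table(reg$genome_id)), rep(2L, length(genomes)))
  # every truth HGT gene flagged, and all flagged genes lie in regions
  cl <- mcl_cluster(build_graph(filter_hits(panel$hits)))
  fams <- classify_families(cl, genomes, panel$genes)
  ds <- deviation_summary(fams, prof, reg)
  expect_equal(ds$flagged_in_region_fraction, 1.0)
  # block size 6 >= min_genes 5; a short gene can miss the threshold by
  # sampling noise but each block must still surface as one region
  expect_true(all(reg$n_flagged >= 5))
})

test_that("the deviant-family fraction recovers the generator setting", {
  # 2 blocks x 6 families out of 60 + ~20 + 12 families: expected ~ 12 / 89
  panel <- small_panel(seed = 43)
  genomes <- sort(unique(panel$genes$genome_id))
  prof <- flag_deviant(panel$genes$gene_id, gc_percent(panel$genes$nt_seq))
  reg <- aggregate_regions(panel$genes, prof)
  cl <- mcl_cluster(build_graph(filter_hits(panel$hits)))
  fams <- classify_families(cl, genomes, panel$genes)
  ds <- deviation_summary(fams, prof, reg)
  expected <- 12 / length(panel$truth$class_of)
  expect_equal(ds$family_deviant_fraction, expected, tolerance = 0.02 / expected)
})

test_that("no flagged genes give empty regions and zero fractions", {
  fx <- region_fixture(rep(FALSE, 10))
  reg <- aggregate_regions(fx$genes, fx$prof)
  expect_equal(nrow(reg), 0)
  fams <- list(families = data.frame(family_id = "F1"),
               members = data.frame(family_id = "F1", gene_id = "g001"))
  ds <- deviation_summary(fams, fx$prof, reg)
  expect_equal(ds$family_deviant_fraction, 0)
  expect_equal(ds$flagged_in_region_fraction, 0)
})
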