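test_that("growth binarization is inclusive at the OD cut-off", {
  od <- matrix(c(0.31, 0.29, 0.30, 0.0), 2, 2,
               dimnames = list(c("X", "Y"), c("s1", "s2")))
  gm <- binarize_growth(od)
  expect_equal(unname(gm$growth), matrix(c(1L, 0L, 1L, 0L), 2, 2))
  expect_equal(gm$cutoff, 0.3)
  expect_error(binarize_growth(od - 1), "non-negative")
})

pattern_matrix <- function(rows) {
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("f%d", seq_along(rows))
  colnames(m) <- sprintf("st%d", seq_len(ncol(m)))
  m
}

test_that("exact mode groups families by identical pattern", {
  m <- pattern_matrix(list(c(1, 1, 0, 0), c(1, 1, 0, 0), c(1, 0, 0, 0)))
  cl <- cluster_patterns(m)
  expect_equal(length(unique(cl$clusters$cluster_id)), 2)
  sizes <- table(cl$clusters$cluster_id)
  expect_equal(sort(unname(as.integer(sizes))), c(1, 2))
  # numbering follows first family appearance
  expect_equal(cl$clusters$cluster_id[1], "Cluster1")
  expect_equal(unname(cl$patterns["Cluster1", ]), c(1L, 1L, 0L, 0L))
})

test_that("constant patterns are set aside, not clustered", {
  m <- pattern_matrix(list(c(1, 1, 1, 1), c(0, 0, 0, 0), c(1, 0, 1, 0)))
  cl <- cluster_patterns(m)
  expect_equal(nrow(cl$patterns), 1)
  expect_setequal(cl$constant_families, c("f1", "f2"))
  # all-core matrix -> no clusters at all
  allc <- pattern_matrix(list(c(1, 1, 1), c(1, 1, 1)))
  cl0 <- cluster_patterns(allc)
  expect_equal(nrow(cl0$clusters), 0)
  expect_setequal(cl0$constant_families, c("f1", "f2"))
  expect_error(cluster_patterns(m[, 1, drop = FALSE]), "2 assayed strains")
})

test_that("hcl mode merges near-identical patterns with majority consensus", {
  m <- pattern_matrix(list(c(1, 1, 0, 0), c(1, 1, 0, 1)))
  merged <- cluster_patterns(m, mode = "hcl", cut_height = 1)
  expect_equal(length(unique(merged$clusters$cluster_id)), 1)
  # tie on strain 4 (0.5 presence) resolves to present
  expect_equal(unname(merged$patterns["Cluster1", ]), c(1L, 1L, 0L, 1L))
  # cut_height = 0 reproduces exact grouping
  exact <- cluster_patterns(m, mode = "hcl", cut_height = 0)
  expect_equal(length(unique(exact$clusters$cluster_id)), 2)
})

test_that("matching distance is Hamming with deterministic min-ranking", {
  m <- pattern_matrix(list(c(1, 1, 0, 0), c(1, 0, 0, 0), c(0, 0, 1, 1)))
  cl <- cluster_patterns(m)
  growth <- matrix(c(1L, 1L, 0L, 0L), 4, 1,
                   dimnames = list(sprintf("st%d", 1:4), "sugarA"))
  mt <- match_traits(cl, list(growth = growth, cutoff = 0.3))
  d <- mt$matches[order(mt$matches$cluster_id), ]
  expect_equal(d$distance[d$cluster_id == "Cluster1"], 0)
  expect_equal(d$distance[d$cluster_id == "Cluster2"], 1)
  expect_equal(d$distance[d$cluster_id == "Cluster3"], 4)
  expect_equal(d$rank[d$cluster_id == "Cluster1"], 1)
  expect_equal(d$anti_distance[d$cluster_id == "Cluster3"], 0)
  expect_true(all(d$distance >= 0 & d$distance <= 4))
})

test_that("constant-growth carbohydrates are reported unmatchable", {
  m <- pattern_matrix(list(c(1, 0, 1, 0)))
  cl <- cluster_patterns(m)
  growth <- matrix(c(1L, 1L, 1L, 1L, 1L, 0L, 1L, 0L), 4, 2,
                   dimnames = list(sprintf("st%d", 1:4), c("allgrow", "var")))
  mt <- match_traits(cl, list(growth = growth, cutoff = 0.3))
  expect_equal(mt$unmatchable, "allgrow")
  expect_equal(unique(mt$matches$carbohydrate), "var")
})

test_that("adding a core family never changes any match result", {
  panel <- small_panel(seed = 3)
  pm <- panel$truth$presence
  strains <- colnames(pm)
  gm <- binarize_growth(panel$phenotypes)
  base <- match_traits(cluster_patterns(pm[, rownames(gm$growth)]), gm)
  extra <- rbind(pm, CORE_EXTRA = rep(1L, ncol(pm)))
  with_core <- match_traits(cluster_patterns(extra[, rownames(gm$growth)]), gm)
  expect_identical(base$matches, with_core$matches)
})

test_that("noiseless causal clusters match at distance 0 and rank 1", {
  panel <- small_panel(seed = 3)
  gm <- binarize_growth(panel$phenotypes)
  cl <- cluster_patterns(panel$truth$presence[, rownames(gm$growth)])
  mt <- match_traits(cl, gm)
  for (t in names(panel$truth$causal_cluster_of)) {
    fam <- panel$truth$causal_cluster_of[[t]][1]
    cid <- cl$clusters$cluster_id[cl$clusters$family_id == fam]
    row <- mt$matches[mt$matches$carbohydrate == t &
                        mt$matches$cluster_id == cid, ]
    expect_equal(row$distance, 0, info = t)
    expect_equal(row$rank, 1, info = t)
  }
  # causal families share one cluster (same forced pattern)
  for (t in names(panel$truth$causal_cluster_of)) {
    fams <- panel$truth$causal_cluster_of[[t]]
    cids <- cl$clusters$cluster_id[cl$clusters$family_id %in% fams]
    expect_equal(length(unique(cids)), 1, info = t)
  }
})

test_that("causal clusters still rank first for most traits under label noise", {
  # Panel sized so that pattern-collision defeats are rare (< 5% per trait
  # in expectation over 9 strains): few non-causal dispensable clusters and
  # no strain-unique singletons, isolating the matching machinery from
  # collision chance.
  cfg <- panel_config(n_strains = 9, n_core = 80, n_dispensable = 30,
                      n_unique_per_strain = 0, n_traits = 8,
                      hgt_block_count = 2, hgt_block_size = 6,
                      pheno_flip_prob = 0.1, seed = 29)
  panel <- simulate_panel(cfg)
  gm <- binarize_growth(panel$phenotypes)
  cl <- cluster_patterns(panel$truth$presence[, rownames(gm$growth)])
  mt <- match_traits(cl, gm)
  first <- 0
  for (t in names(panel$truth$causal_cluster_of)) {
    if (!(t %in% mt$matches$carbohydrate)) next  # flipped to constant growth
    fam <- panel$truth$causal_cluster_of[[t]][1]
    cid <- cl$clusters$cluster_id[cl$clusters$family_id == fam]
    row <- mt$matches[mt$matches$carbohydrate == t &
                        mt$matches$cluster_id == cid, ]
    if (row$rank == 1) first <- first + 1
  }
  expect_gte(first, 7)
})

test_that("candidate reports list the top clusters with annotations", {
  m <- pattern_matrix(list(c(1, 1, 0, 0), c(0, 1, 0, 1)))
  cl <- cluster_patterns(m)
  growth <- matrix(c(1L, 1L, 0L, 0L), 4, 1,
                   dimnames = list(sprintf("st%d", 1:4), "ribose"))
  mt <- match_traits(cl, list(growth = growth, cutoff = 0.3))
  ann <- c(f1 = "ribokinase", f2 = "unrelated permease")
  rep <- candidate_report(mt, cl, ann, k = 1)
  expect_equal(rep$ribose$cluster_id, "Cluster1")
  expect_equal(rep$ribose$distance, 0)
  expect_match(rep$ribose$annotations, "ribokinase")
})
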