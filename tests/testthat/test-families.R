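test_that("hit filtering applies identity, E-value and either-protein coverage", {
  hits <- rbind(
    make_hit("a", "b", 85, 120, 1e-50, 130, 125),   # all thresholds cleared
    make_hit("c", "d", 49.9, 200, 0, 200, 200),     # identity just below 50
    make_hit("e", "f", 90, 60, 1e-30, 130, 125),    # 60 < 0.5 * min(130,125)
    make_hit("g", "h", 90, 63, 1e-30, 130, 125),    # 63 >= 62.5: covered
    make_hit("i", "j", 55, 100, 2e-4, 120, 120)     # E-value above 1e-4
  )
  kept <- filter_hits(hits)
  expect_setequal(kept$query_id, c("a", "g"))
  # min-length denominator: covering half the shorter protein suffices
  one <- make_hit("q", "s", 60, 50, 1e-9, 100, 400)
  expect_equal(nrow(filter_hits(one)), 1)
})

test_that("graph edges require both directions and weight the best E-value", {
  hits <- rbind(
    make_hit("a", "b", 80, 100, 1e-50, 100, 100),
    make_hit("b", "a", 80, 100, 1e-40, 100, 100),
    make_hit("a", "c", 80, 100, 1e-30, 100, 100),  # one direction only
    make_hit("d", "e", 80, 100, 0, 100, 100),
    make_hit("e", "d", 80, 100, 0, 100, 100)
  )
  g <- build_graph(hits)
  expect_equal(nrow(g$edges), 2)
  ab <- g$edges[g$edges$from == "a" & g$edges$to == "b", ]
  expect_equal(ab$weight, 50)          # -log10 of the best direction
  de <- g$edges[g$edges$from == "d" & g$edges$to == "e", ]
  expect_equal(de$weight, 200)         # E = 0 maps to the cap
  expect_false(any(g$edges$from == "a" & g$edges$to == "c"))
})

test_that("MCL separates disjoint cliques and keeps singletons", {
  clique_hits <- function(members, e = 1e-30) {
    do.call(rbind, lapply(members, function(q)
      do.call(rbind, lapply(setdiff(members, q), function(s)
        make_hit(q, s, 90, 100, e, 100, 100)))))
  }
  hits <- rbind(clique_hits(c("a1", "a2", "a3")),
                clique_hits(c("b1", "b2", "b3")))
  g <- build_graph(hits)
  cl <- mcl_cluster(g)
  expect_length(cl, 2)
  expect_setequal(cl[[1]], c("a1", "a2", "a3"))
  expect_setequal(cl[[2]], c("b1", "b2", "b3"))

  lone <- list(nodes = "solo", edges = data.frame(from = character(),
                                                  to = character(),
                                                  weight = numeric()))
  expect_equal(mcl_cluster(lone), list("solo"))
})

test_that("MCL equals connected components on uniform clique graphs", {
  # brute-force reachability oracle on a graph whose components are cliques
  set.seed(42)
  sizes <- c(2, 3, 5, 4, 1, 6)
  members <- lapply(seq_along(sizes), function(k)
    sprintf("n%d_%d", k, seq_len(sizes[k])))
  edges <- do.call(rbind, lapply(members, function(m) {
    if (length(m) < 2) return(NULL)
    cmb <- t(combn(m, 2))
    data.frame(from = cmb[, 1], to = cmb[, 2], weight = 30,
               stringsAsFactors = FALSE)
  }))
  g <- list(nodes = sort(unlist(members)), edges = edges)
  cl <- mcl_cluster(g)
  expect_length(cl, length(sizes))
  got <- lapply(cl, sort)
  want <- lapply(members, sort)
  expect_setequal(vapply(got, paste, character(1), collapse = ","),
                  vapply(want, paste, character(1), collapse = ","))
})

test_that("MCL partition is invariant under node relabeling", {
  panel <- small_panel()
  g <- build_graph(filter_hits(panel$hits))
  cl1 <- mcl_cluster(g)
  # relabel nodes with a prefix that reverses lexicographic order
  relab <- setNames(sprintf("z%05d|%s", rev(seq_along(g$nodes)), g$nodes),
                    g$nodes)
  g2 <- list(nodes = unname(relab[g$nodes]),
             edges = data.frame(from = unname(relab[g$edges$from]),
                                to = unname(relab[g$edges$to]),
                                weight = g$edges$weight,
                                stringsAsFactors = FALSE))
  cl2 <- mcl_cluster(g2)
  norm1 <- sort(vapply(cl1, function(x) paste(sort(x), collapse = ","),
                       character(1)))
  norm2 <- sort(vapply(cl2, function(x)
    paste(sort(sub("^z\\d+\\|", "", x)), collapse = ","), character(1)))
  expect_identical(norm1, norm2)
})

test_that("family classification follows the core/dispensable/unique rules", {
  genomes <- c("gA", "gB", "gC")
  gi <- data.frame(
    gene_id = c("a1", "b1", "c1", "a2", "b2", "a3", "a4", "b4", "c4", "c4b",
                "a5", "b5", "c5"),
    genome_id = c("gA", "gB", "gC", "gA", "gB", "gA", "gA", "gB", "gC", "gC",
                  "gA", "gB", "gC"),
    is_mobile = c(rep(FALSE, 10), TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  clusters <- list(c("a1", "b1", "c1"),      # core, single copy
                   c("a2", "b2"),            # dispensable (2 of 3)
                   c("a4", "b4", "c4", "c4b"),# core but paralogous in gC
                   c("a5", "b5", "c5"))      # core but contains mobilome
  fams <- classify_families(clusters, genomes, gi)
  f <- fams$families
  expect_equal(f$family_class, c("core", "dispensable", "core", "core", "unique"))
  expect_equal(f$is_single_copy_orthologue, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(fams$summary$n_unique, 1)      # a3 left over -> singleton
  expect_equal(fams$summary$n_orthologues, 1)
  # partition property: every gene in exactly one family
  expect_setequal(fams$members$gene_id, gi$gene_id)
  expect_equal(sum(f$size), nrow(gi))
  expect_equal(fams$summary$n_core + fams$summary$n_dispensable +
                 fams$summary$n_unique, fams$summary$n_families)
  expect_error(classify_families(list(c("nope")), genomes, gi), "unknown")
})

test_that("noiseless synthetic panels are recovered exactly (ARI = 1)", {
  panel <- small_panel(seed = 19)
  genomes <- sort(unique(panel$genes$genome_id))
  cl <- mcl_cluster(build_graph(filter_hits(panel$hits)))
  fams <- classify_families(cl, genomes, panel$genes)
  ari <- adjusted_rand_index(
    panel$truth$family_of,
    setNames(fams$members$family_id, fams$members$gene_id))
  expect_equal(ari, 1.0)
  # realized classes match the ground truth per family
  fam_map <- setNames(fams$members$family_id, fams$members$gene_id)
  for (cls in c("core", "dispensable", "unique")) {
    truth_n <- sum(panel$truth$class_of == cls)
    expect_equal(fams$summary[[paste0("n_", cls)]], unname(truth_n))
  }
})

test_that("spurious cross-family hits do not degrade recovery", {
  panel <- small_panel(seed = 23, spurious_hit_rate = 0.02)
  genomes <- sort(unique(panel$genes$genome_id))
  cl <- mcl_cluster(build_graph(filter_hits(panel$hits)))
  fams <- classify_families(cl, genomes, panel$genes)
  ari <- adjusted_rand_index(
    panel$truth$family_of,
    setNames(fams$members$family_id, fams$members$gene_id))
  expect_gte(ari, 0.95)
})

test_that("presence matrix holds copy counts with no all-zero rows", {
  panel <- small_panel()
  genomes <- sort(unique(panel$genes$genome_id))
  cl <- mcl_cluster(build_graph(filter_hits(panel$hits)))
  fams <- classify_families(cl, genomes, panel$genes)
  pm <- presence_matrix(fams, genomes)
  expect_equal(sum(pm), nrow(panel$genes))
  expect_true(all(rowSums(pm) > 0))
  core_rows <- fams$families$family_id[fams$families$family_class == "core"]
  expect_true(all(pm[core_rows, ] >= 1))
})
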