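mk_genome <- function(id, kos, counts = NULL, phylum = "Bacillota") {
  if (is.null(counts)) counts <- rep(1L, length(kos))
  genome_annotation(id, stats::setNames(as.integer(counts), kos),
                    taxonomy = c(phylum = phylum, family = "f"))
}

test_that("union deduplicates KOs within and across members", {
  a <- mk_genome("a", c("K00001", "K00002"), c(3L, 1L))
  b <- mk_genome("b", c("K00002", "K00003"))
  cons <- consortium_spec("u", list(a, b))
  expect_setequal(union_kos(cons), c("K00001", "K00002", "K00003"))

  solo <- consortium_spec("solo", list(a))
  expect_setequal(union_kos(solo), c("K00001", "K00002"))

  # adding a copy of a member (fresh id) leaves the union unchanged
  a2 <- mk_genome("a2", c("K00001", "K00002"))
  cons2 <- consortium_spec("u2", list(a, b, a2))
  expect_setequal(union_kos(cons2), union_kos(cons))
})

test_that("unique KOs are the presence-based set difference against all others", {
  target <- consortium_profile(consortium_spec("t", list(
    mk_genome("t1", c("K00001", "K00002")), mk_genome("t2", "K00003"))))
  oA <- consortium_profile(consortium_spec("oA", list(mk_genome("o1", "K00002"))))
  oB <- consortium_profile(consortium_spec("oB", list(mk_genome("o2", "K00003"))))
  expect_equal(unique_kos(target, list(oA, oB)), "K00001")
  expect_length(unique_kos(target, list(target)), 0)
  expect_error(unique_kos(target, list()), ">= 1 other")

  # partition identity: |unique| + |shared| = |target union|
  expect_equal(length(unique_kos(target, list(oA, oB))) +
                 length(intersect(target$ko_union,
                                  union(oA$ko_union, oB$ko_union))),
               length(target$ko_union))
})

test_that("prevalence table reproduces the printed worked-example aggregates", {
  tab <- infant_enriched_ko_table()
  cons <- consortium_from_count_table(tab, infant_enriched_isolates(),
                                      "PedsCom")
  prev <- build_prevalence_table(cons, config = analysis_config())

  expect_equal(prev$n_total, rep(9L, nrow(prev)))
  # every printed row is reproduced exactly
  printed_n <- as.integer(sub("/9", "", tab$prevalence))
  for (i in seq_len(nrow(tab))) {
    row <- prev[prev$ko == tab$ko[i], ]
    expect_equal(row$gene_count, tab$gene_count[i], info = tab$ko[i])
    expect_equal(row$n_present, printed_n[i], info = tab$ko[i])
  }
  # spot checks of the two fully worked rows
  expect_equal(prev$gene_count[prev$ko == "K02793"], 10L)
  expect_equal(prev$n_present[prev$ko == "K02793"], 6L)
  expect_equal(prev$gene_count[prev$ko == "K02538"], 8L)
  expect_equal(prev$n_present[prev$ko == "K02538"], 6L)
})

test_that("prevalence rows filter, sort and self-check", {
  cons <- consortium_spec("p", list(
    mk_genome("g1", c("K00001", "K00002"), c(2L, 1L)),
    mk_genome("g2", c("K00001", "K00003")),
    mk_genome("g3", "K00001")))
  prev <- build_prevalence_table(cons,
                                 config = analysis_config(prevalence_min_isolates = 2))
  # K00002/K00003 each in one isolate only -> dropped
  expect_equal(prev$ko, "K00001")
  expect_equal(prev$gene_count, 4L)
  expect_equal(prev$n_present, 3L)
  # recomputing from the per-isolate columns matches stored fields
  iso_counts <- as.integer(prev[1, c("g1", "g2", "g3")])
  expect_equal(sum(iso_counts), prev$gene_count)
  expect_equal(sum(iso_counts > 0), prev$n_present)

  # filter KO absent everywhere -> empty, not an error
  empty <- build_prevalence_table(cons, ko_filter = "K99999",
                                  config = analysis_config())
  expect_equal(nrow(empty), 0)
})

test_that("module prevalence matrix gives member proportions per consortium", {
  db <- gen_module_db(4, steps_range = c(2L, 2L), seed = 31)
  mod1 <- db[[1]]$module_id
  plan <- function(n, carriers) {
    data.frame(genome = seq_len(n), module = mod1,
               coverage = c(rep(1, carriers), rep(0, n - carriers)))
  }
  cfg <- analysis_config()
  gens <- list(
    ref = gen_consortium("ref", 9, db, completeness_plan = plan(9, 4), seed = 1),
    oA = gen_consortium("oA", 8, db, completeness_plan = plan(8, 1), seed = 2),
    oB = gen_consortium("oB", 12, db, completeness_plan = plan(12, 1), seed = 3))
  profiles <- lapply(gens, function(g)
    profile_consortium_modules(g$consortium, db, cfg))
  mat <- gmm_prevalence_matrix(profiles)
  expect_true(all(mat >= 0 & mat <= 1))
  expect_equal(unname(mat[mod1, ]), c(4 / 9, 1 / 8, 1 / 12),
               tolerance = 1e-12)
  # rows sorted by reference proportion, ties by module id
  expect_equal(order(-mat[, 1], rownames(mat)), seq_len(nrow(mat)))
  # dense: an everywhere-absent module keeps its all-zero row
  expect_equal(nrow(mat), 4)

  # category filter restricted to the module database's categories
  sub <- gmm_prevalence_matrix(profiles, db,
                               category_filter = db[[1]]$category)
  expect_true(mod1 %in% rownames(sub))
  expect_warning(gmm_prevalence_matrix(profiles, db, "no such category"),
                 "unknown category")
})

test_that("category allocation counts distinct KOs once per category", {
  h <- functional_hierarchy(data.frame(
    ko = c("K00001", "K00001", "K00002", "K00003"),
    pathway = c("p1", "p2", "p3", "p4"),
    category = c("catA", "catB", "catA", "catA"),
    subcategory = c("s1", "s2", "s1", "s1")))
  g <- mk_genome("g", c("K00001", "K00002", "K00003"))
  alloc <- category_allocation(g, h)
  # K00001 contributes to both categories (documented double count)
  expect_equal(alloc$counts$n_kos[alloc$counts$category == "catA"], 3L)
  expect_equal(alloc$counts$n_kos[alloc$counts$category == "catB"], 1L)

  # all-in-one-subcategory genome
  g2 <- mk_genome("g2", c("K00002", "K00003"))
  alloc2 <- category_allocation(g2, h)
  expect_equal(alloc2$counts$n_kos, 3 - 1)

  # unannotated KOs land in the explicit bucket
  g3 <- mk_genome("g3", "K99999")
  alloc3 <- category_allocation(g3, h)
  expect_equal(alloc3$counts$category, "unannotated")
})

test_that("module-KO totals and medians summarise per-genome allocation", {
  kos <- sprintf("K%05d", 1:30)
  db <- list(module_definition("MTOT", "all thirty", lapply(kos, function(k)
    list(list(required = k, optional = character())))))
  members <- list(
    mk_genome("m1", kos[seq_len(10)]),
    mk_genome("m2", kos[seq_len(20)]),
    mk_genome("m3", kos[seq_len(30)]))
  cons <- consortium_spec("med", members)
  tot <- module_ko_totals(cons, db)
  expect_equal(unname(tot$per_genome), c(10L, 20L, 30L))
  expect_equal(tot$median, 20)
})
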