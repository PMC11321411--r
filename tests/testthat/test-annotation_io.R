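test_that("gene-to-KO tables aggregate copy counts and unassigned genes", {
  f <- withr::local_tempfile()
  writeLines(c("g1\tK00001", "g2\tK00001", "g3\tK00002", "g4\t", "g5\tK00003"),
             f)
  g <- read_ko_annotation(f, "toy")
  expect_equal(g$ko_counts, c(K00001 = 2L, K00002 = 1L, K00003 = 1L))
  expect_equal(g$n_unassigned, 1L)

  # permuting rows changes nothing
  f2 <- withr::local_tempfile()
  writeLines(c("g5\tK00003", "g4\t", "g1\tK00001", "g3\tK00002", "g2\tK00001"),
             f2)
  g2 <- read_ko_annotation(f2, "toy")
  expect_equal(g2$ko_counts, g$ko_counts)
  expect_equal(g2$n_unassigned, g$n_unassigned)

  # row conservation: copies + unassigned = rows
  expect_equal(sum(g$ko_counts) + g$n_unassigned, 5L)
})

test_that("annotation reader handles empty input, CRLF, duplicates and errors", {
  f <- withr::local_tempfile()
  writeLines(character(0), f)
  g <- read_ko_annotation(f, "empty")
  expect_length(g$ko_counts, 0)
  expect_equal(g$n_unassigned, 0L)

  # CRLF and blank lines are tolerated
  f2 <- withr::local_tempfile()
  writeBin(charToRaw("g1\tK00001\r\n\r\ng2\tK00002\r\n"), f2)
  g2 <- read_ko_annotation(f2, "crlf")
  expect_equal(g2$ko_counts, c(K00001 = 1L, K00002 = 1L))

  # duplicate gene ids: warning, counted once
  f3 <- withr::local_tempfile()
  writeLines(c("g1\tK00001", "g1\tK00002"), f3)
  expect_warning(g3 <- read_ko_annotation(f3, "dup"), "duplicate gene")
  expect_equal(sum(g3$ko_counts), 1L)

  # malformed line names its number
  f4 <- withr::local_tempfile()
  writeLines(c("g1\tK00001", "a\tb\tc"), f4)
  expect_error(read_ko_annotation(f4, "bad"), "line 2")
})

test_that("annotation writer round-trips through the reader", {
  g <- genome_annotation("rt", c(K00001 = 3L, K00042 = 1L), n_unassigned = 2L)
  f <- withr::local_tempfile()
  write_ko_annotation(g, f)
  g2 <- read_ko_annotation(f, "rt")
  expect_equal(g2$ko_counts, g$ko_counts)
  expect_equal(g2$n_unassigned, g$n_unassigned)
})

test_that("GMM flat-file parser handles alternatives, complexes and errors", {
  f <- withr::local_tempfile()
  writeLines(c("MF9001\ttoy module", "K00001", "K00002,K00003", "///"), f)
  mods <- read_gmm_definitions(f)
  expect_length(mods, 1)
  expect_length(mods[[1]]$steps, 2)
  expect_length(mods[[1]]$steps[[2]], 2)

  f2 <- withr::local_tempfile()
  writeLines(c("MF9002\tcomplex module", "K00004+K00005", "///"), f2)
  m <- read_gmm_definitions(f2)[[1]]
  expect_length(m$steps[[1]], 1)
  expect_setequal(m$steps[[1]][[1]]$required, c("K00004", "K00005"))

  # empty file -> empty list; missing terminator -> error
  f3 <- withr::local_tempfile()
  writeLines(character(0), f3)
  expect_length(read_gmm_definitions(f3), 0)
  f4 <- withr::local_tempfile()
  writeLines(c("MF9003\tunterminated", "K00001"), f4)
  expect_error(read_gmm_definitions(f4), "terminator")

  # duplicate module ids: keep first with a warning
  f5 <- withr::local_tempfile()
  writeLines(c("MF1\ta", "K00001", "///", "MF1\tb", "K00002", "///"), f5)
  expect_warning(mods5 <- read_gmm_definitions(f5), "duplicate module id")
  expect_length(mods5, 1)
  expect_equal(mods5[[1]]$name, "a")
})

test_that("GMM writer round-trips module databases exactly", {
  db <- gen_module_db(8, seed = 11)
  f <- withr::local_tempfile()
  write_gmm_definitions(db, f)
  db2 <- expect_no_warning(read_gmm_definitions(f))
  expect_equal(lapply(db2, unclass), lapply(db, unclass))
})

test_that("KEGG-style definition grammar parses steps, OR groups and complexes", {
  m <- parse_kegg_definition("K00001 K00002", "M1", "serial")
  expect_length(m$steps, 2)
  expect_equal(m$steps[[1]][[1]]$required, "K00001")

  m2 <- parse_kegg_definition("(K00001,K00002) K00003", "M2", "or")
  expect_length(m2$steps, 2)
  expect_length(m2$steps[[1]], 2)
  expect_setequal(vapply(m2$steps[[1]], `[[`, character(1), "required"),
                  c("K00001", "K00002"))

  m3 <- parse_kegg_definition("K00001+K00002 -K00003", "M3", "optional")
  expect_length(m3$steps, 1)
  expect_setequal(m3$steps[[1]][[1]]$required, c("K00001", "K00002"))
  expect_true("K00003" %in% m3$steps[[1]][[1]]$optional)

  # nesting to depth 3
  m4 <- parse_kegg_definition("((K00001,(K00002,K00004)),K00003) K00005",
                              "M4", "nested")
  expect_length(m4$steps, 2)
  expect_setequal(vapply(m4$steps[[1]], `[[`, character(1), "required"),
                  c("K00001", "K00002", "K00004", "K00003"))

  expect_error(parse_kegg_definition("(K00001 K00002", "M5", "bad"),
               "unclosed")
  expect_error(parse_kegg_definition("K00001)", "M6", "bad"), "position")
})

test_that("hierarchy reader maps KOs to pathways with an unannotated bucket", {
  f <- withr::local_tempfile()
  writeLines(c("ko\tpathway\tcategory\tsubcategory",
               "K00001\tGlycolysis\tMetabolism\tCarbohydrate",
               "K00001\tTCA cycle\tMetabolism\tCarbohydrate",
               "K00002\tLipolysis\tMetabolism\tLipid"), f)
  h <- read_hierarchy(f)
  expect_equal(nrow(h), 3)
  expect_equal(sort(hierarchy_lookup(h, "K00001")$pathway),
               c("Glycolysis", "TCA cycle"))
  unk <- hierarchy_lookup(h, "K99999")
  expect_equal(unk$category, "unannotated")

  # idempotent on re-read
  h2 <- read_hierarchy(f)
  expect_equal(as.data.frame(h2), as.data.frame(h))

  f2 <- withr::local_tempfile()
  writeLines(c("ko\tpathway", "K00001\tGlycolysis"), f2)
  expect_error(read_hierarchy(f2), "4 columns")
})

test_that("consortium metadata loader resolves members and taxonomy", {
  dir <- withr::local_tempdir()
  writeLines(c("gA\tK00001", "gB\tK00002"), file.path(dir, "m1.tsv"))
  writeLines(c("gC\tK00003"), file.path(dir, "m2.tsv"))
  writeLines(c("genome_id\tconsortium\tphylum\tfamily\tannotation_path",
               "iso1\tdemo\tBacillota\tLactobacillaceae\tm1.tsv",
               "iso2\tdemo\tBacteroidota\tTannerellaceae\tm2.tsv"),
             file.path(dir, "meta.tsv"))
  cons <- read_consortium(file.path(dir, "meta.tsv"))
  expect_s3_class(cons, "consortium_spec")
  expect_length(cons$members, 2)
  expect_equal(cons$members[[2]]$taxonomy[["phylum"]], "Bacteroidota")
  expect_error(read_consortium(file.path(dir, "meta.tsv"), "nope"),
               "no members")
})
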