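test_that("GMT lines parse into pathways with dedup and preserved order", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("P1\tdesc\tTP53\tEGFR",
               "P2\td\tTP53\tTP53",
               "P3\tthird\tBRCA1\tBRCA2\tATM"), f)
  x <- read_gmt(f)
  expect_s3_class(x, "pathway_collection")
  expect_identical(pathway_ids(x), c("P1", "P2", "P3"))
  expect_setequal(x$pathways$P1$genes, c("TP53", "EGFR"))
  expect_identical(x$pathways$P2$genes, "TP53")  # within-line dedup
  expect_setequal(x$universe, c("TP53", "EGFR", "BRCA1", "BRCA2", "ATM"))
})

test_that("malformed GMT lines and duplicate ids are rejected with context", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("P1\tdesc\tTP53", "P3\tonly-description"), f)
  expect_error(read_gmt(f), "line 2")
  writeLines(c("P1\tdesc\tTP53", "P1\tagain\tEGFR"), f)
  expect_error(read_gmt(f), "duplicate pathway id")
  expect_error(read_gmt(file.path(tempdir(), "nope.gmt")), "not found")
})

test_that("GMT write/read round-trips ids, gene sets, and provenance", {
  x <- pathway_collection(list(
    pathway("Pa", c("z1", "a9", "m5"), name = "A pathway"),
    pathway("Pb", c("a9"), provenance = c("Pold2", "Pold1"))))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(x, f)
  y <- read_gmt(f)
  expect_identical(pathway_ids(y), pathway_ids(x))
  for (id in pathway_ids(x)) {
    expect_setequal(y$pathways[[id]]$genes, x$pathways[[id]]$genes)
  }
  expect_setequal(y$pathways$Pb$provenance, c("Pold1", "Pold2"))
  # empty collection -> empty file, still round-trips
  f2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(pathway_collection(), f2)
  expect_identical(length(read_gmt(f2)), 0L)
})

test_that("generator GMT output parses losslessly (parsing is total)", {
  for (seed in c(2, 9)) {
    sim <- generate_collection(small_synth_cfg(seed))
    f <- withr::local_tempfile(fileext = ".gmt")
    write_gmt(sim$collection, f)
    y <- expect_no_error(read_gmt(f))
    expect_identical(pathway_ids(y), pathway_ids(sim$collection))
    for (id in pathway_ids(y)) {
      expect_setequal(y$pathways[[id]]$genes, sim$collection$pathways[[id]]$genes)
    }
  }
})

test_that("assay annotation tables parse with source priority and validation", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tsources", "TP53\tPUBCHEM;TOX21", "EGFR\tCOMMERCIAL"), f)
  ann <- read_annotation_table(f, "assay")
  # priority order retained regardless of input order
  expect_identical(ann$sources[[1L]], c("TOX21", "PUBCHEM"))
  expect_identical(ann$sources[[2L]], "COMMERCIAL")
  writeLines(c("gene\tsources", "TP53\tTOX21;ACME"), f)
  expect_error(read_annotation_table(f, "assay"), "unknown assay source")
  writeLines(c("gene\twrong", "TP53\tTOX21"), f)
  expect_error(read_annotation_table(f, "assay"), "missing required column")
})

test_that("activity tables enforce binary calls and unique ids", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("compound\ta1\ta2", "c1\t0\t1", "c2\t1\t0"), f)
  m <- read_annotation_table(f, "activity")
  expect_identical(dim(m), c(2L, 2L))
  expect_identical(m["c1", "a2"], 1L)
  writeLines(c("compound\ta1", "c1\t2"), f)
  expect_error(read_annotation_table(f, "activity"), "0 or 1")
  writeLines(c("compound\ta1", "c1\t1", "c1\t0"), f)
  expect_error(read_annotation_table(f, "activity"), "duplicate compound")
})

test_that("header-only tables yield empty records", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene\ttag", f)
  expect_identical(nrow(read_annotation_table(f, "gene_tag")), 0L)
})

test_that("gene ids are whitespace-stripped but case-preserved", {
  p <- pathway("P1", c("  TP53 ", "tp53"))
  expect_setequal(p$genes, c("TP53", "tp53"))
  expect_error(pathway("P1", c("TP53", "   ")), "non-empty")
})

test_that("collection invariants are enforced", {
  expect_error(pathway_collection(list(pathway("A", "g1"), pathway("A", "g2"))),
               "duplicate pathway id")
  expect_error(pathway_collection(list(pathway("A", c("g1", "g2"))),
                                  universe = "g1"),
               "universe is missing")
  expect_error(pathway("A", "g1", provenance = "A"), "own id")
})
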