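test_that("shipped vocabulary has 51 unique tags in seven categories", {
  v <- default_tag_vocabulary()
  expect_identical(nrow(v), 51L)
  expect_identical(anyDuplicated(v$tag), 0L)
  expect_identical(length(unique(v$category)), 7L)
})

test_that("gene-based tagging enforces both thresholds on the boundary", {
  tag <- "Cell death"
  mk <- function(n_genes, n_tagged) {
    x <- make_collection(P = genes(n_genes))
    gt <- data.frame(gene = genes(n_tagged), tag = tag)
    tag_by_gene_annotations(x, gt)
  }
  # 4 tagged of 40 genes: 4 >= 4 and 10% >= 10% -> assigned
  hit <- mk(40, 4)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$n_tagged_genes, 4L)
  expect_equal(hit$frac_tagged, 0.1)
  # 4 of 50: 8% < 10% -> not assigned
  expect_identical(nrow(mk(50, 4)), 0L)
  # 3 of 9: 33% but only 3 genes -> not assigned
  expect_identical(nrow(mk(9, 3)), 0L)
})

test_that("every gene-based assignment satisfies the printed thresholds", {
  sim <- generate_collection(small_synth_cfg(21, tag_prob = 0.8))
  out <- tag_by_gene_annotations(sim$collection, sim$gene_tags)
  expect_gt(nrow(out), 0L)
  expect_true(all(out$n_tagged_genes >= 4L))
  expect_true(all(out$frac_tagged >= 0.10))
})

test_that("genes with several tags count toward each tag independently", {
  x <- make_collection(P = genes(10))
  gt <- rbind(data.frame(gene = genes(4), tag = "Cell death"),
              data.frame(gene = genes(4), tag = "Cell cycle"))
  out <- tag_by_gene_annotations(x, gt)
  expect_setequal(out$tag, c("Cell death", "Cell cycle"))
  expect_error(tag_by_gene_annotations(x, data.frame(gene = "g01",
                                                     tag = "Not a tag")),
               "outside the vocabulary")
})

test_that("keyword tagging matches whole words case-insensitively", {
  x <- pathway_collection(list(
    pathway("P1", genes(3), name = "Purine catabolism"),
    pathway("P2", genes(3), name = "HIV-induced T cell apoptosis"),
    pathway("P3", genes(3), name = "Spurine metabolism")))  # no whole word
  out <- tag_by_keywords(x)
  p1 <- out$tag[out$pathway_id == "P1"]
  expect_true("Nucleic acid metabolism" %in% p1)
  p2 <- out$tag[out$pathway_id == "P2"]
  # hyphen is a word boundary: HIV matches inside "HIV-induced"
  expect_setequal(p2, c("Infectious disease", "Immune system", "Cell death"))
  expect_false("P3" %in% out$pathway_id)
})

test_that("keyword tagging with an empty or unmatched lexicon assigns nothing", {
  x <- pathway_collection(list(pathway("P1", genes(3), name = "Something else")))
  lex <- data.frame(keyword = "zzzz", tag = "Cancer")
  expect_identical(nrow(tag_by_keywords(x, lex)), 0L)
  expect_identical(nrow(tag_by_keywords(x, lex[0, ])), 0L)
})

test_that("combined tagging unions methods and keeps provenance", {
  x <- pathway_collection(list(pathway("P1", genes(40), name = "apoptosis core")))
  gt <- data.frame(gene = genes(4), tag = "Cell death")
  res <- assign_tags(x, gt, default_keyword_lexicon())
  row <- res$assignments[res$assignments$tag == "Cell death", ]
  expect_identical(nrow(row), 1L)  # one tag, both methods
  expect_identical(row$methods, "gene_based+keyword")
  expect_equal(res$frac_tagged_pathways, 1)
  # no annotations at all -> zero assignments
  res0 <- assign_tags(x, NULL, NULL)
  expect_identical(nrow(res0$assignments), 0L)
  expect_equal(res0$frac_tagged_pathways, 0)
})

test_that("planted tag structure is recovered exactly", {
  sim <- generate_collection(small_synth_cfg(33, tag_prob = 0.7))
  res <- assign_tags(sim$collection, sim$gene_tags, NULL)
  expect_identical(res$tags[names(sim$planted_tags)], sim$planted_tags)
})

test_that("adding lexicon entries never removes an assignment", {
  x <- pathway_collection(list(
    pathway("P1", genes(5), name = "Purine salvage"),
    pathway("P2", genes(5), name = "T cell activation")))
  lex1 <- data.frame(keyword = "Purine", tag = "Nucleic acid metabolism")
  lex2 <- rbind(lex1, data.frame(keyword = "T cell", tag = "Immune system"))
  out1 <- tag_by_keywords(x, lex1)
  out2 <- tag_by_keywords(x, lex2)
  key <- function(d) paste(d$pathway_id, d$tag)
  expect_true(all(key(out1) %in% key(out2)))
  expect_gt(nrow(out2), nrow(out1))
})

test_that("assignments do not depend on pathway order", {
  sim <- generate_collection(small_synth_cfg(5, tag_prob = 0.6))
  x <- sim$collection
  set.seed(1); perm <- sample(length(x))
  x_shuf <- pathway_collection(x$pathways[perm], universe = x$universe)
  a <- assign_tags(x, sim$gene_tags, default_keyword_lexicon())
  b <- assign_tags(x_shuf, sim$gene_tags, default_keyword_lexicon())
  expect_identical(a$assignments, b$assignments)
})
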