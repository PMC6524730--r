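test_that("merge criteria fire exactly as defined", {
  u <- 1000
  # c2: symmetric difference of one gene
  d <- merge_decision(pathway("A", genes(10)), pathway("B", genes(11)), u)
  expect_true(d$c2_differ_by_one)
  expect_true(d$mergeable)
  expect_true(d$c1_overlap_gt_90)  # 10/11 > 0.9: criterion 1 also fires
  d2 <- merge_decision(pathway("A", genes(5)), pathway("B", genes(6)), u)
  expect_true(d2$c2_differ_by_one)
  expect_false(d2$c1_overlap_gt_90)  # 5/6 < 0.9
  # c3: small pathway contained in the other
  d3 <- merge_decision(pathway("A", genes(2)), pathway("B", genes(20)), u)
  expect_true(d3$c3_small_subset)
  expect_true(d3$mergeable)
  # not mergeable: disjoint sets
  d0 <- merge_decision(pathway("A", genes(10)),
                       pathway("B", genes(10, prefix = "h")), u)
  expect_false(d0$mergeable)
  expect_true(is.na(d0$p))  # p only computed when overlap > 0.5
})

test_that("criterion 4 matches the brute-force hypergeometric tail", {
  # 10-gene sets sharing 8 genes over a universe of 1000
  a <- pathway("A", genes(10))
  b <- pathway("B", c(genes(8), "x1", "x2"))
  d <- merge_decision(a, b, 1000)
  expect_equal(d$overlap, 8 / 12)
  p_oracle <- brute_hyper_tail(8, 10, 10, 1000)
  expect_equal(d$p, p_oracle, tolerance = 1e-12)
  expect_lt(d$p, 0.05)
  expect_true(d$c4_overlap_gt_50_and_significant)
})

test_that("universe smaller than the union is rejected", {
  expect_error(merge_decision(pathway("A", genes(10)),
                              pathway("B", genes(12)), 11),
               "universe_size")
  expect_error(merge_decision(pathway("A", character()), pathway("B", "g"), 5))
})

test_that("both criterion-2 spellings agree", {
  u <- 500
  set.seed(31)
  for (i in 1:40) {
    a <- pathway("A", sample(genes(20), sample(1:12, 1)))
    b <- pathway("B", sample(genes(20), sample(1:12, 1)))
    expect_identical(
      merge_decision(a, b, u, criterion2_mode = "symmetric")$c2_differ_by_one,
      merge_decision(a, b, u, criterion2_mode = "containment")$c2_differ_by_one)
  }
})

test_that("a one-gene chain collapses to a single pathway", {
  # over a realistic background the chain A < B < C collapses completely:
  # B and C merge first (highest overlap), then A joins the merged pathway
  # through the significant->50%-overlap criterion
  x <- pathway_collection(
    list(pathway("A", genes(10)), pathway("B", genes(11)),
         pathway("C", genes(12))),
    universe = c(genes(12), sprintf("u%04d", 1:988)))
  res <- condense_collection(x)
  expect_identical(length(res$collection), 1L)
  expect_setequal(res$collection$pathways[[1L]]$genes, genes(12))
  expect_identical(nrow(res$report$merge_log), 2L)
  expect_true(all(res$report$merge_log$criterion %in% c("c1", "c2", "c4")))
})

test_that("identical pathways merge; disjoint pathways are untouched", {
  x <- make_collection(A = genes(5), B = genes(5))
  res <- condense_collection(x)
  expect_identical(length(res$collection), 1L)
  expect_setequal(res$collection$pathways[[1L]]$genes, genes(5))

  y <- make_collection(A = genes(10), B = genes(10, prefix = "h"))
  res_y <- condense_collection(y)
  expect_identical(length(res_y$collection), 2L)
  expect_identical(nrow(res_y$report$merge_log), 0L)
})

test_that("condensation is idempotent, conserves genes, and shrinks", {
  for (seed in c(4, 17)) {
    sim <- generate_collection(small_synth_cfg(seed))
    res1 <- condense_collection(sim$collection)
    expect_lte(length(res1$collection), length(sim$collection))
    # gene conservation
    before <- sort(unique(unlist(lapply(sim$collection$pathways, `[[`, "genes"))))
    after <- sort(unique(unlist(lapply(res1$collection$pathways, `[[`, "genes"))))
    expect_identical(after, before)
    # fixpoint: a second pass does nothing
    res2 <- condense_collection(res1$collection)
    expect_identical(nrow(res2$report$merge_log), 0L)
    expect_identical(pathway_ids(res2$collection), pathway_ids(res1$collection))
    # report bookkeeping replays
    expect_identical(res1$report$n_output,
                     res1$report$n_input - nrow(res1$report$merge_log))
  }
})

test_that("condensation recovers the planted base pathways", {
  sim <- generate_collection(small_synth_cfg(12))
  res <- condense_collection(sim$collection)
  n_base <- sum(sim$ledger$class == "base")
  expect_identical(length(res$collection), n_base)
  # provenance accounts for every absorbed pathway
  absorbed <- unlist(lapply(res$collection$pathways, `[[`, "provenance"))
  expect_setequal(absorbed, res$report$merge_log$absorbed)
})

test_that("condensed output is independent of input order", {
  sim <- generate_collection(small_synth_cfg(8))
  x <- sim$collection
  set.seed(99)
  perm <- sample(length(x))
  x_shuf <- pathway_collection(x$pathways[perm], universe = x$universe)
  a <- condense_collection(x)$collection
  b <- condense_collection(x_shuf)$collection
  expect_setequal(pathway_ids(a), pathway_ids(b))
  for (id in pathway_ids(a)) {
    expect_setequal(a$pathways[[id]]$genes, b$pathways[[id]]$genes)
  }
})

test_that("survivor keeps the larger pathway's identity", {
  x <- make_collection(Bsmall = genes(5), Abig = genes(6))
  res <- condense_collection(x)  # symmetric difference 1 -> c2
  expect_identical(pathway_ids(res$collection), "Abig")
  expect_identical(res$collection$pathways$Abig$provenance, "Bsmall")
  # equal sizes: lexicographically smaller id survives
  y <- make_collection(Zed = genes(4), Alpha = genes(4))
  res_y <- condense_collection(y)
  expect_identical(pathway_ids(res_y$collection), "Alpha")
})

test_that("small-pathway exclusion applies the strict <3 boundary", {
  x <- make_collection(P2 = genes(2), P3 = genes(3), P0 = genes(5))
  out <- exclude_small(x)
  expect_setequal(pathway_ids(out), c("P3", "P0"))
  expect_identical(attr(out, "removed"), "P2")
  expect_identical(length(exclude_small(pathway_collection())), 0L)
  expect_identical(length(exclude_small(x, min_genes = 6)), 0L)
})
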