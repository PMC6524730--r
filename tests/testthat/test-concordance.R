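test_that("activity overlap follows the shared-over-either definition", {
  expect_equal(activity_overlap(c("c1", "c2"), c("c1", "c2")), 1)
  expect_equal(activity_overlap(c("c1", "c2"), c("c3", "c4")), 0)
  expect_equal(activity_overlap(c("c1", "c2", "c3"), c("c2", "c3", "c4")), 0.5)
  expect_error(activity_overlap(character(), character()), "undefined")
})

test_that("activity overlap agrees with the gene-set similarity score", {
  set.seed(19)
  pool <- sprintf("c%03d", 1:40)
  for (i in 1:50) {
    a <- sample(pool, sample(1:20, 1))
    b <- sample(pool, sample(1:20, 1))
    expect_identical(activity_overlap(a, b), pathway_similarity(a, b))
  }
})

test_that("identical activity columns over one pathway are degenerate", {
  x <- make_collection(P = genes(5))
  m <- matrix(rep(c(1L, 0L, 1L), 3), ncol = 3,
              dimnames = list(c("c1", "c2", "c3"), c("a1", "a2", "a3")))
  amap <- setNames(rep("P", 3), c("a1", "a2", "a3"))
  expect_error(sharing_activity_correlation(m, amap, x), "degenerate")
})

test_that("too few usable pairs and unmapped assays are rejected", {
  x <- make_collection(P = genes(5), Q = genes(5, "h"))
  m <- matrix(c(1L, 0L, 0L, 1L), ncol = 2,
              dimnames = list(c("c1", "c2"), c("a1", "a2")))
  expect_error(sharing_activity_correlation(m, c(a1 = "P", a2 = "Q"), x),
               "at least 3")
  expect_error(sharing_activity_correlation(m, c(a1 = "P"), x), "not mapped")
  expect_error(sharing_activity_correlation(m, c(a1 = "P", a2 = "Zed"), x),
               "absent")
})

test_that("pairs with no actives in either assay are excluded with a count", {
  # a4 and a5 have no active compounds at all: only the (a4, a5) pair has an
  # empty union of actives, so exactly one pair is undefined and excluded
  x <- make_collection(P1 = c("q", "a"), P2 = c("q", "b"), P3 = c("a", "b"),
                       P4 = c("q", "z"), P5 = c("a", "z"))
  m <- cbind(a1 = c(1L, 1L, 0L, 0L), a2 = c(1L, 0L, 1L, 0L),
             a3 = c(0L, 1L, 1L, 0L), a4 = c(0L, 0L, 0L, 0L),
             a5 = c(0L, 0L, 0L, 0L))
  rownames(m) <- sprintf("c%d", 1:4)
  amap <- setNames(paste0("P", 1:5), colnames(m))
  expect_warning(res <- sharing_activity_correlation(m, amap, x), "excluded")
  expect_identical(res$n_excluded, 1L)
  expect_identical(res$n_pairs, 9L)
  # an all-zero assay paired with an active one is defined, with overlap 0
  a14 <- res$pairs[res$pairs$assay_a == "a1" & res$pairs$assay_b == "a4", ]
  expect_equal(a14$activity_overlap, 0)
})

test_that("r is invariant to compound and assay permutations", {
  cfg <- concordance_cfg(41, n_compounds = 400L)
  sim <- generate_collection(cfg)
  amap <- synth_assay_map(sim$collection, cfg$n_assays)
  m <- generate_activity(cfg, amap, sim$collection)
  r0 <- sharing_activity_correlation(m, amap, sim$collection)$r
  set.seed(2)
  m_perm <- m[sample(nrow(m)), sample(ncol(m))]
  r1 <- sharing_activity_correlation(m_perm, amap, sim$collection)$r
  expect_equal(r1, r0, tolerance = 1e-12)
})

test_that("a planted sharing effect produces a positive correlation", {
  res <- run_concordance(concordance_cfg(7))
  expect_gt(res$r, 0)
  expect_lt(res$p_value, 0.05)
  expect_identical(res$n_pairs, 300L)  # choose(25, 2)
})

test_that("the spearman variant runs and agrees in sign", {
  cfg <- concordance_cfg(9, n_compounds = 500L)
  sim <- generate_collection(cfg)
  amap <- synth_assay_map(sim$collection, cfg$n_assays)
  m <- generate_activity(cfg, amap, sim$collection)
  rp <- sharing_activity_correlation(m, amap, sim$collection)$r
  rs <- sharing_activity_correlation(m, amap, sim$collection,
                                     method = "spearman")$r
  expect_gt(rp, 0); expect_gt(rs, 0)
})

test_that("the conditional correlation restricts to high-sharing pairs", {
  # hand-built: 5 assays over pathways with graded sharing
  base <- genes(10)
  x <- make_collection(P1 = base, P2 = base,                       # s = 1
                       P3 = c(base[1:6], genes(4, "h")),           # s ~ 0.43
                       P4 = genes(10, "k"), P5 = genes(10, "m"))   # disjoint
  set.seed(3)
  m <- matrix(rbinom(100 * 5, 1, 0.3), ncol = 5,
              dimnames = list(sprintf("c%03d", 1:100), sprintf("a%d", 1:5)))
  amap <- setNames(paste0("P", 1:5), colnames(m))
  res <- sharing_activity_correlation(m, amap, x, threshold = 0.2)
  expect_identical(res$n_pairs_conditional,
                   sum(res$pairs$gene_sharing > 0.2))
  expect_lte(res$n_pairs_conditional, res$n_pairs)
})
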