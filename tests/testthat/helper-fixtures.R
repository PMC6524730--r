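# Shared fixtures and independent oracles for the test suite.

# Independent hypergeometric tail oracle: direct summation of
# C(K, i) C(N-K, m-i) / C(N, m) over i >= k. Deliberately avoids phyper so it
# can serve as a cross-check of the implementation's Fisher p-values.
brute_hyper_tail <- function(k, K, m, N) {
  hi <- min(K, m)
  if (k > hi) return(0)
  i <- max(k, 0L):hi
  sum(choose(K, i) * choose(N - K, m - i)) / choose(N, m)
}

# toy collections -----------------------------------------------------------

make_collection <- function(...) {
  sets <- list(...)
  ids <- names(sets)
  pathway_collection(lapply(seq_along(sets), function(i) {
    pathway(ids[i], sets[[i]])
  }))
}

genes <- function(n, prefix = "g") sprintf("%s%02d", prefix, seq_len(n))

# random small cover instance (deterministic under the caller's seed)
random_cover_instance <- function(n_genes, n_pathways, size_range = 2:5) {
  gs <- sprintf("g%02d", seq_len(n_genes))
  pws <- lapply(seq_len(n_pathways), function(j) {
    pathway(sprintf("P%02d", j), sample(gs, sample(size_range, 1L)))
  })
  pathway_collection(pws)
}

geodesic_dist <- function(layout) {
  C <- tcrossprod(layout$coordinates)
  C[C > 1] <- 1; C[C < -1] <- -1
  acos(C)
}

# small synthetic config used across tests (fast to generate)
small_synth_cfg <- function(seed, ...) {
  defaults <- list(seed = seed, n_base = 30L, universe_size = 800L,
                   n_exact_dup = 4L, n_near_dup = 4L, n_one_off = 4L,
                   n_small_subset = 4L, n_compounds = 300L, n_assays = 10L)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

# config for concordance studies: overlapping mid-size pathways, no planted
# redundancy, so gene sharing varies across assay pairs
concordance_cfg <- function(seed, sharing_effect = 0.5, n_compounds = 2000L) {
  synth_config(seed = seed, n_base = 25L, universe_size = 300L,
               size_range = c(20L, 40L), n_exact_dup = 0L, n_near_dup = 0L,
               n_one_off = 0L, n_small_subset = 0L, hub_size = 150L,
               hub_frac = 0.5, tag_prob = 0,
               n_compounds = n_compounds, n_assays = 25L,
               baseline_rate = 0.02, sharing_effect = sharing_effect)
}

run_concordance <- function(cfg) {
  sim <- generate_collection(cfg)
  amap <- synth_assay_map(sim$collection, cfg$n_assays)
  act <- generate_activity(cfg, amap, sim$collection)
  sharing_activity_correlation(act, amap, sim$collection)
}

# expected triggering criterion per merge, looked up from a generator ledger
# by the planted (derived) pathway id in the merge pair
merge_expected_criteria <- function(merge_log, ledger) {
  derived <- ifelse(merge_log$absorbed %in%
                      ledger$pathway_id[ledger$class != "base"],
                    merge_log$absorbed, merge_log$surviving)
  ledger$expected_criterion[match(derived, ledger$pathway_id)]
}
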