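# pathcondense

Toolkit for integrating multi-source collections of biological pathways
treated as gene sets. Pooling public pathway databases produces heavy
redundancy — exact duplicates, >90%-overlap near-duplicates, fragments — and
`pathcondense` provides the algorithms for turning such a pool into a
non-redundant, annotated, experimentally probeable pathway universe:

- **Similarity & redundancy statistics** — pairwise gene-component similarity
  `s(A,B) = |A∩B| / |A∪B|` (shared genes over total unique genes) and
  collection-level duplicate/close-match/size summaries.
- **Condensation** — iterative merging to a fixpoint under four criteria:
  (1) overlap > 0.9; (2) the two gene sets differ by exactly one gene;
  (3) one pathway has < 3 genes, all contained in the other; (4) overlap
  > 0.5 with one-sided Fisher's exact `p < 0.05` over the gene universe.
  Deterministic highest-overlap-first merge order, union gene sets, full
  provenance, plus small-pathway exclusion (< 3 genes).
- **Automated tagging** — a 51-tag functional vocabulary in seven categories;
  a tag is assigned when ≥ 10% of a pathway's genes *and* ≥ 4 genes carry it,
  and/or when a lexicon keyword matches the title on word boundaries.
- **Assay panel design** — greedy minimal gene cover: rank genes by pathway
  participation (more pathways, then smaller pathways, first), optionally
  prioritising genes with available assays (Tox21 > NCATS > PubChem >
  commercial), and scan until every pathway contains a selected gene. An
  exhaustive small-instance oracle (`brute_force_cover`) certifies minimality
  in tests.
- **Enrichment** — per-pathway one-sided Fisher's exact over-representation
  of a query gene list, `p = P(X ≥ k)`, `X ~ Hypergeom(N, K, m)`, with
  Benjamini–Hochberg q-values.
- **Spherical layout** — seeded stress-minimising embedding on the unit
  sphere with geodesic distance targeting `(1 − s)·π`, so similar pathways
  sit close and disjoint ones antipodal.
- **Activity concordance** — Jaccard overlap of active-compound sets per
  assay pair, correlated against the gene sharing of the probed pathways.
- **Synthetic data** — a seeded generator planting all four redundancy
  classes, tag structure, and latent-target activity matrices, with a
  ground-truth ledger used as the oracle throughout the tests.

## Worked example

```r
library(pathcondense)

# a synthetic multi-source collection: 50 true pathways + 32 planted
# redundant ones (8 each: exact duplicates, near duplicates, one-gene
# variants, tiny subsets)
cfg <- synth_config(seed = 42, n_base = 50, universe_size = 1500,
                    n_exact_dup = 8, n_near_dup = 8, n_one_off = 8,
                    n_small_subset = 8)
sim <- generate_collection(cfg)
redundancy_stats(sim$collection)
#> <redundancy_stats> over 82 pathways
#>   with a complete duplicate:       19.5%
#>   with a close match (s > 0.90):   58.5%
#>   with <=5 genes:                   9.8%
#>   with a single gene:               4.9%

res <- condense_collection(sim$collection)
res$report
#> <condensation_report> 82 -> 50 pathways (32 merges, 33 iterations)
#>   merges by criterion: c1: 24, c3: 8

merged <- exclude_small(res$collection)   # drop anything left with <3 genes
merged
#> <pathway_collection> 50 pathways, 1500 genes in universe
#>   gene-set sizes: min 6, median 28, max 50
```

Condensation recovered exactly the 50 planted base pathways: the 24
duplicates/variants merged by the >90%-overlap criterion (c1), the 8 tiny
subsets by the containment criterion (c3). A 12-gene panel suffices to touch
every surviving pathway, and a query drawn from one pathway's genes ranks
that pathway first with `p ≈ 3e-17`:

```r
greedy_cover(merged)
#> <cover_result> 12 genes cover 50 pathways (static-rank scan)

head(enrich(merged$pathways[[3]]$genes[1:10], merged)[ ,
     c("pathway_id", "k", "m", "K", "N", "p", "q")], 3)
#>   pathway_id  k  m  K    N            p            q
#> 1       B004 10 10 38 1500 3.065656e-17 1.532828e-15
#> 2       B026  2 10 20 1500 7.131978e-03 1.378937e-01
#> 3       B033  2 10 24 1500 1.021325e-02 1.378937e-01
```

`k` of `m` query genes fall among the pathway's `K` genes out of a
universe of `N`; `p` is the one-sided Fisher tail and `q` its
Benjamini–Hochberg adjustment.

## Command line

Every step is exposed as a subcommand of the `inst/cli/pathcondense`
Rscript (GMT in, TSV out, parameters echoed into report headers, atomic
writes, `--seed` fixes all randomness):

```sh
pathcondense simulate  --seed 1 --out-dir fixtures/
pathcondense condense  --in fixtures/collection.gmt --out merged.gmt --report report.tsv
pathcondense tag       --in merged.gmt --gene-tags fixtures/gene_tags.tsv --out tags.tsv
pathcondense cover     --in merged.gmt --out panel.tsv
pathcondense enrich    --genes query.txt --in merged.gmt --out enrichment.tsv
pathcondense embed     --in merged.gmt --seed 17 --iters 500 --out layout.tsv
pathcondense concordance --activity fixtures/activity.tsv \
    --assay-map fixtures/assay_map.tsv --in fixtures/collection.gmt --out conc.tsv
```

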