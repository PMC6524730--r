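---
title: "Condensing, tagging, and probing a pathway universe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condensing, tagging, and probing a pathway universe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcondense)
```

## The problem

Public pathway databases (KEGG, Reactome, WikiPathways, BioCarta and their
kin) annotate overlapping slices of human biology. Pooling them yields a
collection in which a large fraction of entries are exact duplicates, near
duplicates, or fragments of one another, and in which many "pathways" carry
only one or two genes — artifacts of incomplete curation rather than real
biology. `pathcondense` treats each pathway purely as a gene set and provides
the algorithmic toolkit for working with such a pooled collection: measuring
redundancy, condensing it to a non-redundant core, categorising the survivors,
designing a minimal assay panel over them, testing gene-list enrichment
against them, laying them out on a sphere, and validating the panel-design
premise against screening data. A seeded synthetic generator with a
ground-truth ledger makes every one of those steps testable offline.

## Similarity and the four merge criteria

The similarity between pathways $A$ and $B$ is the Jaccard index of their
gene sets,

$$ s(A, B) = \frac{|A \cap B|}{|A \cup B|}, $$

i.e. shared genes over total unique genes. $1 - s$ is a metric, which the
test suite verifies on random triples.

Condensation merges a pair of pathways when **any** of four criteria holds:

1. $s(A,B) > 0.9$ (strict);
2. the symmetric difference of the gene sets has size 1 ("differ by only one
   gene"; this is equivalent to one set being the other plus a single gene,
   which is why the `criterion2_mode = "containment"` spelling computes the
   same predicate);
3. one pathway has fewer than 3 genes, all contained in the other;
4. $s(A,B) > 0.5$ and a one-sided Fisher's exact test of the $2\times2$
   membership table over the gene universe gives $p < 0.05$.

All inequalities are strict. The Fisher table puts $|A|$ and $|B|$ on the
margins, the shared-gene count in the top-left cell, and the collection's
gene universe size $N$ as the background, and tests over-enrichment of
sharing — the only direction in which association supports merging. The
p-value is the hypergeometric upper tail; an exhaustive brute-force summation
over every table with $N \le 60$ (635,375 tables) agrees with the
implementation to below $10^{-12}$.

### Merge order and identity

The merging procedure is repeated until no pair meets any criterion. The
order of merges is not forced by the criteria, so the implementation fixes a
deterministic rule: at each step the qualifying pair with the **highest
overlap** merges first, ties broken by the lexicographically smallest id
pair. The merged gene set is the union; the survivor keeps the id and name of
the larger member (ties to the smaller id) and accumulates the absorbed id in
its provenance, which `write_gmt()` serialises into the GMT description field
so a merged collection round-trips through the standard format.

Merge order can matter at the margin. For a nested chain $A \subset B
\subset C$ with one-gene steps, highest-overlap-first merges $B$ and $C$
before $A$ can pair with $B$; over a realistic background universe the chain
still collapses to one pathway (criterion 4 catches $A$ against $B \cup C$),
but over a degenerate universe equal to the chain's own union, criterion 4
loses all power ($p = 1$ when the query spans the whole background) and the
fixpoint keeps two pathways. This is intended behaviour, not a bug: with a
background that small, "significant sharing" has no meaning.

Small-pathway exclusion (`exclude_small()`, default threshold: fewer than 3
genes) runs **after** condensation by default, because criterion 3 needs the
small fragments present to absorb them into their parents; a pre-filter flag
exists for collections where fragments are known noise.

## Automated tagging

Two rules assign functional-category tags from a 51-tag vocabulary grouped
into seven categories (major organ systems, metabolism, signaling, genetic
information processing, cell cycle, development, disease):

- **gene-based**: a tag is assigned when at least 10% of the pathway's genes
  *and* at least four genes carry that tag (both thresholds inclusive,
  evaluated per tag; multi-tag genes count toward each of their tags);
- **keyword**: lexicon keywords are matched case-insensitively on word
  boundaries against the pathway title, with hyphen and slash treated as
  boundaries so "HIV" matches inside "HIV-induced".

The gene-to-tag table is an input, not something the package derives from an
ontology: the mapping from high-level ontology terms to tags is inherently a
curation decision, and accepting it as a table keeps the thresholds — the
algorithmic content — fully testable. The shipped keyword lexicon is a
conservative starter set; note that "T cell" maps to "Immune system" since
the vocabulary carries no separate immune-response tag. Automated tagging of
this kind is known to over-assign (a subset of genes can carry a tag the
pathway as a whole does not deserve), so the output retains per-assignment
evidence — gene counts and fractions, or the matched keyword — to support
manual review.

## Minimal assay panels by greedy set cover

To probe every pathway with as few assays as possible, genes are ranked by
participation — more pathways first, then smaller mean pathway size, then
gene id — and the ranked list is scanned once, collecting each gene that
covers at least one not-yet-covered pathway, until all coverable pathways are
covered. When assay-availability annotations are supplied (sources in fixed
decreasing priority Tox21 > NCATS > PubChem > commercial), assayable genes
outrank all others, trading panel size for experimental feasibility.

Minimum set cover is NP-hard; the static scan is a deliberate, documented
reading of "go through the gene list", and an adaptive mode (classic greedy:
re-rank by residual coverage each step) is available behind a flag. An
exhaustive enumeration oracle (`brute_force_cover()`, refusing instances
beyond 20 genes) anchors the tests: on random small instances the greedy
panel is always a valid cover, never smaller than the true minimum, and
within the classic $1 + \ln d$ factor of it ($d$ = the largest number of
pathways any single gene covers). Prioritising assayable genes *usually*
costs panel size, but this is not a theorem — on a few percent of random
instances the reordering happens to find a smaller panel — so the package
documents the comparison as typical rather than guaranteed. Zero-gene
pathways are reported as uncoverable rather than failing the run, since the
tool must stand alone on un-condensed input.

## Enrichment

`enrich()` is the standard one-sided Fisher's exact over-representation test
per pathway — $p = P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, m)$ — with
Benjamini–Hochberg q-values across all pathways tested. Query genes outside
the universe are dropped **with a warning** and the effective query size is
reported; silently keeping them is the classic enrichment bug. The background
defaults to the collection universe and is overridable, since the right
background is a study-design question the tool cannot answer.

## The globe

The spherical layout places pathways on the unit sphere so that geodesic
distance tracks gene-set *dissimilarity*: the target distance for a pair with
similarity $s$ is $(1-s) \cdot \pi$, so identical pathways coincide and
disjoint ones are antipodal. (The alternative literal reading — more overlap,
more distance — would put every pathway's closest relatives on the opposite
side of the globe and defeat the display's purpose.) The optimizer minimises
a normalised Kruskal-type stress

$$ \sigma = \frac{\sum_{i<j} (g_{ij} - d_{ij})^2}{\sum_{i<j} d_{ij}^2},
   \qquad g_{ij} = \arccos(x_i \cdot x_j), $$

by projected gradient descent on the sphere with step halving whenever a step
would increase stress (so the recorded trace is monotone non-increasing),
4 random restarts, and fully seeded initialisation — the same seed reproduces
coordinates bit-for-bit.

Numerical notes: the $\arccos$ derivative is guarded near coincident and
antipodal pairs; a collection of all-identical pathways has zero target
norm and is given stress 0 by convention. Not every target configuration is
realizable — three mutually disjoint pathways ask for three pairwise
antipodal points, which do not exist, so their stress has a positive floor
(~0.11) while symmetry still forces an equilateral layout. Tests therefore
check the near-zero-stress contract on *realizable* symmetric targets (three
pathways pairwise sharing one of two genes: targets $2\pi/3$, an equilateral
triangle on a great circle) and only the distance-symmetry contract on the
disjoint triple.

## Activity concordance

If one assay can stand in for several gene-sharing pathways, assay pairs
probing similar pathways should flag overlapping sets of active compounds.
`sharing_activity_correlation()` computes, per assay pair, the Jaccard
overlap of active-compound sets and the gene sharing of the probed pathways,
and reports the Pearson correlation (Spearman behind a flag) with a two-sided
p-value, plus the correlation restricted to pairs sharing more than 20% of
genes. Pairs in which *neither* assay has any active compound are undefined
and excluded with a reported count; a pair where only one assay is silent is
a defined overlap of zero.

## The synthetic generator

`generate_collection()` emulates exactly the structures the algorithms are
built to find, each planted from a distinct base pathway and recorded in a
ledger that the tests treat as ground truth:

- 100 base pathways of 5–50 genes over a 2,000-gene universe, with a 50-gene
  hub pool contributing ~20% of each pathway so bases overlap mildly;
- planted exact duplicates ($s = 1$), near duplicates ($0.9 < s < 1$, made
  by swapping $k < n/19$ genes), one-gene-difference variants, and 1–2-gene
  subset pathways — 15 of each by default;
- optional planted tag structure: a tagged base has
  $\max(4, \lceil 0.1 n \rceil)$ of its collection-exclusive genes annotated
  with one vocabulary tag, so the tagging rule fires by construction;
- `generate_activity()` gives each of 2,000 compounds one latent target gene
  and calls it active in an assay with probability $0.02 + 0.5 \cdot
  [\text{target} \in \text{probed pathway}]$ (baseline chosen to mimic the
  low hit rates of quantitative high-throughput screens; effect size chosen
  so a 25-assay screen detects the association reliably). Setting the effect
  to 0 yields the null model used for calibration.

The ledger also records, per planted pathway, the merge criterion its
relation fires first (in the 1–4 precedence the condenser uses), computed
arithmetically from the planted sets at generation time. Condensing the
default configuration recovers exactly the 100 base pathways in every seed
tested, with merge-log criterion labels agreeing with the ledger for ~99.5%
of merges; the rare disagreements come from planted fragments that happen to
duplicate each other (two one-gene subsets landing on the same hub gene merge
with each other first, under a different criterion than either's ledger
entry).

What the generator deliberately does not emulate: real gene-identifier noise
(withdrawn/obsolete symbols, cross-species contamination), correlated
multi-source annotation bias, concentration–response artifacts in activity
calls, and the name semantics that drive manual curation. Passing the
recovery tests therefore shows the algorithms are correct on clean planted
structure, not that they reproduce any specific curated compendium, whose
published pathway counts also reflect manual editing that no algorithm
re-derives.

## Study sizes and calibration

The test suite and the acceptance script run, by design, at sizes a laptop
handles in seconds: 20-seed condensation sweeps of 160-pathway collections;
the exhaustive Fisher grid at $N \le 60$; 200 random cover instances within
the enumeration oracle's reach; 500 null seeds and 100 effect seeds for the
concordance calibration (type-I rate expected in $0.05 \pm 0.02$ by binomial
tolerance; power expected $\ge 95\%$). The null calibration is an honest
check, not a formality: the 300 assay-pair overlaps entering one correlation
share assays and are not independent, so the nominal t-based p-value could in
principle be miscalibrated; empirically it is not (measured type-I ~5–7%).

## Known limitations

- Condensation is quadratic in collection size per merge round; fine for the
  few-thousand-pathway scale it is built for, not for ontology-scale inputs.
- The one-sided Fisher background defaults to the collection universe; users
  whose assays probe a restricted gene space should pass their own.
- Greedy panels are tie-break-sensitive: equally ranked genes swap freely, so
  two runs agree in panel *size* and coverage but may differ in membership
  under a different tie rule. The shipped rule (gene id) is deterministic.
- The spherical layout is a visual aid: a 2-sphere cannot embed an arbitrary
  Jaccard-distance matrix isometrically, so stress is generally positive and
  only relative positions are interpretable.
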