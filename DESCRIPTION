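Package: pathcondense
Title: Redundancy Condensation, Tagging, and Assay-Panel Design for Gene-Set Pathway Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating multi-source collections of biological pathways
    treated as gene sets. Computes gene-component (Jaccard) similarity and
    collection-level redundancy statistics, condenses redundant pathways by
    iterating four merge criteria (including a one-sided Fisher's exact test) to a
    fixpoint, assigns functional category tags from gene annotations and title
    keywords, selects a minimal gene panel covering all pathways by greedy set
    cover with an exhaustive small-instance oracle, performs Fisher's exact
    gene-list enrichment with Benjamini-Hochberg control, embeds pathways on a
    sphere so geodesic distance tracks gene-set dissimilarity, and relates
    compound-activity overlap between assays to the gene sharing of the pathways
    they probe. A seeded synthetic-data generator with a ground-truth ledger makes
    every analysis testable without external downloads. Includes a command-line
    interface over GMT gene-set files and TSV annotation tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, optparse
Suggests: testthat (>= 3.0.0), yaml, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
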