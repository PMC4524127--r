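Package: phyloconflict
Title: Gene Tree Conflict, Concordance, and Duplication Mapping on Species Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes rooted homolog (gene-family) trees into rooted
    bipartitions and maps them onto a species tree as concordant,
    conflicting, or uninformative, with bootstrap-support filtering and
    support for partially overlapping taxon sets and multiple gene copies
    per taxon. Groups conflicting bipartitions into alternative topological
    statements, computes internode certainty (ICA) from the frequency
    distribution of the focal and conflicting bipartitions, detects and maps
    gene-duplication events in homolog trees by a shared-taxon criterion,
    and generates null distributions of conflict under the multispecies
    coalescent on an ultrametric species tree in coalescent units. Includes
    per-homolog summary statistics, a deterministic synthetic-fixture
    generator with planted conflict and duplications, and tab-delimited and
    newick exports of all per-node summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
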