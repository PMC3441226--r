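Package: coextree
Title: Gene Coexpression Trees, Ranked Neighbourhoods and Term Enrichment
Version: 0.1.0
Authors@R: person("Maintainer", "Anonymous", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds gene coexpression networks from probe-set by sample
    expression matrices. Provides trimmed-mean (MAS5-style) signal scaling,
    intensity-range quality control and hash-signature duplicate detection,
    tissue/series-balanced sample selection, pairwise Pearson correlation
    with Student-t significance and Bonferroni correction, Neighbour-Joining
    coexpression trees with Newick export, height-adjustable tree
    neighbourhoods around a driver probe set, hypergeometric annotation-term
    over-representation with Benjamini-Hochberg correction, and
    position-weight-matrix promoter scanning with core/matrix similarity
    scoring. A deterministic synthetic-data module generates expression
    matrices with planted coexpression modules, annotation catalogs with
    planted enriched terms, intensity sets with planted duplicates and
    promoters with planted motif sites, so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    digest,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
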