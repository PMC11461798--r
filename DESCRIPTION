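Package: phylonull
Title: Auditing Phylogenetic-Tree Defects in Null-Model Community Assembly Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how defects in the phylogenetic tree of a
    microbial metacommunity distort null-model community-assembly metrics.
    Implements the nearest taxon index (NTI) and beta nearest taxon index
    (bNTI) with tip-label-shuffling null models, a robust (median/MAD)
    detector for misclassified long-branch tips, full-versus-filtered
    community similarity comparisons (Bray-Curtis, Sorensen, weighted and
    unweighted UniFrac), a Mantel-correlogram phylogenetic-signal check, a
    sensitivity pipeline that tabulates how assembly conclusions change under
    outlier removal and metacommunity subsetting, and a synthetic-data
    generator with planted long-branch outliers for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    vegan,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    picante,
    phyloseq,
    jsonlite
Config/testthat/edition: 3
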