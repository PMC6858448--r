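Package: crisprome
Title: CRISPRome Amplicon Analysis: Spacer Extraction, Array Graphs and
    Virus-Borne Mini-CRISPR Array Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of deep-sequenced CRISPR spacer amplicons
    ("CRISPRomes") from microbial communities. Extracts spacers from
    repeat-anchored amplicon reads by degenerate IUPAC motif scanning,
    clusters them at 85% identity with free end gaps, summarises diversity
    (Good's coverage, Shannon entropy, Chao1), reconstructs CRISPR arrays
    from a directed graph of neighbouring-spacer pairs with a 5% edge-weight
    chimera filter, detects virus-borne mini-CRISPR arrays of 1-2 spacers
    with probabilistic completeness tests, maps spacers to protospacers with
    PAM inference and a simulation-based chi-square test that CRISPR
    targeting coincides with genome divergence, and assembles viral contigs
    by spacer tiling. A synthetic-community generator with planted ground
    truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    IRanges,
    igraph,
    stats,
    tools,
    utils
Suggests:
    withr,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan
LinkingTo:
    Rcpp
Config/testthat/edition: 3
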