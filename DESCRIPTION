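Package: npmine
Title: Neuropeptide Precursor Mining and Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Homology-based discovery and annotation of insect neuropeptide
    precursors from protein or transcript sequence sets. Provides
    signal-peptide prediction by a transparent hydrophobicity/(-3,-1) rule
    heuristic, prohormone-convertase cleavage-site calling from a tiered
    mono-/dibasic rule table, excision of mature peptides with amidation,
    pyroglutamate and cysteine annotation, neuropeptide-family classification
    by C-terminal consensus motifs and Smith-Waterman homology, ClustalX-style
    global alignment with conservation shading and sequence-logo statistics,
    neighbor-joining trees with bootstrap supports, and a synthetic precursor
    generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    yaml,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
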