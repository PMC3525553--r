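Package: mirnaome
Title: Small-RNA miRNAome Discovery and Four-Stage Tooth-Germ Expression Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-usable pipeline for small-RNA miRNAome discovery and
    short time-course expression analysis, modelled on developing minipig
    tooth germ. Implements the read-cleaning funnel (adapter stripping,
    collapsing to unique tags, length and copy-number filters, contaminant
    removal), six-group miRNA novelty classification with Nussinov-style
    stem-loop hairpin prediction from 60-nt genomic extensions, microarray
    signal analysis over four developmental stages (quantile normalization,
    detectability calls, ANOVA and pairwise tests, hierarchical clustering,
    signal-strength filtering), STC-style short time-series model-profile
    clustering with permutation significance, seed-match target prediction
    with cross-species conservation, GO/pathway hypergeometric enrichment,
    bipartite miRNA-gene network degree ranking with key-miRNA selection,
    and delta-delta-CT qPCR concordance validation. A synthetic-data module
    generates every pipeline input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    Biostrings,
    SummarizedExperiment,
    limma,
    igraph,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Transcriptomics, SmallRNA, Microarray, TimeCourse, NetworkInference
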