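Package: pgcMultiome
Title: Paired Single-Nucleus Multiome Analysis of Germ Cell Sex Determination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing paired single-nucleus RNA and ATAC (multiome)
    data from developing gonads, centred on the sex determination of
    primordial germ cells. Provides per-nucleus quality control and
    chromosomal-sex filtering, marker-rule population selection, per-modality
    and joint embeddings with graph clustering, Wilcoxon differential
    expression and accessibility testing, peak-to-gene linkage against a
    GC/accessibility-matched background null, position-weight-matrix motif
    scanning with GC-matched hypergeometric enrichment and per-cell motif
    activity deviations, a candidate transcription-factor and target-gene
    (gene regulatory network) inference flow, and a permutation
    ligand-receptor screen between supporting cells and germ cells. Includes
    a synthetic paired multiome generator with planted, recoverable
    regulatory structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    data.table,
    jsonlite,
    igraph,
    irlba,
    RANN,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
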