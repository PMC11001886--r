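Package: hbmultiome
Title: Single-Cell Multiome Analysis of Hepatoblastoma Differentiation States and Clonal Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the joint analysis of single-nucleus RNA and ATAC data
    from pediatric liver tumors. Implements classification of tumor nuclei
    along two differentiation axes (mesenchymal, and the liver-progenitor to
    hepatocyte continuum), detection of copy-neutral loss of heterozygosity
    from phased germline SNPs by an exact binomial test, genotyping of somatic
    mutations in single nuclei, reconstruction of genetic subclones and
    comparison of their phenotypes, differential chromatin accessibility with
    nucleotide-level chromatin-state and motif enrichment, chromVAR-style
    motif deviations, transposase footprint aggregation, composite
    transcription-factor scoring with peak-to-gene linking for gene
    regulatory network construction, and a principal-component regression
    variance decomposition. A synthetic multiome generator with known ground
    truth (cell states, subclones, LOH, planted regulons) makes every stage
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    knitr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
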