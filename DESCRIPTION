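Package: hyperchrom
Title: Hypergraph Analysis of Multi-Way Chromatin Contacts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constructs genomic hypergraphs from long-read multi-way
    chromatin contact data (Pore-C style), in which each sequencing read
    contributes one hyperedge joining the genomic bins it touches.
    Provides incidence-matrix construction at configurable resolution,
    pair-frequency filtering of spurious contacts, decomposition to
    Hi-C-like pairwise contact matrices, spectral quantification via a
    hypergraph Laplacian and its eigenvalue (von Neumann style) entropy,
    three hypergraph distance measures (Hamming, spectral, DeltaCon) with
    permutation significance against degree-matched random hypergraphs,
    and a transcription-cluster calling pipeline that integrates
    chromatin accessibility, RNA polymerase II binding, gene expression
    and transcription-factor binding-site tables to classify clusters as
    potential, common-TF, specialized, self-sustaining and core. A
    synthetic-data generator emulates all required inputs with planted
    transcription clusters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
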