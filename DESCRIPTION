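Package: trnscreen
Title: Core Transcription Factor Screening from Thermodynamic Regulatory
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds transcription-factor regulatory networks from
    transcriptomic snapshots, motif score matrices and
    chromatin-accessibility intervals. Open promoter and gene-body regions
    are derived from per-assay peak intervals, promoters are scanned with
    min-max normalised motif score matrices, and gene expression is
    propagated through a thermodynamic occupancy model with Lambert-W
    Michaelis-Menten protein degradation. Per-factor dissociation
    constants are fitted by gradient descent so that the model carries an
    initial expression state toward a reference state; factors whose
    constants move during fitting are reported as core factors, with
    activator and repressor digraphs exported from the derivative factors
    of the fit. A self-contained synthetic fixture generator with a known
    ground-truth network supports end-to-end testing.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'coretf.R'
    'model.R'
    'fit.R'
    'motifs.R'
    'regions.R'
    'fixtures.R'
    'pipeline.R'
    'trnscreen-package.R'
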