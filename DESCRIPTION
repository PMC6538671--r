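Package: ampliscan
Title: Design and Validation of Short Metabarcoding Markers with Conserved
    Flanks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for designing and validating short PCR markers for
    environmental-DNA metabarcoding. Scans multiple sequence alignments of
    reference panels for conserved primer-binding windows flanking a short
    variable core, evaluates candidate primers (nearest-neighbor melting
    temperature, G/C content, per-template mismatch profiles with wobble
    classification), quantifies the taxonomic resolution of the amplified
    region (p and Kimura two-parameter distances, bootstrapped
    neighbor-joining trees, ambiguity reports), and re-implements a
    six-step amplicon read-processing chain (pair merging, primer
    stripping, expected-error filtering, dereplication, abundance-skew
    denoising, identity-threshold taxonomic assignment). A built-in
    simulator generates planted-marker alignments and mock-community
    paired-end reads so the whole chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    Biostrings,
    IRanges,
    XVector,
    ape,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'ampliscan-package.R'
    'seqio.R'
    'thermo.R'
    'markerdesign.R'
    'simdata.R'
    'readpipe.R'
    'resolution.R'
    'cli.R'
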