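Package: plexscreen
Title: In Silico Evaluation of Multiplex PCR and Hybridization Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens multiplex PCR and probe-hybridization assay designs
    against user-supplied reference sequences. Locates every binding site of
    every primer and probe on both strands with up to a configurable number of
    mismatches (exact multi-pattern Aho-Corasick search with Hamming-ball
    expansion of mismatches and IUPAC degenerate bases), predicts all amplicons
    formed by any rightward/leftward primer combination within a maximum
    product size (including unintended cross-pair by-products), attaches
    probes falling inside amplicons, and evaluates oligonucleotide panels for
    self-dimers, cross-dimers and hairpins with nearest-neighbor
    thermodynamics (SantaLucia unified parameters with single internal
    mismatch extensions and salt correction). Results are written as
    deterministic CSV reports suitable for regression tracking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    methods,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Optional external search backends require NCBI BLAST+
    (blastn, makeblastdb) or bowtie on the PATH; the native backend has no
    system requirements.
Config/testthat/edition: 3
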