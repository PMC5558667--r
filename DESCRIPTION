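Package: bhlhfam
Title: Genome-Wide bHLH Transcription-Factor Family Analysis
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable, tested pipeline for genome-wide characterisation of
    basic helix-loop-helix (bHLH) transcription-factor families:
    mismatch-tolerant consensus-profile domain scanning, residue-rule
    DNA-binding classification, neighbor-joining phylogenetics with bootstrap
    subfamily extraction, tandem and segmental duplication detection with
    Nei-Gojobori (1986) Ka/Ks estimation and synonymous molecular-clock
    dating, exon-intron pattern typing, promoter IUPAC motif scanning,
    physicochemical profiling, and expression / qPCR quantification.  A
    synthetic-data generator with a machine-readable truth ledger makes every
    stage exercisable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
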