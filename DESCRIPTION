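Package: lucitrace
Title: Transgene Insertion-Site Mapping and Luciferase Reporter Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects and counts reporter-transgene insertion sites from
    paired-end whole-genome sequencing evidence (chimeric split reads with a
    minimum junction overhang, corroborated by discordant read pairs),
    estimates per-genome transgene abundance from sequencing depth ratios
    standardized for aneuploid karyotypes, performs in-silico PCR validation
    of reporter constructs, and computes bioluminescence reporter calibration
    and stability statistics (per-cell slopes, DNA-normalized co-culture fold
    changes, delta-delta-Ct expression). Includes simulators for host genomes
    with planted insertions, paired-end reads, and plate assays, so every
    stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
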