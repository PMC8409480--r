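Package: coligor
Title: Cross-Contamination Tracing, Dual-Index Demultiplexing, and
    Spike-In Normalization for Amplicon Sequencing Plates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Laboratory informatics for highly multiplexed amplicon
    (16S/ITS) sequencing on 96- and 384-well plates. Designs
    variable-length dual-index molecular identifiers (MIDs) and
    error-correcting 13-nt cross-contamination checking oligonucleotides
    ("coligos"); demultiplexes paired-end reads carrying inline
    variable-length dual indexes anchored by locus primers; quantifies
    per-well cross-contamination from coligo counts, including spatial
    distance profiles and plate-rotation checks; normalizes compositional
    feature tables by an internal standard (ISD) spike-in to recover
    abundance-proportional scales; and simulates plates, contamination
    events, and paired FASTQ reads so every analysis has a closed-loop
    test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
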