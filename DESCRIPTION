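Package: oligobench
Title: Standardized Benchmarking of DNA Data-Storage Codecs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale benchmarking framework for DNA data-storage
    codecs. Simulates the DNA data-storage error channel (independent
    per-position substitutions, deletions and insertions, and a
    multi-stage synthesis/PCR/dilution/sequencing workflow with high-
    and low-fidelity presets), reduces simulated reads to consensus
    sequences by naive or MinHash clustering with star-alignment
    consensus calling, and provides reference codecs embodying the
    inner/outer code-separation strategy (a no-ECC baseline, a
    Reed-Solomon inner/outer codec over GF(256), and an LT fountain
    codec with error-detecting droplets). A benchmarking harness runs
    resource-limited decode trials, estimates 95%-success parameter
    thresholds by a three-stage adaptive scan with logistic regression,
    builds Pareto fronts over pairs of workflow parameters, and
    replicates common literature protocols (serial dilution, serial
    amplification, read down-sampling). Storage-density and error-rate
    accounting utilities complete the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
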