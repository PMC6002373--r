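Package: stmtrack
Title: Combinatorial Spike-In Sample Tracking for 16S Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design, simulation and analysis of combinatorial spike-in
    sample tracking mixes (STMs) for 16S rRNA gene amplicon sequencing
    quality control. Enumerates k-subset STMs from a spike-in panel,
    constructs multi-well plate layouts in which adjacent wells share no
    spike-in controls, calls STMs from per-sample read count tables to
    verify sample identity and resolve swaps, traces and quantifies
    cross-contamination from minority STMs, analyses source
    resolvability of an STM set, classifies amplicon reads against
    spike-in references by global alignment identity, and simulates
    realistic spike-in experiments (multinomial counts, GC-dependent
    amplification bias, admixtures, label swaps, index cross-talk) for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
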