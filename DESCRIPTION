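Package: nucpattern
Title: Nucleosome Positioning from Position-Specific k-mer Sequence Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Learns 301-bp position-specific k-mer frequency patterns from
    DNA sequences aligned at nucleosome dyads, converts sequence windows into
    pattern-correlation and k-mer-count features, and weights them with a
    linear support vector machine into a local dyad score. Includes a
    triangle-kernel dyad caller for fully sequenced MNase reads, ROC-based
    dyad-versus-linker evaluation with leave-one-chromosome-out
    cross-validation, an empirical null model for pattern significance,
    inter-dyad spacing analysis against a geometric null, pattern-variant
    partitioning, and a seeded synthetic-genome generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
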