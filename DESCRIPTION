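Package: prercoloc
Title: Windowed Co-Localization and Signal Profiling of Pre-Replication-Complex Peak Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Genome-wide analysis of pre-replication-complex (pre-RC) binding
    sites from interval and read data: moving-average coverage tracks with
    reads-per-million (RPM) normalization, ratio-to-input and input-subtraction
    schemes, windowed co-localization of peak sets against length-preserving
    shuffled nulls with chi-square tests, nested peak-set selection
    (A_w0.5_B notation), TSS-proximity tests, anchor-centered aggregation and
    metagene profiles, and two-condition FAIRE open-chromatin comparison.
    Includes a deterministic synthetic-data generator (peak sets with
    controlled co-localization fractions, enriched read sets with matched
    inputs, knockdown conditions, gene annotations) so the whole pipeline is
    testable without external sequencing data, and a one-configuration
    pipeline driver with reproducible seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    IRanges,
    S4Vectors,
    optparse
Config/testthat/edition: 3
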