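Package: cropscreen
Title: Pooled CRISPR Screen Informatics with UMI Clonal Tracking,
    Combinatorial Guides and Base-Editing Tiling
Version: 0.1.0
Authors@R:
    person("Screen", "Informatics", email = "screens@example.org",
           role = c("aut", "cre"))
Description: End-to-end informatics for pooled CRISPR screens in engineered
    T cells: a synthetic-data generator for clonal in vivo screens, stagger-aware
    guide counting from paired FASTQ reads, UMI-based clone estimation via
    knee-plot sigmoid fitting, internal-replicate construction from UMI prefixes,
    permutation-based enrichment statistics with SSMD screen-quality scoring,
    dual-guide (spacer-iBAR) recombination detection, and rule-based tiling
    base-editor library design with self-editing-aware quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
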