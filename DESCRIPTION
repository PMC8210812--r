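Package: viromock
Title: Mock Viromes and Benchmarking Metrics for dsDNA Virus Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates mock viromes and bulk metagenomes with ground truth by
    fragmenting labeled genomes into non-overlapping pieces and mixing them at
    prescribed class ratios, scores virus-identification tool output with a
    confusion-matrix metric suite (Matthews correlation coefficient, recall,
    false discovery, accuracy, F1, positive predictive value, specificity),
    evaluates virus taxonomy tools with clustering-wise sensitivity, PPV,
    accuracy and separation plus genus-assignment and distance-matrix
    degradation summaries, and triages candidate auxiliary metabolic genes
    (AMGs) on viral contigs with genomic-context rules. All inputs can be
    generated synthetically, so complete benchmarking studies run without any
    reference-database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
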