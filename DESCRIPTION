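Package: qtrimsim
Title: Simulating the Effect of Quality Trimming on Paired-End 16S Amplicon Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulation-and-evaluation framework for studying how right-side
    phred-quality trimming interacts with paired-end read merging in 16S rRNA
    V3-V4 amplicon sequencing. Generates reference amplicons delimited by
    degenerate primers, simulates 2x300 Illumina read pairs with realistic
    positional quality decay and phred-driven substitution errors alongside
    error-free gold-standard read sets, and runs them through primer trimming,
    Mott-style quality trimming, overlap merging with a
    percent-maximum-difference criterion, and mean-quality filtering. Recovered
    community compositions are scored against the per-sample gold standard via
    false-positive/false-negative OTU percentages and the Euclidean distance to
    the gold standard in principal coordinates space under the Jaccard
    distance.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    ape,
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
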