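Package: plasmidcn
Title: Plasmid Copy Number Estimation by Pseudoalignment and Iterative
    Multiread Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates plasmid copy number (PCN) from short sequencing
    reads by pseudoaligning reads against a multi-replicon reference with
    a colored k-mer index, and resolving reads that map to several
    replicons (multireads) with a probabilistic iterative read assignment
    EM algorithm. Includes a ground-truth read simulator for
    multi-replicon genomes carrying shared mobile elements, and the
    downstream scaling-law statistics: segmented (broken-line) log-log
    regression with breakpoint estimation, AIC model comparison, K-means
    size clustering, intragenomic length-copy-number correlation census,
    and plasmid DNA content scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    dplyr,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
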