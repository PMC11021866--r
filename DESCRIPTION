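Package: poolscan
Title: QTL-Seq Bulked Segregant Analysis with Pooled Index Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for QTL-seq (bulked segregant analysis by pooled
    whole-genome sequencing) of outbred F1 populations. Computes per-site
    SNP-index, InDel-index and delta-index statistics from pooled allele
    depths, applies the standard low-index/low-depth site filters, runs a
    sliding-window genome scan against simulation-based null confidence
    intervals, calls and merges candidate intervals, classifies variant
    location and coding consequence against gene models, and screens
    candidate genes by consequence tier. Includes descriptive quantitative
    genetics for the phenotype side (coefficient of variation, mid-parent
    value, mid-parent heterosis rate, extreme-pool screening) and a fully
    seeded synthetic data generator that emulates an F1 pseudo-testcross
    population with a planted fruit-size QTL, extreme phenotype pools and
    pooled short-read allele depths, so the whole pipeline is testable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    jsonlite,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
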