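Package: xreact
Title: Allele-Specific Analysis of X Chromosome Reactivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for calling X-linked gene reactivation from allele-resolved
    (Cast/EiJ vs C57BL/6) RNA-seq count tables in F1 hybrid mouse cells, and for
    relating reactivation to genomic and epigenomic context. Implements an
    informative-coverage filter, escapee calling from control allelic ratios, a
    per-gene beta-binomial likelihood-ratio test of allelic imbalance between
    conditions, per-gene feature extraction (promoter CpG density, SINE/LINE
    landscape around the TSS, distance to escapees, metagene signal profiles),
    per-TAD binomial enrichment of reactivated genes, MeD-seq-style promoter
    methylation analysis, and gene-list overlap statistics. Ships a synthetic
    data generator that plants a known class structure so the whole pipeline is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
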