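Package: txmap
Title: Sliding-Window Transcriptome Maps for Cross-Platform Expression Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds quantitative transcriptome maps from heterogeneous microarray
    studies. Probe-level expression from multiple datasets and platforms is
    linearized, quantile-normalized within each dataset, collapsed to gene
    symbols, median-scaled across datasets and pooled by study group. Pooled
    gene expression ratios between two groups are laid out on sliding genomic
    windows; each window is scored by the mean expression of its gene loci,
    and windows enriched for genes in the extreme tails of the ratio
    distribution are tested with a hypergeometric model against the genome-wide
    background and corrected by the Benjamini-Hochberg false discovery rate.
    Includes a seeded multi-platform study simulator with spike-in
    differential gene blocks for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
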