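Package: asmpath
Title: Allele-Specific-Methylation Weighted Pathway Analysis for GWAS
    Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pathway (gene-set) enrichment analysis of genome-wide
    association summary statistics that incorporates brain allele-specific
    methylation (ASM) information. Genes are scored by the minimum SNP
    p-value in a window around the gene, normalized for gene size by
    resampling, and partitioned into ASM and non-ASM subsets from a list
    of SNP-CpG regulatory pairs. A harmonic-average weighting scheme
    up-weights the subset with the larger proportion of informative genes,
    and three permutation-based set statistics (GSEA enrichment score,
    sum-statistic, sum-square-statistic) are computed with and without
    weights, with Benjamini-Hochberg FDR control. Includes a synthetic
    study generator, GO over-representation follow-up, an over-represented
    gene report, and a command-line pipeline.
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
    yaml,
    optparse,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
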