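Package: twinmeth
Title: Differential DNA Methylation Analysis for Bisulfite Sequencing of
    Twin Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for reduced representation bisulfite sequencing (RRBS)
    analyses of paired sample designs, in particular monozygotic twin pairs
    discordant for a condition such as trisomy 21.  Provides per-CpG
    methylation calling from cytosine count reports with coverage filters,
    bisulfite conversion and technical-replicate concordance metrics,
    annotation-driven region scoring (promoters, CpG islands and shores,
    exons, introns, LADs), promoter differential-methylation testing with
    pooled Fisher's exact tests and sliding-linear-model (SLIM) q-values,
    a multi-comparison filtering cascade for isolating condition-induced
    DMRs, metagene methylation profiles around gene models, and
    methylation-expression integration (quantile normalisation, fold
    changes, correlation, hypergeometric gene-set enrichment).  A
    beta-binomial simulator generates RRBS-like count data with planted
    differentially methylated regions so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
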