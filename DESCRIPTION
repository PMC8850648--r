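Package: xdosage
Title: X-Chromosome Dosage and Inactivation-Escape Analysis for Bulk and
    Single-Cell Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying X-chromosome dosage compensation in sex
    chromosome aneuploidies (47,XXY Klinefelter syndrome and higher-grade
    karyotypes up to 49,XXXXY). Implements allele-specific expression
    classification of SNPs and genes as biallelic or monoallelic with
    pseudoautosomal-region annotation and X-erosion flagging; bulk dosage
    statistics including the X:autosome expression ratio, male-median fold
    change and a loess moving average along the X chromosome; per-gene and
    per-module dosage-trend classification with co-expression module
    detection on a signed network; single-cell tests of XIST dosage and of
    the independence of escape-gene expression from XIST and cell-cycle
    phase; promoter position-weight-matrix scanning with Fisher's exact
    gene-coverage enrichment; and a synthetic-cohort generator encoding the
    expected dosage laws so the entire pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    yaml,
    jsonlite,
    vcfR,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
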