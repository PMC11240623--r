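Package: priorgs
Title: Genomic Selection with GWAS-Derived Prior Marker Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genomic prediction of quantitative traits with GBLUP mixed
    models whose genomic relationship matrix is informed by a prior
    genome-wide association scan.  Provides PLINK binary genotype input
    and quality control, a synthetic population generator with linkage
    disequilibrium and polygenic-plus-QTL trait architecture, an
    iterative fixed/random-model association scan in the FarmCPU style,
    VanRaden relationship matrices with variance-weighted multi-kernel
    blending, average-information REML, and five-fold cross-validated
    prediction accuracy against a plain-GBLUP baseline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
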