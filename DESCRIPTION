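Package: poolancestry
Title: Ancestry Estimation and Ancestry-Informative-Marker Discovery from
    Pooled-DNA SNP Array Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates per-SNP allele frequencies from pooled-DNA SNP array
    intensities by a polar transformation of genotype-cluster geometry,
    applies SNP-level quality-control filters tailored to pooled
    genotyping, estimates admixture proportions by least-squares regression
    of pooled allele frequencies on reference-panel frequencies, constructs
    admixture-weighted pseudopopulations, and identifies ancestry
    informative markers with a chi-square statistic deflated for pooling
    error variance.  Includes a synthetic-data generator (drifted reference
    panels, admixed cohorts, bivariate intensity clusters, noisy pool
    replicates) so the whole pipeline can be exercised with known ground
    truth, plus population-genetic evaluation utilities (F_ST, PCA with
    outlier removal, null maximum allele-frequency-difference simulation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
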