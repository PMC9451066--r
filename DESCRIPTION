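Package: aamix
Title: Archetypal Analysis for Population Structure and Ancestry Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fast unsupervised estimation of genetic clusters and ancestry
    fractions from diploid biallelic genotypes using Archetypal Analysis on
    singular-value-decomposition scores. Each individual is modelled as a
    convex combination of K archetypes, and each archetype as a convex
    combination of observed individuals, fitted by alternating constrained
    non-negative least squares. Includes genotype input from VCF or dosage
    matrices with minor-allele-frequency filtering, an admixture-model
    simulator with known ground truth, binary-assignment K-means and
    K-medoids reductions, compositional and stacked-bar ancestry plots, and
    a command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    ggplot2,
    jsonlite,
    optparse,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
Suggests: knitr, pracma, rmarkdown, testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
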