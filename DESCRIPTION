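Package: coassoc
Title: Gene-Gene Co-Association Testing via Partial Least Squares Path Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-based tests of gene-gene co-association for case-control
    genetic association studies. The core statistic contrasts the path
    coefficient between two gene-level latent variables, estimated by
    two-block partial least squares path modeling (Lohmoller algorithm,
    reflective measurement, centroid inner scheme) separately in cases and
    controls, standardizes the difference by bootstrap variances, and
    assesses significance by case/control label permutation. Also provides
    four benchmark tests (single-SNP logistic with min-p permutation
    adjustment, principal-component logistic interaction,
    first-canonical-correlation difference, and a covariance-difference
    statistic with Moore-Penrose fallback), readers for PLINK raw, VCF and
    haplotype panel text formats, and an LD-aware case-control genotype
    simulator for type-I-error calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    parallel,
    Rcpp,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
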