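Package: ordliab
Title: Ordinal-Trait QTL Mapping in Cultivar Panels via a Hierarchical
    Generalized Linear Mixed Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps main-effect QTL and QTL-by-environment interactions for
    ordinal phenotypes in panels of homozygous crop cultivars genotyped with
    multi-allelic markers. Observed grades are modelled through a probit
    threshold (liability) model; all allelic and allele-by-environment
    effects enter jointly as random effects with locus-specific variances
    under scaled inverse chi-square priors, estimated by an
    expectation-maximization empirical Bayes algorithm on a pseudo-data
    normal approximation of the ordinal likelihood. Detected loci are
    confirmed by a two-stage likelihood-ratio test on the exact ordinal
    likelihood and reported as LOD scores with the proportion of liability
    variance explained, elite alleles and their carriers, and predicted best
    parental combinations. A pedigree-based simulator of recombinant inbred
    lines from multi-allelic founder populations supports power and
    false-positive-rate studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), MASS, withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'liability.R'
    'io.R'
    'design.R'
    'ebfit.R'
    'ml.R'
    'inference.R'
    'simulate.R'
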