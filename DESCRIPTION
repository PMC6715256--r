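Package: mshtc
Title: First Coalescent Time Estimation from Maximum Shared Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood estimation of the first coalescent time (the
    number of generations back to the most recent common ancestor of a focal
    chromosome and any other sampled chromosome at a focal base) for every
    variant copy in phased population haplotype data, including singletons.
    Shared-haplotype tract lengths are extracted in linear time with the
    positional Burrows-Wheeler transform, converted to a composite
    mutation-plus-recombination event statistic using an arbitrary genetic
    map, and maximized under a coalescent likelihood that marginalizes over
    the unknown sister-branch length. Includes singleton phasing by relative
    coalescent-time, CpG-transition masking, and a coalescent-simulation
    validation harness with per-copy genealogical truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    vcfR,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: Python (>= 3.8) with msprime and tskit, required only for
    the coalescent-simulation validation functions.
Config/testthat/edition: 3
RoxygenNote: 7.3.3
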