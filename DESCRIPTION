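Package: gorillakin
Title: Kinship, Parentage and Dispersal Inference from Microsatellite
    Genotypes of Group-Living Primates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the genetic analysis of social structure and dispersal
    in one-male polygynous primates genotyped at codominant microsatellite
    loci. Implements pairwise relatedness estimation (Queller-Goodnight,
    Lynch-Ritland and Loiselle estimators) with allele-permutation
    significance, error-aware likelihood parentage assignment with
    simulation-calibrated confidence thresholds, dyadic relationship
    likelihood ratios, permutation tests for within-group and within-region
    kin structure and female-silverback relatedness, allele-size based R_ST
    differentiation with isolation-by-distance regression, behavioural
    proximity indices, and a forward population simulator with known pedigree
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
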