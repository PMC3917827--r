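Package: divaxes
Title: Climatic Niche, Morphological and Population-Genetic Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrated tools to quantify divergence between two groups of
    populations along three axes: climatic niche (principal-component
    difference-of-means statistics with permutation nulls and a Wilks lambda
    MANOVA), morphology (trait transforms, a structural-size index, factorial
    ANOVA, and AICc-ranked linear and quadratic climate regressions), and
    multilocus sequence variation (segregating sites, haplotype diversity,
    Watterson's theta, nucleotide diversity, Tajima's D, Hudson's Kst, fixed
    differences, Dxy, hierarchical AMOVA and mitochondrial amino-acid
    profiles). A seeded synthetic-data module, including a two-deme
    isolation-with-migration coalescent simulator with locus-specific
    inheritance scalars, generates datasets with the statistical structure
    the analyses assume, so the whole pipeline runs and is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
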