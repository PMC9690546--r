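Package: breedgate
Title: SNP-Based Breed Assignment at the Breed Boundary
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether a candidate dog (or any diploid
    individual) belongs to the reference population of a breed, using
    genome-wide SNP genotypes. Implements two standardized assignment
    scores anchored at 0 (the breed's most representative genome) and 1
    (the closest individual of the nearest related breed): an
    identity-by-state centrality score and a principal-coordinate distance
    to the breed median. Also provides the supporting pipeline: PLINK
    text import/export, dataset merging with call-rate filtering,
    per-marker Fst screening and composite-LD pruning to build
    breed-informative marker panels, block-mosaic admixture simulation
    for threshold calibration, a Rannala-Mountain/Paetkau inclusion
    probability comparator, a Balding-Nichols multi-breed genotype
    simulator, and an expanding reference-population assignment protocol
    driver.
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
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
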