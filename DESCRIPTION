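Package: domestiscan
Title: Genomic Signatures of Domestication in Wild and Selected Shellfish Strains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for contrasting wild populations with
    hatchery-selected strains using dense SNP-array genotypes. Implements
    quality filtering and LD clumping, per-population diversity indices and
    Ritland relatedness, pairwise Weir-Cockerham FST, LD-based effective
    population size with cross-chromosome locus pairing and jackknife
    confidence intervals, Hill-Weir LD-decay curve fitting with half-decay
    distances, sliding-window runs-of-homozygosity calling with genomic
    inbreeding coefficients, dual genome-scan outlier detection (trimmed
    FST-based and principal-component-based tests), Random-Forest backward
    purging of outlier panels with DAPC validation, hypergeometric term
    enrichment, and a forward Wright-Fisher simulator of wild populations and
    derived captive strains that serves as the pipeline's test substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    vcfR,
    randomForest,
    minpack.lm,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
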