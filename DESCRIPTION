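Package: altqtl
Title: Multi-Trait QTL Mapping for Aluminum Tolerance Trials in Sorghum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage analysis of biparental recombinant inbred line (RIL)
    trials for aluminum tolerance on acid soils. Stage 1 computes the
    hydroponic tolerance index (relative net root growth, RNRG) from seminal
    root measurements and fits per-design mixed models (randomized complete
    block, resolvable incomplete block) to obtain adjusted genotype means
    (BLUEs), variance components and line-mean heritability. Stage 2 is a
    multi-trait mixed-model QTL engine: simple and composite interval mapping
    by Wald tests on conditional QTL genotype probabilities, an
    eigenvalue-based effective-number-of-tests genome-wide threshold,
    backward elimination, per-trait allele-substitution effects and the
    percentage of genetic variance explained. A split-plot module analyses
    isogenic hybrid yield trials including an allele-dosage covariate test
    for additive gene action, and a calibrated synthetic-data generator
    emulates the full study design (90 RILs, 344 markers, two pleiotropic
    QTL, incomplete-block field trials, hydroponics and the 2x4 factorial
    hybrid trial) so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    MASS,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
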