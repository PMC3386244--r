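Package: introgressim
Title: Competitive Exclusion of Introgressed Genomic Segments: Simulation
    and Likelihood Inference
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Individual-based forward simulation of a neutral microsatellite
    marker linked to a selected incompatibility locus during multi-generation
    competition experiments between Drosophila simulans and D. sechellia
    introgression lines, with sex-limited (achiasmate-male) recombination and
    viability selection with dominance. Includes a grid-search maximum
    likelihood estimator of the selection coefficient and marker-locus
    recombination fraction from binned distributions of sampled marker
    frequencies, statistics for mating-success, fertility, and linkage
    disequilibrium assays, and a synthetic-data generator emulating the
    experimental design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
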