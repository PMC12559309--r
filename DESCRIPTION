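Package: paleoadmix
Title: Admixture Inference for Low-Coverage Ancient Genomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for ancestry analysis of pseudo-haploid ancient genomes
    against modern reference panels: EIGENSTRAT genotype I/O, pseudo-haploid
    calling and coverage downsampling from read pileups, outgroup f3 and D
    statistics with weighted block-jackknife standard errors, qpAdm-style
    admixture-proportion estimation with nested-model tests and a
    downsampling robustness experiment, admixture-LD decay dating of
    admixture events, least-squares PCA projection of damaged samples,
    read-count sex assignment and deamination profiling, and an
    admixture-graph simulator (Balding-Nichols drift plus ancestry-tract
    genomes) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
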