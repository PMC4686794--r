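Package: tatakit
Title: TBP-Promoter Affinity Prediction, Regulatory Variant Verdicts, and
    Binding Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based estimation of TATA-binding protein (TBP) affinity
    for core-promoter DNA (-ln KD with an uncertainty band), comparison of
    SNP alleles with a Z-score verdict (expression excess, deficiency or
    insignificant change), simulation and global fitting of pseudo-first-order
    TBP-DNA association kinetics with derivation of the apparent dissociation
    constant, complex half-life and Gibbs free energy, and the rank and linear
    correlation statistics used to confront predictions with electrophoretic
    mobility shift assay measurements. Ships the six 26-bp leptin and glucagon
    promoter probes and their measured rate constants as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    minpack.lm,
    jsonlite
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'model-config.R'
    'affinity.R'
    'compare.R'
    'correlation.R'
    'sequence-io.R'
    'fixtures.R'
    'kinetics.R'
    'tatakit-package.R'
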