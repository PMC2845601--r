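Package: tillkit
Title: Analysis of EMS Mutagenesis TILLING Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative analysis of TILLING (Targeting
    Induced Local Lesions IN Genomes) reverse-genetics screens of
    EMS-mutagenized plant populations. Provides per-amplicon and
    population-average mutation-density estimation with the Mendelian
    segregation correction for undetectable wild-type segregants,
    classification of induced substitutions into the six canonical
    base-pair-change classes, coding-effect annotation (silent, missense,
    nonsense, stop-loss) on CDS-annotated amplicons, a controlled-vocabulary
    phenotype catalog with validation and summaries, and a seeded forward
    simulator of pooled screens for estimator validation by parameter
    recovery. Ships the Red Setter tomato screen tables as worked example
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse
biocViews: Genetics, SNP, Sequencing, VariantAnnotation, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
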