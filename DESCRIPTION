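Package: digenica
Title: Digenic Co-Carrier Depletion Tests and Power Analysis for
    Population Cohorts
Version: 0.1.0
Authors@R:
    person("digenica", "maintainers", email = "digenica@example.org",
           role = c("aut", "cre"))
Description: Assess candidate digenic (two-locus) disease variant
    combinations in healthy population cohorts. Expected two-locus
    genotype counts are derived under Hardy-Weinberg equilibrium and
    linkage equilibrium from the two alternate-allele frequencies, and
    observed co-carrier counts are compared with a Pearson chi-squared
    goodness-of-fit test (collapsed four-category, 1 df, or full
    nine-class, 6 df). Includes a Monte-Carlo power simulator for
    incomplete-penetrance co-carrier depletion, per-sample carrier
    counting from multi-sample VCF files, a synthetic diploid cohort
    generator with a VCF writer, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
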