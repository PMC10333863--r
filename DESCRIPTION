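Package: coactivity
Title: Transcriptional Decomposition and Analysis of Gene Co-Activity Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes binned per-individual RNA-seq read counts into a
    positionally dependent co-activity component, modelled as a first-order
    random walk along each chromosome, and a positionally independent
    component, under a negative binomial observation model fitted by
    penalized maximum a posteriori estimation with Laplace posterior
    variances. On top of the fitted co-activity scores the package calls
    co-activity domains and variable co-activity domains, maps cis
    expression and co-activity quantitative trait loci with principal
    component covariates, prunes linked variants, summarises domain QTLs
    into a per-individual weighted allele score, selects predictive
    transcription factors by cross-validated random-forest importance, and
    partitions co-activity variance among transcription factor expression,
    local genotype, and enhancer interaction counts using type-II sums of
    squares with held-one-out significance tests. A synthetic-data
    generator with known ground truth supports recovery testing of every
    stage, and readers and writers for BED, bedGraph, VCF, GTF and TSV
    matrices tie the stages into a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    Matrix,
    MASS,
    ranger,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
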