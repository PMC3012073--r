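Package: strainHAM
Title: Haplotype Association Mapping for Inbred Strain Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: In-silico haplotype association mapping for panels of fully
    inbred laboratory strains. Provides strain-level phenotype
    summarization with exclusion handling, broad-sense heritability by
    one-way strain ANOVA (adjusted variance explained), strain-mean
    Pearson correlations, a sliding-window haplotype genome scan with
    relatedness-weighted ANOVA F statistics, permutation-based
    generalized family-wise error rate (gFWER) calibration with locus
    merging and strain-distribution-pattern matching, and a synthetic
    strain-panel generator with planted quantitative trait loci for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, GenomeWideAssociation, Software
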