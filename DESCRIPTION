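Package: sgemix
Title: Direct and Indirect (Social) Genetic Effects on Microbiome Phenotypes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Variance-component analysis of host genetic effects on
    microbiome composition in group-housed study designs. Implements
    restricted maximum likelihood (REML) fitting of linear mixed models with
    genetic, cage and maternal random effects; a direct plus indirect (social)
    genetic effects model in which cage mates' genotypes contribute to an
    individual's phenotype, with likelihood-ratio testing against a
    chi-square mixture null calibrated by parametric bootstrap; total
    heritable variance combining direct effects, indirect effects and their
    covariance; cross-cohort bivariate genetic correlations; genetic
    relatedness matrix construction with LD pruning and leave-one-chromosome-out
    support; mixed-model GWAS with permutation-derived significance thresholds;
    compositional (centred log-ratio) preprocessing of amplicon count tables;
    and a synthetic-data generator for family-structured genotypes, cage
    designs and phenotypes drawn from the exact model covariance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vcfR,
    biomformat,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'bivariate.R'
    'gwas.R'
    'io.R'
    'kinship.R'
    'preprocess.R'
    'reml.R'
    'sge.R'
    'sim-counts.R'
    'sim-design.R'
    'sim-genotypes.R'
    'sim-phenotype.R'
    'utils.R'
    'varcomp.R'
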