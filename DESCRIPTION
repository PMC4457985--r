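Package: ClineScreen
Title: Subgroup Allelic Screening, Multi-Locus Protective Scores and
    Altitude Clines
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Case-control style allelic association screening between
    phenotype-defined subgroups of a cohort using exact tests with
    false-discovery-rate control, an additive multi-locus protective-allele
    genotype score, logistic and multinomial regression of that score on
    subgroup or altitude class, and rank-correlation tests of score clines
    against population altitude. Includes readers for simple genotype tables
    and VCF, and a Hardy-Weinberg synthetic-cohort generator so every stage
    of the pipeline can be exercised and calibrated without access to
    restricted genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    nnet,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: SNP, GeneticVariability, StatisticalMethod, Genetics
RoxygenNote: 7.3.3
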