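Package: methStages
Title: Stage-Resolved Differential Methylation and Variability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering stage-specific and progression-associated
    DNA methylation changes in case/control methylome studies, modelled on
    multiple-myeloma mesenchymal stromal cell cohorts. Implements mean-based
    differentially methylated position (DMP) calling with empirical-Bayes
    moderated t-statistics on M-values, variance-based differentially
    variable position (DVP) calling by Bartlett's test regularized with a
    t-test (the iEVORA scheme), paired designs for co-culture experiments,
    disease-stage set algebra, CpG-island and chromHMM genomic-context
    enrichment, nearest-gene mapping, methylation-expression integration,
    RRBS coverage filtering, and a synthetic-data generator with planted,
    truth-tabled effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    limma,
    stats,
    utils,
    tools,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
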