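Package: pgspectrum
Title: Multi-Polygenic-Score Analysis of Psychosis-Spectrum Symptoms in Youth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the polygenic architecture of psychosis-spectrum
    symptoms (PS) in a multi-ancestry youth cohort: polygenic scoring from
    GWAS summary statistics by LD clumping and p-value thresholding or an
    infinitesimal-model LD adjustment, principal-component correction of
    scores within ancestry groups, elastic-net multi-PGS classification with
    repeated train/test evaluation and a permutation null, univariate PGS
    association with interaction, decile and sensitivity analyses, and
    phenotypic-overlap statistics. Includes a two-ancestry cohort simulator
    (Balding-Nichols allele-frequency divergence, blockwise autoregressive
    LD, liability-threshold phenotypes) so the whole pipeline is testable
    without access to controlled genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    Matrix,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
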