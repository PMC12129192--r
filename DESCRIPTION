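Package: adgcn
Title: Multi-Omics Patient-Similarity Graph Classification for Alzheimer's Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end multi-omics diagnostic modelling for Alzheimer's
    disease staging: SNP quality control and covariate-adjusted association
    scanning, polygenic risk scores by clumping-and-thresholding and the
    LDpred infinitesimal closed form, methylation marker selection with
    hybrid borderline-SMOTE/undersampling class balancing, three classical
    multi-omics integration baselines, and a patient-similarity graph
    neural network (graph-convolution plus GraphSAGE hidden layers) with
    cognitive-score edge weights. Includes a synthetic multi-omics cohort
    generator so the whole pipeline is exercisable without access-restricted
    clinical cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    ranger,
    class,
    rpart,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    xgboost,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
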