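Package: hybridDMR
Title: Hybrid Deep-Learning/Gradient-Boosting Prediction of
    Transgenerational DNA Methylation Regions
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts whether a 1000 bp genomic window is susceptible to
    becoming an environmentally induced transgenerational differentially
    methylated region (DMR, an epimutation). A two-block convolutional
    neural network is trained on one-hot encoded windows; the 32
    first-convolution-layer kernels are then used to re-express every
    window as a 32-dimensional feature vector that is classified by a
    gradient-boosted decision-tree ensemble (XGBoost). The package covers
    training-set construction from per-region differential-methylation
    p-value tables (positives: p < 1e-5 in any exposure; negatives:
    CpG-free windows), stratified fivefold cross-validation of the hybrid
    model, whole-genome scanning with BED output, conv-kernel motif
    visualization as position weight matrices with MEME export, and a
    fully seeded synthetic-data generator for end-to-end testing. The
    convolutional network (convolution, batch normalization, ReLU, max
    pooling, dropout, dense softmax head, Adam optimizer, early stopping)
    is implemented natively on BLAS-backed matrix operations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    xgboost,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Epigenetics, DNAMethylation, Classification, MachineLearning,
    Sequencing
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'nn-layers.R'
    'network.R'
    'features.R'
    'classifier.R'
    'windows.R'
    'dataset.R'
    'hybrid.R'
    'hybridDMR-package.R'
    'motifs.R'
    'scan.R'
    'synthetic.R'
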