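Package: gwasxplain
Title: Explainable Convolutional Neural Network Prioritization of
    Case-Control GWAS Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: End-to-end case-control genome-wide association analysis with
    deep-learning-based variant prioritization. Simulates genotype panels
    with Hardy-Weinberg structure, population stratification
    (Balding-Nichols model) and planted causal variants; applies standard
    genotype quality control; runs a covariate-adjusted per-SNP logistic
    association scan with principal-component correction; trains a small
    one-dimensional convolutional neural network to classify case status
    from p-value-thresholded SNP subsets; computes Deep SHAP (DeepLIFT
    rescale) per-SNP attributions; and aggregates them into a contribution
    score used to rank variants and re-evaluate prediction with top-k
    subsets. Includes readers and writers for VCF, PLINK text and
    tab-separated phenotype formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
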