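Package: chemtaste
Title: Bitter and Sweet Taste Prediction for Small Molecules
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for building and applying bitter/sweet taste
    classifiers for small molecules. Covers SMILES curation
    (canonicalization, salt stripping, peptide and size filters), open 2D
    physicochemical descriptor blocks and hashed circular fingerprints,
    all-relevant (Boruta) feature selection, PCA preprocessing, random
    forest / ridge logistic / AdaBoost classifiers under stratified
    cross-validation, threshold-independent evaluation (AUROC, average
    precision, non-error rate), nearest-neighbour applicability-domain
    assessment, and batch screening of chemical libraries with taste
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    ranger,
    glmnet,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'methods.R'
    'chemio.R'
    'chemtaste-package.R'
    'structure.R'
    'descriptors.R'
    'domain.R'
    'evaluation.R'
    'utils.R'
    'fingerprints.R'
    'selection.R'
    'models.R'
    'screening.R'
    'synthetic.R'
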