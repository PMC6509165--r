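# chemtaste

Bitter and sweet taste prediction for small molecules in R.

Bitterness and sweetness are the two taste qualities most relevant to drug
development and food science, and both are predictable to a useful degree
from two-dimensional molecular structure. `chemtaste` implements the full
quantitative structure–taste workflow as two independent binary tasks
(bitter vs. non-bitter, sweet vs. non-sweet):

* **Curation** — SMILES canonicalization (OpenBabel via `ChemmineOB`),
  salt/ion reduction to the largest organic fragment, minimum-size and
  peptide filters, duplicate pruning with label-conflict handling, and a
  reconciled curation log.
* **Features** — nine blocks of classical 2D physicochemical descriptors
  (constitution, topology, connectivity, kappa shape, Gasteiger charge,
  Burden/BCUT eigenvalues, E-state, MOE-type surface, bulk properties) plus
  hashed circular fingerprints (2048 bits, radius 2), with missing-value
  policies in `cleanFeatures`.
* **Selection** — all-relevant Boruta selection (shadow features, binomial
  test with Bonferroni correction) and standardized PCA preprocessing.
* **Models** — random forest (`ranger`), ridge logistic regression
  (`glmnet`), and AdaBoost over CART stumps, behind one `classifierSpec`
  interface, with stratified k-fold cross-validation and a
  sensitivity/specificity-balancing threshold calibration.
* **Evaluation** — rank-form AUROC (ties = 1/2), step-wise average precision
  (never trapezoidal), sensitivity/specificity/F1/NER with explicit
  degenerate-case flags.
* **Applicability domain** — nearest-neighbour distance check on the
  top-importance features (defaults k = 25, N = 5, delta = 3).
* **Screening** — batch prediction over chemical libraries with per-molecule
  failure capture and integer-percentage summaries.
* **Synthetic ground truth** — generators with planted signal for validating
  the selection/model stack, a version-pinned 40-molecule toy fixture, and
  binormal score/label pairs with a target AUROC.

## Worked example

Curate the built-in toy molecule set, featurize it, and cross-validate a
bitter classifier:

```r
library(chemtaste)

res <- curateDataset(makeToyMolecules())
res$log
#> CurationLog: 40 in, 34 retained ( 1 invalid, 2 duplicate, 1 salt/ion, 1 too small, 1 peptide )
res$dataset
#> TasteDataset with 34 molecules
#>   bitter: 7 positive / 22 negative
#>   sweet:  10 positive / 23 negative
#>   split:  0 train / 0 test / 34 unassigned

feats <- cleanFeatures(featurizeDataset(res$dataset, what = "descriptors"))
feats
#> FeatureTable: 34 molecules x 76 features
#>   blocks: burden(12), charge(11), connectivity(7), constitution(15), estate(8), moe_type(7), molecular_properties(6), topology(10)

labels <- tasteLabels(res$dataset, "bitter")
use <- labels != "unknown"
tab <- feats[which(use), ]
y <- as.integer(labels[use] == "positive")

spec <- classifierSpec("random_forest", list(num_trees = 300), seed = 1)
cv <- crossValidate(tab, y, spec, "none", k = 3)
cv
#> CVReport: 3 folds, random_forest + none
#>   pooled out-of-fold AUROC 0.792, AUPR 0.708

evaluateScores(cv@labels, cv@scores, threshold = 0.5)
#> MetricReport: AUPR 0.708 AUROC 0.792 F1 0.571 NER 0.7175 Sn 0.571 Sp 0.864 NA 0.0%
```

(29 labelled molecules is far too few for a real model — the toy fixture
exists to exercise the pipeline. On real training sets, fit with
`fitFinal()`, persist with `savePredictor()`, and batch-screen libraries
with `screenLibrary()`/`summarizeScreening()`.)

A thin command-line interface over the same functions ships in
`inst/scripts/chemtaste-cli.R` (subcommands `curate`, `featurize`, `select`,
`train`, `evaluate`, `screen`, `synth`). The methods are described in
`vignettes/taste-prediction.Rmd`.

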