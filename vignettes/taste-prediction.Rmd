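---
title: "Predicting bitter and sweet taste from molecular structure"
author: "chemtaste maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting bitter and sweet taste from molecular structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemtaste)
```

## The problem

Bitterness and sweetness are the two taste qualities with the clearest
pharmacological and nutritional consequences: bitterness often flags
toxicity and drives drug-compliance problems, while sweetness guides the
search for sugar substitutes. Both arise from the interaction of small
molecules with families of taste receptors, and both have been shown to be
predictable — to a useful degree — from two-dimensional molecular structure
alone. `chemtaste` implements a complete quantitative structure–taste
modelling workflow: data curation, feature generation, all-relevant feature
selection, classifier training under cross-validation, threshold-independent
evaluation, applicability-domain assessment, and batch screening of chemical
libraries.

The design follows the common shape of published taste-prediction studies:
two independent binary tasks (bitter vs. non-bitter, sweet vs. non-sweet),
each trained on experimentally labelled molecules plus tasteless and
opposite-taste controls as negatives.

## Curation

Raw taste datasets are lists of SMILES strings of mixed quality. `curateDataset`
applies, in order:

1. **Canonicalization.** Every SMILES is converted to a canonical form via
   OpenBabel (through `ChemmineOB`), so equivalent spellings (`CCO` vs.
   `C(C)O`, Kekulé vs. aromatic benzene) collapse to one key. OpenBabel is
   lenient with some malformed strings, so a bracket/parenthesis/ring-bond
   balance pre-check is applied first; genuinely unparseable records are
   logged as invalid, never raised as errors.
2. **Salt and ion reduction.** Disconnected structures are reduced to their
   largest carbon-containing fragment (e.g. sodium acetate to acetate);
   purely inorganic records (e.g. `[Na+].[Cl-]`) are removed.
3. **Size filter.** Molecules with fewer than 3 heavy atoms carry too little
   structure for 2D descriptors and are removed.
4. **Peptide filter.** Molecules containing at least two alpha-amino-acid
   residue units (`[NX3][CX4][CX3](=O)` matches) joined by an amide bond are
   removed: peptide sweeteners and bitter peptides follow sequence-driven
   structure–activity rules that a small-molecule model should not be asked
   to absorb. Single amino acids and simple amides are kept; a dipeptide is
   the smallest structure removed.
5. **Duplicate pruning** on canonical SMILES. The first record is kept;
   conflicting labels among duplicates reset the kept record's label to
   `unknown` for that task, with a warning.

Every removal is counted in a `CurationLog` whose fields must reconcile with
the input count; curation of an already-curated set removes nothing.

```{r curate}
res <- curateDataset(makeToyMolecules())
res$log
```

## Features

Two complementary feature families are available through
`featurizeDataset`.

**Descriptor blocks.** Nine blocks of classical 2D physicochemical
descriptors (83 features in total) are computed from the molecular graph:
constitution (atom/bond/ring counts), topology (Wiener, Harary, Balaban-J,
Zagreb, Platt indices and distance-matrix shape statistics), Kier–Hall
connectivity chi indices (simple and valence), kappa shape indices,
Gasteiger partial-charge statistics, Burden-matrix (BCUT) eigenvalues with
mass/charge/electronegativity weights, electrotopological state (E-state)
indices, MOE-type surface descriptors (Labute approximate surface area and
PEOE-binned van der Waals surface areas), and bulk properties (molecular
weight, logP, topological polar surface area, molar refractivity, hydrogen
bonding counts) from OpenBabel. The graph model (implicit hydrogens,
aromaticity, topological distances) and all descriptor formulas are
implemented in this package; structure parsing, SMARTS matching, Gasteiger
charges and the bulk properties come from `ChemmineR`/`ChemmineOB`. A block
that fails for a molecule marks its features missing rather than erroring;
`cleanFeatures` then drops features missing in more than a set fraction of
molecules (default 10%) and median-imputes the rest.

**Hashed circular fingerprints.** A binary, folded, Morgan-style circular
fingerprint (default 2048 bits, radius 2) is computed by iteratively hashing
each atom's environment from graph-intrinsic invariants (element, degree,
hydrogen count, formal charge, aromaticity, ring membership). The
implementation is self-contained and deterministic: the same structure
always sets the same bits regardless of input SMILES spelling.

## All-relevant feature selection

With a few thousand training molecules and hundreds to thousands of
features, taste models benefit from discarding features that carry no
signal at all while keeping *every* feature that does (all-relevant
selection, as opposed to minimal-optimal selection). `borutaSelect`
implements the shadow-feature scheme:

* In each of `nIterations` rounds (default 100), every feature is copied and
  the copy's values are permuted ("shadow" features), destroying any label
  association while preserving the marginal distribution. A random forest is
  fit on real plus shadow features and Gini (mean decrease in impurity)
  importances are collected.
* A feature scores a *hit* when its importance exceeds the maximum shadow
  importance of that round.
* After all rounds, a two-sided binomial test against p = 0.5 classifies
  each feature: significantly more hits than chance → confirmed,
  significantly fewer → rejected, otherwise tentative. The default applies a
  Bonferroni correction across features at alpha 0.05.

Unlike the progressive-dropping variant, all features stay in the matrix for
all iterations, which keeps the hit counts exchangeable and the binomial
test exact. Tentative features can be resolved by policy
(`resolveTentative`): compare their median importance against the median
round-maximum shadow importance (default), or simply include/exclude them.

`pcaFit`/`pcaTransform` provide the alternative preprocessing used with
fingerprints: standardized principal components retained up to a cumulative
explained-variance threshold (default 0.99). In cross-validation the PCA
rotation is refit inside each fold; Boruta selection, which is
computationally heavy and stable, is run once on the full training set
before folding.

## Models, validation, and evaluation

Three classifier families are wrapped behind one interface
(`classifierSpec`): random forests (via `ranger`, probability forests with
impurity importances), ridge-penalized logistic regression (via `glmnet`,
alpha 0), and discrete AdaBoost over depth-limited CART trees (implemented
here over `rpart`, with probabilities through the logistic link of the
ensemble margin). Random forests are the reference choice; the linear and
boosting baselines are kept to show the margin is model-independent.

`crossValidate` runs stratified k-fold cross-validation (default 5 folds)
in which every molecule is scored exactly once out-of-fold; everything is
deterministic given the spec's seed. Evaluation is deliberately
threshold-independent first: AUROC is computed in its rank (Mann–Whitney)
form with ties counted one half, and average precision (`auprScore`) is the
step-wise average of precision over recall increments at descending unique
score cuts — never trapezoidal interpolation, which is optimistic for
precision-recall curves. Threshold metrics (sensitivity, specificity,
precision, F1, and the non-error rate NER = (Sn + Sp)/2) call the cut
closed on the positive side; 0/0 cases return 0 with a `degenerate` flag so
batch sweeps complete. `calibrateThreshold` picks the decision cut that
balances sensitivity and specificity on pooled out-of-fold scores.

`fitFinal` ties it together: preprocess, train on all rows, calibrate the
threshold (unless given), and anchor an applicability domain.

## Applicability domain

A screening prediction is only trustworthy near the training data.
`buildDomain` keeps the k = 25 most important features, standardizes them by
training mean and standard deviation, and stores the training matrix;
`inDomain` declares a query in-domain when the median Euclidean distance to
its N = 5 nearest training molecules is at most delta = 3 (midpoint
convention for even N). The defaults are deliberately permissive: every
training molecule should be in its own domain, while a probe far outside
the training distribution fails the check. Membership is monotone in delta.

## Screening

`screenLibrary` pushes an arbitrary molecule library through featurization,
both predictors' domain checks, scoring and calling. Per-molecule failures
(unparseable structures, failed descriptors) are recorded with a reason and
excluded from tallies — never fatal. `summarizeScreening` reports integer
percentages of the in-domain count, rounded half away from zero, matching
the reporting convention of published library screens; a zero in-domain
denominator yields flagged NA percentages instead of a division.

A thin command-line interface over these functions ships in
`inst/scripts/chemtaste-cli.R` (subcommands `curate`, `featurize`,
`select`, `train`, `evaluate`, `screen`, `synth`).

## Synthetic data as study conditions

The `synthetic` module provides the ground-truth instruments the test suite
and acceptance script are built on:

* `makeClassificationTable` draws Gaussian class-conditional features:
  relevant features carry a standardized between-class mean shift
  (`effectSize`) at unit within-class variance; noise features are
  independent of the labels. This gives analytic control of Boruta's power:
  at n = 500 and effect size 2.0 a forest separates relevant from shadow
  importances essentially always, while effect size 0 is an exact null. A
  heavy-tailed t(3) variant is available for robustness checks.
* `makeToyMolecules` is a version-pinned 40-molecule SMILES fixture whose
  curation outcome is known by construction (one invalid, one inorganic
  salt, one too-small, one dipeptide, two duplicate spellings; 34 retained).
* `makeScoreLabelPairs` draws binormal score/label pairs whose expected
  AUROC equals a requested target (mean shift sqrt(2) * qnorm(target)).

Generator defaults are study conditions, not tuning knobs: they were fixed
before the validation results were inspected.

## Numerical conventions worth knowing

* Percentages: integer, half away from zero (not banker's rounding).
* Medians: midpoint convention for even counts, everywhere.
* AUROC ties: one half per tied positive–negative pair.
* Decision thresholds: closed on the positive side (score ≥ t is positive).
* All seeds are explicit; derived seeds stay below 2^31.

## Limitations

The package ships no experimental taste data: models are only as good as
the labelled sets supplied to them. Descriptors are 2D only —
conformation-dependent effects (and stereochemistry generally) are out of
scope. The applicability domain is a geometric heuristic, not a guarantee;
and the bitter/sweet tasks are modelled independently, so a molecule can
legitimately be called both.
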