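#' @import methods
NULL

.TASTE_LABELS <- c("positive", "negative", "unknown")
.SPLIT_LEVELS <- c("train", "test", "unassigned")

#' TasteDataset: a labelled collection of molecules
#'
#' Ordered set of molecule records for taste modelling. Each record carries an
#' identifier, the input SMILES, its canonical form (NA until computed or if
#' the structure is invalid), bitter/sweet labels in
#' \code{c("positive", "negative", "unknown")}, a free-text source tag and a
#' train/test split tag.
#'
#' @slot records data.frame with columns \code{id}, \code{smiles},
#'   \code{canonical_smiles}, \code{bitter_label}, \code{sweet_label},
#'   \code{source}, \code{split}.
#' @exportClass TasteDataset
setClass("TasteDataset", representation(records = "data.frame"))

.validTasteDataset <- function(object) {
    r <- object@records
    need <- c("id", "smiles", "canonical_smiles", "bitter_label",
              "sweet_label", "source", "split")
    msg <- character()
    if (!all(need %in% colnames(r)))
        msg <- c(msg, paste("missing record columns:",
                            paste(setdiff(need, colnames(r)), collapse = ", ")))
    else {
        if (anyDuplicated(r$id))
            msg <- c(msg, "molecule ids must be unique")
        if (!all(r$bitter_label %in% .TASTE_LABELS) ||
            !all(r$sweet_label %in% .TASTE_LABELS))
            msg <- c(msg, "labels must be positive/negative/unknown")
        if (!all(r$split %in% .SPLIT_LEVELS))
            msg <- c(msg, "split must be train/test/unassigned")
    }
    if (length(msg)) msg else TRUE
}
setValidity("TasteDataset", .validTasteDataset)

#' CurationLog: bookkeeping for molecule curation
#'
#' Counts of records removed by each curation filter. The counts reconcile:
#' \code{nRetained = nInput - nInvalid - nDuplicatesRemoved -
#' nSaltOrIonRemoved - nTooSmallRemoved - nPeptideRemoved}.
#'
#' @slot nInput,nInvalid,nDuplicatesRemoved,nSaltOrIonRemoved,nTooSmallRemoved,nPeptideRemoved,nRetained integer(1)
#' @exportClass CurationLog
setClass("CurationLog", representation(
    nInput = "integer", nInvalid = "integer",
    nDuplicatesRemoved = "integer", nSaltOrIonRemoved = "integer",
    nTooSmallRemoved = "integer", nPeptideRemoved = "integer",
    nRetained = "integer"))

setValidity("CurationLog", function(object) {
    v <- c(object@nInput, object@nInvalid, object@nDuplicatesRemoved,
           object@nSaltOrIonRemoved, object@nTooSmallRemoved,
           object@nPeptideRemoved, object@nRetained)
    if (any(v < 0)) return("curation counts must be non-negative")
    removed <- object@nInvalid + object@nDuplicatesRemoved +
        object@nSaltOrIonRemoved + object@nTooSmallRemoved +
        object@nPeptideRemoved
    if (object@nRetained != object@nInput - removed)
        return("curation counts do not reconcile")
    TRUE
})

#' FeatureTable: molecules-by-features matrix with block membership
#'
#' Real-valued feature matrix (rows = molecules, columns = named features)
#' together with a missing-value mask and a mapping from feature name to
#' descriptor block.
#'
#' @slot values numeric matrix with row and column names.
#' @slot missingMask logical matrix, same shape; TRUE marks a failed/missing
#'   value (the corresponding entry of \code{values} is then NA).
#' @slot blockOf named character vector mapping every feature to a block id.
#' @exportClass FeatureTable
setClass("FeatureTable", representation(
    values = "matrix", missingMask = "matrix", blockOf = "character"))

setValidity("FeatureTable", function(object) {
    v <- object@values; m <- object@missingMask
    msg <- character()
    if (!identical(dim(v), dim(m)))
        msg <- c(msg, "values and missingMask shapes differ")
    if ((ncol(v) > 0 && is.null(colnames(v))) || anyDuplicated(colnames(v)))
        msg <- c(msg, "feature names must be present and unique")
    else {
        if (!all(colnames(v) %in% names(object@blockOf)))
            msg <- c(msg, "every feature needs a block assignment")
        ok <- !m
        if (any(!is.finite(v[ok])))
            msg <- c(msg, "non-finite values at non-missing positions")
    }
    if (length(msg)) msg else TRUE
})

#' FingerprintConfig: hashed circular fingerprint settings
#'
#' @slot nBits integer(1), a power of two >= 64 (default 2048).
#' @slot radius integer(1), maximum circular-environment radius (default 2).
#' @exportClass FingerprintConfig
setClass("FingerprintConfig",
         representation(nBits = "integer", radius = "integer"))

setValidity("FingerprintConfig", function(object) {
    n <- object@nBits
    if (length(n) != 1L || n < 64L || bitwAnd(n, n - 1L) != 0L)
        return("nBits must be a power of two >= 64")
    if (object@radius < 0L) return("radius must be >= 0")
    TRUE
})

#' BorutaConfig: settings for all-relevant feature selection
#'
#' @slot nIterations integer(1) >= 10, number of shadow/importance rounds.
#' @slot alpha numeric(1) in (0,1), significance level of the binomial test.
#' @slot correction "bonferroni" or "none".
#' @slot tentativePolicy how tentative features are resolved on request:
#'   "include", "exclude", or "median_test".
#' @slot numTrees integer(1), forest size per iteration.
#' @slot seed integer(1) RNG seed.
#' @exportClass BorutaConfig
setClass("BorutaConfig", representation(
    nIterations = "integer", alpha = "numeric", correction = "character",
    tentativePolicy = "character", numTrees = "integer", seed = "integer"))

setValidity("BorutaConfig", function(object) {
    if (object@nIterations < 10L) return("nIterations must be >= 10")
    if (object@alpha <= 0 || object@alpha >= 1) return("alpha must be in (0,1)")
    if (!object@correction %in% c("bonferroni", "none"))
        return("correction must be bonferroni or none")
    if (!object@tentativePolicy %in% c("include", "exclude", "median_test"))
        return("unknown tentativePolicy")
    TRUE
})

#' BorutaResult: per-feature outcome of Boruta selection
#'
#' @slot status named character, one of confirmed/tentative/rejected per
#'   feature.
#' @slot hits named integer, iterations in which the real feature beat the
#'   best shadow feature.
#' @slot nIterations integer(1).
#' @slot importanceHistory numeric matrix, iterations x features, raw
#'   random-forest importances.
#' @slot shadowMaxHistory numeric, per-iteration maximum shadow importance.
#' @slot zScores named numeric, mean standardized importance per feature
#'   (importance centred/scaled by the shadow distribution of each round).
#' @slot config BorutaConfig used.
#' @exportClass BorutaResult
setClass("BorutaResult", representation(
    status = "character", hits = "integer", nIterations = "integer",
    importanceHistory = "matrix", shadowMaxHistory = "numeric",
    zScores = "numeric", config = "BorutaConfig"))

setValidity("BorutaResult", function(object) {
    if (!all(object@status %in% c("confirmed", "tentative", "rejected")))
        return("invalid status value")
    if (any(object@hits > object@nIterations))
        return("hit count exceeds iteration count")
    TRUE
})

#' PCAModel: centred, scaled principal-component decomposition
#'
#' @slot center,scaleFactor named numeric, per-feature standardization.
#' @slot loadings numeric matrix (features x components), orthonormal columns.
#' @slot explainedVarRatio numeric, non-increasing, sums to <= 1.
#' @slot nComponents integer(1), components retained.
#' @slot featureNames character, fitted feature order.
#' @exportClass PCAModel
setClass("PCAModel", representation(
    center = "numeric", scaleFactor = "numeric", loadings = "matrix",
    explainedVarRatio = "numeric", nComponents = "integer",
    featureNames = "character"))

setValidity("PCAModel", function(object) {
    r <- object@explainedVarRatio
    if (any(r < -1e-12)) return("explained variance ratios must be >= 0")
    if (is.unsorted(rev(r), strictly = FALSE) && any(diff(r) > 1e-12))
        return("explained variance ratios must be non-increasing")
    if (sum(r) > 1 + 1e-8) return("explained variance ratios sum to > 1")
    TRUE
})

#' ClassifierSpec: algorithm choice plus hyperparameters
#'
#' @slot algorithm "random_forest", "ridge_logistic" or "adaboost_trees".
#' @slot params named list of hyperparameters (see \code{classifierSpec}).
#' @slot seed integer(1) RNG seed for all stochastic components.
#' @exportClass ClassifierSpec
setClass("ClassifierSpec", representation(
    algorithm = "character", params = "list", seed = "integer"))

setValidity("ClassifierSpec", function(object) {
    if (!object@algorithm %in%
        c("random_forest", "ridge_logistic", "adaboost_trees"))
        return("unknown algorithm")
    TRUE
})

#' DomainReference: nearest-neighbour applicability domain
#'
#' Training rows restricted to the k most important features, standardized by
#' the training mean/SD. A query is in-domain when the median Euclidean
#' distance to its N nearest training rows is <= delta.
#'
#' @slot reference standardized training matrix (rows x k features).
#' @slot center,scaleFactor named numeric standardization statistics.
#' @slot k,N integer(1); \code{delta} numeric(1) > 0.
#' @slot featureNames the k retained feature names.
#' @exportClass DomainReference
setClass("DomainReference", representation(
    reference = "matrix", center = "numeric", scaleFactor = "numeric",
    k = "integer", N = "integer", delta = "numeric",
    featureNames = "character"))

setValidity("DomainReference", function(object) {
    if (object@N < 1L) return("N must be >= 1")
    if (object@delta <= 0) return("delta must be > 0")
    if (object@k != length(object@featureNames))
        return("k must match the number of retained features")
    TRUE
})

#' TastePredictor: a fitted taste classifier with its preprocessing
#'
#' @slot task "bitter" or "sweet".
#' @slot algorithm classifier family used.
#' @slot preprocessing "none", "boruta" or "pca".
#' @slot preprocessor fitted BorutaResult/PCAModel, or NULL.
#' @slot model opaque fitted classifier handle.
#' @slot featureNames input feature names expected, in training order.
#' @slot threshold numeric(1) in [0,1] decision cut on the probability.
#' @slot domain DomainReference or NULL.
#' @slot provenance list: spec, seed, training fingerprint, format version.
#' @exportClass TastePredictor
setClass("TastePredictor", representation(
    task = "character", algorithm = "character", preprocessing = "character",
    preprocessor = "ANY", model = "ANY", featureNames = "character",
    threshold = "numeric", domain = "ANY", provenance = "list"))

setValidity("TastePredictor", function(object) {
    if (!object@task %in% c("bitter", "sweet")) return("task must be bitter/sweet")
    if (object@threshold < 0 || object@threshold > 1)
        return("threshold must be in [0,1]")
    if (!length(object@featureNames)) return("feature list must be nonempty")
    TRUE
})

#' MetricReport: threshold-dependent and threshold-independent metrics
#'
#' @slot precision,sensitivity,specificity,f1,ner,auroc,aupr numeric(1) in
#'   [0,1] (NA when undefined, e.g. AUROC on one-class input is never built).
#' @slot naFraction numeric(1), fraction of molecules left unpredicted.
#' @slot degenerate logical(1), TRUE when a 0/0 metric was coerced to 0.
#' @exportClass MetricReport
setClass("MetricReport", representation(
    precision = "numeric", sensitivity = "numeric", specificity = "numeric",
    f1 = "numeric", ner = "numeric", auroc = "numeric", aupr = "numeric",
    naFraction = "numeric", degenerate = "logical"))

#' CVReport: stratified cross-validation outcome
#'
#' @slot folds list of validation-row index vectors (a partition).
#' @slot foldMetrics data.frame of per-fold metrics.
#' @slot scores pooled out-of-fold probabilities (training row order).
#' @slot labels binary labels (0/1) in the same order.
#' @slot spec ClassifierSpec used; @slot preprocessing character(1).
#' @exportClass CVReport
setClass("CVReport", representation(
    folds = "list", foldMetrics = "data.frame", scores = "numeric",
    labels = "integer", spec = "ClassifierSpec", preprocessing = "character"))

setValidity("CVReport", function(object) {
    idx <- sort(unlist(object@folds))
    if (!identical(idx, seq_along(object@scores)))
        return("folds must partition the training rows")
    TRUE
})

#' ScreeningSummary: library-level taste tallies
#'
#' Percentages are integer percents of the in-domain count, rounded half away
#' from zero; NA (with \code{flagged = TRUE}) when no molecule is in-domain.
#'
#' @slot nTotal,nInDomain,nBitter,nSweet,nBoth integer(1).
#' @slot pctBitter,pctSweet,pctBoth integer(1) or NA.
#' @slot flagged logical(1).
#' @exportClass ScreeningSummary
setClass("ScreeningSummary", representation(
    nTotal = "integer", nInDomain = "integer", nBitter = "integer",
    nSweet = "integer", nBoth = "integer", pctBitter = "integer",
    pctSweet = "integer", pctBoth = "integer", flagged = "logical"))

setValidity("ScreeningSummary", function(object) {
    if (object@nBoth > min(object@nBitter, object@nSweet))
        return("nBoth exceeds a marginal tally")
    if (object@nBitter > object@nInDomain || object@nSweet > object@nInDomain ||
        object@nInDomain > object@nTotal)
        return("tallies must nest: bitter/sweet <= in-domain <= total")
    TRUE
})
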