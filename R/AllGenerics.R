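#' @include AllClasses.R
NULL

#' Molecule identifiers of a dataset or table
#' @param x a TasteDataset or FeatureTable
#' @return character vector of ids in row order
#' @export
setGeneric("moleculeIds", function(x) standardGeneric("moleculeIds"))

#' Canonical SMILES of a dataset
#' @param x a TasteDataset
#' @return character vector (NA where not yet computed / invalid)
#' @export
setGeneric("canonicalSmiles", function(x) standardGeneric("canonicalSmiles"))

#' Taste labels for one task
#' @param x a TasteDataset
#' @param task "bitter" or "sweet"
#' @return character vector in positive/negative/unknown
#' @export
setGeneric("tasteLabels", function(x, task) standardGeneric("tasteLabels"))

#' Feature names of a table or model
#' @param x a FeatureTable, PCAModel, DomainReference or TastePredictor
#' @return character vector
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' Feature values matrix
#' @param x a FeatureTable
#' @return numeric matrix (NA at missing positions)
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' Missing-value mask
#' @param x a FeatureTable
#' @return logical matrix
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' Block membership of features
#' @param x a FeatureTable
#' @return named character vector feature -> block id
#' @export
setGeneric("featureBlocks", function(x) standardGeneric("featureBlocks"))

#' Features confirmed by Boruta
#' @param x a BorutaResult
#' @return character vector
#' @export
setGeneric("confirmedFeatures", function(x) standardGeneric("confirmedFeatures"))

#' Features left tentative by Boruta
#' @param x a BorutaResult
#' @return character vector
#' @export
setGeneric("tentativeFeatures", function(x) standardGeneric("tentativeFeatures"))

#' Features rejected by Boruta
#' @param x a BorutaResult
#' @return character vector
#' @export
setGeneric("rejectedFeatures", function(x) standardGeneric("rejectedFeatures"))

#' Decision threshold of a predictor
#' @param x a TastePredictor
#' @return numeric(1)
#' @export
setGeneric("decisionThreshold", function(x) standardGeneric("decisionThreshold"))

#' Class probabilities from a fitted taste predictor
#' @param object a TastePredictor
#' @param x a FeatureTable whose features cover the predictor's feature list
#' @return numeric vector of positive-class probabilities, one per row; NA for
#'   rows whose required features are missing (those rows are unpredicted,
#'   never defaulted)
#' @export
setGeneric("predictProba", function(object, x) standardGeneric("predictProba"))
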