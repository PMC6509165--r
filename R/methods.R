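#' @include AllClasses.R AllGenerics.R
NULL

## ---- TasteDataset ----------------------------------------------------------

#' Construct a TasteDataset
#'
#' @param id character vector of unique molecule ids
#' @param smiles input SMILES strings
#' @param canonical_smiles canonical SMILES (NA until computed)
#' @param bitter_label,sweet_label labels in positive/negative/unknown
#' @param source free-text provenance tag
#' @param split "train", "test" or "unassigned"
#' @return a \linkS4class{TasteDataset}
#' @export
TasteDataset <- function(id, smiles,
                         canonical_smiles = NA_character_,
                         bitter_label = "unknown", sweet_label = "unknown",
                         source = "", split = "unassigned") {
    n <- length(smiles)
    rec <- data.frame(
        id = as.character(id), smiles = as.character(smiles),
        canonical_smiles = rep_len(as.character(canonical_smiles), n),
        bitter_label = rep_len(as.character(bitter_label), n),
        sweet_label = rep_len(as.character(sweet_label), n),
        source = rep_len(as.character(source), n),
        split = rep_len(as.character(split), n),
        stringsAsFactors = FALSE)
    rownames(rec) <- NULL
    new("TasteDataset", records = rec)
}

#' Records of a TasteDataset as a data.frame
#' @param x a TasteDataset
#' @return data.frame in row order
#' @export
datasetRecords <- function(x) {
    stopifnot(is(x, "TasteDataset"))
    x@records
}

#' @describeIn TasteDataset number of molecules
#' @param x a TasteDataset
#' @export
setMethod("length", "TasteDataset", function(x) nrow(x@records))

#' @rdname moleculeIds
setMethod("moleculeIds", "TasteDataset", function(x) x@records$id)

#' @rdname canonicalSmiles
setMethod("canonicalSmiles", "TasteDataset", function(x) {
    structure(x@records$canonical_smiles, names = x@records$id)
})

#' @rdname tasteLabels
setMethod("tasteLabels", "TasteDataset", function(x, task) {
    task <- match.arg(task, c("bitter", "sweet"))
    col <- paste0(task, "_label")
    structure(x@records[[col]], names = x@records$id)
})

setMethod("[", "TasteDataset", function(x, i, j, ..., drop = FALSE) {
    initialize(x, records = {
        r <- x@records[i, , drop = FALSE]; rownames(r) <- NULL; r
    })
})

setMethod("show", "TasteDataset", function(object) {
    r <- object@records
    cat("TasteDataset with", nrow(r), "molecules\n")
    cat("  bitter: ", sum(r$bitter_label == "positive"), " positive / ",
        sum(r$bitter_label == "negative"), " negative\n", sep = "")
    cat("  sweet:  ", sum(r$sweet_label == "positive"), " positive / ",
        sum(r$sweet_label == "negative"), " negative\n", sep = "")
    cat("  split:  ", sum(r$split == "train"), " train / ",
        sum(r$split == "test"), " test / ",
        sum(r$split == "unassigned"), " unassigned\n", sep = "")
})

## ---- CurationLog -----------------------------------------------------------

setMethod("show", "CurationLog", function(object) {
    cat("CurationLog:", object@nInput, "in,", object@nRetained, "retained (",
        object@nInvalid, "invalid,", object@nDuplicatesRemoved, "duplicate,",
        object@nSaltOrIonRemoved, "salt/ion,", object@nTooSmallRemoved,
        "too small,", object@nPeptideRemoved, "peptide )\n")
})

#' Convert a CurationLog to a plain list (e.g. for JSON export)
#' @param x a CurationLog
#' @param ... ignored
#' @return named list of counts
#' @export
setMethod("as.list", "CurationLog", function(x, ...) {
    list(n_input = x@nInput, n_invalid = x@nInvalid,
         n_duplicates_removed = x@nDuplicatesRemoved,
         n_salt_or_ion_removed = x@nSaltOrIonRemoved,
         n_too_small_removed = x@nTooSmallRemoved,
         n_peptide_removed = x@nPeptideRemoved,
         n_retained = x@nRetained)
})

## ---- FeatureTable ----------------------------------------------------------

#' Construct a FeatureTable
#'
#' @param values numeric matrix with row (molecule) and column (feature) names
#' @param blockOf named character mapping each feature to a block id; a single
#'   unnamed string recycles to all features
#' @param missingMask logical matrix, defaults to \code{is.na(values)}
#' @return a \linkS4class{FeatureTable}
#' @export
FeatureTable <- function(values, blockOf, missingMask = is.na(values)) {
    if (is.null(colnames(values)))
        stop("feature matrix must have column names")
    if (length(blockOf) == 1L && is.null(names(blockOf)))
        blockOf <- structure(rep(blockOf, ncol(values)),
                             names = colnames(values))
    new("FeatureTable", values = values,
        missingMask = missingMask, blockOf = blockOf)
}

#' @rdname featureValues
setMethod("featureValues", "FeatureTable", function(x) x@values)

#' @rdname missingMask
setMethod("missingMask", "FeatureTable", function(x) x@missingMask)

#' @rdname featureNames
setMethod("featureNames", "FeatureTable", function(x) colnames(x@values))

#' @rdname featureBlocks
setMethod("featureBlocks", "FeatureTable",
          function(x) x@blockOf[colnames(x@values)])

#' @rdname moleculeIds
setMethod("moleculeIds", "FeatureTable", function(x) rownames(x@values))

#' @describeIn FeatureTable dimensions (molecules, features)
#' @param x a FeatureTable
#' @export
setMethod("dim", "FeatureTable", function(x) dim(x@values))

setMethod("[", "FeatureTable", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@values))
    if (missing(j)) j <- seq_len(ncol(x@values))
    v <- x@values[i, j, drop = FALSE]
    m <- x@missingMask[i, j, drop = FALSE]
    new("FeatureTable", values = v, missingMask = m,
        blockOf = x@blockOf[colnames(v)])
})

setMethod("show", "FeatureTable", function(object) {
    cat("FeatureTable:", nrow(object@values), "molecules x",
        ncol(object@values), "features\n")
    tab <- table(object@blockOf[colnames(object@values)])
    cat("  blocks:", paste(sprintf("%s(%d)", names(tab), tab),
                           collapse = ", "), "\n")
    nm <- sum(object@missingMask)
    if (nm) cat("  missing entries:", nm, "\n")
})

#' Column-bind two feature tables over the same molecules
#'
#' @param x,y FeatureTable objects with identical row ids (same order) and
#'   disjoint feature names
#' @return combined FeatureTable
#' @export
combineFeatures <- function(x, y) {
    stopifnot(is(x, "FeatureTable"), is(y, "FeatureTable"))
    if (!identical(rownames(x@values), rownames(y@values)))
        stop("feature tables cover different molecules")
    if (length(intersect(colnames(x@values), colnames(y@values))))
        stop("duplicate feature names across tables")
    new("FeatureTable",
        values = cbind(x@values, y@values),
        missingMask = cbind(x@missingMask, y@missingMask),
        blockOf = c(x@blockOf, y@blockOf))
}

#' Write a FeatureTable to CSV (first column = id)
#' @param x a FeatureTable
#' @param path output file; a JSON sidecar \code{<path>.blocks.json} records
#'   block membership
#' @return invisibly, the path
#' @export
writeFeatureTable <- function(x, path) {
    df <- data.frame(id = rownames(x@values), x@values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
    jsonlite::write_json(as.list(featureBlocks(x)),
                         paste0(path, ".blocks.json"), auto_unbox = TRUE)
    invisible(path)
}

## ---- small constructors ----------------------------------------------------

#' Fingerprint configuration
#' @param nBits number of bits, a power of two >= 64
#' @param radius maximum circular-environment radius
#' @return a \linkS4class{FingerprintConfig}
#' @export
fingerprintConfig <- function(nBits = 2048L, radius = 2L) {
    new("FingerprintConfig", nBits = as.integer(nBits),
        radius = as.integer(radius))
}

#' Boruta configuration
#'
#' @param nIterations shadow/importance rounds (>= 10)
#' @param alpha binomial-test significance level
#' @param correction multiple-test correction across features
#' @param tentativePolicy resolution rule for tentative features
#' @param numTrees forest size per iteration
#' @param seed RNG seed
#' @return a \linkS4class{BorutaConfig}
#' @export
borutaConfig <- function(nIterations = 100L, alpha = 0.05,
                         correction = c("bonferroni", "none"),
                         tentativePolicy = c("median_test", "include", "exclude"),
                         numTrees = 100L, seed = 1L) {
    new("BorutaConfig", nIterations = as.integer(nIterations),
        alpha = alpha, correction = match.arg(correction),
        tentativePolicy = match.arg(tentativePolicy),
        numTrees = as.integer(numTrees), seed = as.integer(seed))
}

#' Classifier specification
#'
#' Supported algorithms and their hyperparameters:
#' \itemize{
#'   \item \code{random_forest}: \code{num_trees} (default 500), \code{mtry}
#'     (default sqrt of feature count)
#'   \item \code{ridge_logistic}: \code{lambda} (L2 penalty, default 0.01)
#'   \item \code{adaboost_trees}: \code{n_rounds} (default 100),
#'     \code{max_depth} (default 1, i.e. stumps)
#' }
#' @param algorithm one of the three families
#' @param params named list of hyperparameters (defaults above)
#' @param seed RNG seed
#' @return a \linkS4class{ClassifierSpec}
#' @export
classifierSpec <- function(algorithm = c("random_forest", "ridge_logistic",
                                         "adaboost_trees"),
                           params = list(), seed = 1L) {
    new("ClassifierSpec", algorithm = match.arg(algorithm),
        params = params, seed = as.integer(seed))
}

## ---- Boruta accessors ------------------------------------------------------

#' @rdname confirmedFeatures
setMethod("confirmedFeatures", "BorutaResult",
          function(x) names(x@status)[x@status == "confirmed"])

#' @rdname tentativeFeatures
setMethod("tentativeFeatures", "BorutaResult",
          function(x) names(x@status)[x@status == "tentative"])

#' @rdname rejectedFeatures
setMethod("rejectedFeatures", "BorutaResult",
          function(x) names(x@status)[x@status == "rejected"])

setMethod("show", "BorutaResult", function(object) {
    tab <- table(factor(object@status,
                        levels = c("confirmed", "tentative", "rejected")))
    cat("BorutaResult over", length(object@status), "features,",
        object@nIterations, "iterations\n")
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "PCAModel", function(object) {
    cat("PCAModel:", length(object@featureNames), "features ->",
        object@nComponents, "components (",
        sprintf("%.1f%%", 100 * sum(
            object@explainedVarRatio[seq_len(object@nComponents)])),
        "variance )\n")
})

#' @rdname featureNames
setMethod("featureNames", "PCAModel", function(x) x@featureNames)

#' @rdname featureNames
setMethod("featureNames", "DomainReference", function(x) x@featureNames)

#' @rdname featureNames
setMethod("featureNames", "TastePredictor", function(x) x@featureNames)

#' @rdname decisionThreshold
setMethod("decisionThreshold", "TastePredictor", function(x) x@threshold)

setMethod("show", "TastePredictor", function(object) {
    cat("TastePredictor [", object@task, "] ", object@algorithm,
        " + ", object@preprocessing,
        sprintf(", threshold %.3f", object@threshold),
        if (!is.null(object@domain)) ", with applicability domain" else "",
        "\n", sep = "")
})

setMethod("show", "MetricReport", function(object) {
    cat(sprintf(paste0("MetricReport: AUPR %.3f AUROC %.3f F1 %.3f NER %.4f ",
                       "Sn %.3f Sp %.3f NA %.1f%%\n"),
                object@aupr, object@auroc, object@f1, object@ner,
                object@sensitivity, object@specificity,
                100 * object@naFraction))
})

#' Convert a MetricReport to a one-row data.frame
#'
#' Column order follows the standard reporting layout (AUPR, AUROC, F1, NER,
#' Sn, Sp, NA fraction).
#' @param x a MetricReport
#' @param ... ignored
#' @return one-row data.frame
#' @export
metricRow <- function(x, ...) {
    data.frame(aupr = x@aupr, auroc = x@auroc, f1 = x@f1, ner = x@ner,
               sensitivity = x@sensitivity, specificity = x@specificity,
               na_fraction = x@naFraction)
}

setMethod("show", "CVReport", function(object) {
    cat("CVReport:", length(object@folds), "folds,", object@spec@algorithm,
        "+", object@preprocessing, "\n")
    cat(sprintf("  pooled out-of-fold AUROC %.3f, AUPR %.3f\n",
                aurocScore(object@labels, object@scores),
                auprScore(object@labels, object@scores)))
})

setMethod("show", "ScreeningSummary", function(object) {
    cat("ScreeningSummary:", object@nTotal, "molecules,",
        object@nInDomain, "in-domain\n")
    if (object@flagged) {
        cat("  no in-domain molecules; percentages unavailable\n")
    } else {
        cat(sprintf("  bitter %d (%d%%), sweet %d (%d%%), both %d (%d%%)\n",
                    object@nBitter, object@pctBitter, object@nSweet,
                    object@pctSweet, object@nBoth, object@pctBoth))
    }
})

setMethod("show", "DomainReference", function(object) {
    cat("DomainReference:", nrow(object@reference), "training rows x",
        object@k, "features; N =", object@N, ", delta =", object@delta, "\n")
})
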