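#' @include AllClasses.R methods.R evaluation.R
NULL

#' All-relevant feature selection (Boruta)
#'
#' Each iteration duplicates the feature matrix into "shadow" columns by
#' independently permuting every real column, trains a random forest on
#' [real | shadow], and records a hit for every real feature whose impurity
#' importance exceeds the maximum shadow importance. After all iterations a
#' two-sided binomial test against p = 0.5 (optionally Bonferroni-corrected
#' across features) classifies each feature: significantly more hits than
#' chance = confirmed, significantly fewer = rejected, otherwise tentative.
#' A standardized importance record (importance centred and scaled by each
#' round's shadow distribution) is kept for reporting.
#'
#' Deterministic given \code{config@seed}.
#'
#' @param x a \linkS4class{FeatureTable} with no missing values (apply
#'   \code{cleanFeatures} first)
#' @param labels binary label vector (both classes present)
#' @param config a \linkS4class{BorutaConfig}
#' @return a \linkS4class{BorutaResult}
#' @export
borutaSelect <- function(x, labels, config = borutaConfig()) {
    stopifnot(is(x, "FeatureTable"), is(config, "BorutaConfig"))
    validObject(config)
    v <- x@values
    if (!ncol(v)) stop("empty feature set")
    if (any(x@missingMask)) stop("missing values present; run cleanFeatures")
    y <- .asBinary(labels)
    if (length(y) != nrow(v)) stop("labels/rows length mismatch")
    if (length(unique(y)) < 2L) stop("both classes must be present")
    p <- ncol(v)
    feats <- colnames(v)
    yf <- factor(y, levels = c(0, 1))
    nIter <- config@nIterations
    hits <- integer(p)
    impHist <- matrix(NA_real_, nIter, p, dimnames = list(NULL, feats))
    shadowMax <- numeric(nIter)
    zSum <- numeric(p)
    set.seed(config@seed)
    for (it in seq_len(nIter)) {
        shadow <- apply(v, 2, sample)
        colnames(shadow) <- paste0(".shadow", seq_len(p))
        df <- data.frame(cbind(v, shadow), check.names = FALSE)
        fit <- ranger::ranger(
            x = df, y = yf, num.trees = config@numTrees,
            importance = "impurity", probability = FALSE,
            num.threads = 1L, seed = .seedFrom(config@seed, it))
        imp <- fit$variable.importance
        real <- imp[feats]
        sh <- imp[paste0(".shadow", seq_len(p))]
        shadowMax[it] <- max(sh)
        hits <- hits + as.integer(real > shadowMax[it])
        impHist[it, ] <- real
        sdSh <- stats::sd(sh)
        if (is.finite(sdSh) && sdSh > 0)
            zSum <- zSum + (real - mean(sh)) / sdSh
    }
    alpha <- config@alpha
    if (config@correction == "bonferroni") alpha <- alpha / p
    pUp <- stats::pbinom(hits - 1L, nIter, 0.5, lower.tail = FALSE)
    pDown <- stats::pbinom(hits, nIter, 0.5)
    status <- rep("tentative", p)
    status[pUp <= alpha / 2] <- "confirmed"
    status[pDown <= alpha / 2] <- "rejected"
    new("BorutaResult",
        status = structure(status, names = feats),
        hits = structure(hits, names = feats),
        nIterations = nIter, importanceHistory = impHist,
        shadowMaxHistory = shadowMax,
        zScores = structure(zSum / nIter, names = feats),
        config = config)
}

#' Resolve tentative features under a policy
#'
#' \code{"include"} treats tentative features as confirmed, \code{"exclude"}
#' as rejected; \code{"median_test"} confirms a tentative feature when its
#' median importance across iterations exceeds the median of the per-round
#' maximum shadow importances.
#'
#' @param result a \linkS4class{BorutaResult}
#' @param policy resolution rule (default: the one in the result's config)
#' @return named character of resolved statuses (confirmed/rejected only)
#' @export
resolveTentative <- function(result, policy = result@config@tentativePolicy) {
    stopifnot(is(result, "BorutaResult"))
    policy <- match.arg(policy, c("median_test", "include", "exclude"))
    st <- result@status
    tent <- names(st)[st == "tentative"]
    if (length(tent)) {
        st[tent] <- switch(policy,
            include = "confirmed",
            exclude = "rejected",
            median_test = {
                shadowMed <- .midpointMedian(result@shadowMaxHistory)
                ifelse(apply(result@importanceHistory[, tent, drop = FALSE],
                             2, .midpointMedian) > shadowMed,
                       "confirmed", "rejected")
            })
    }
    st
}

#' Filter a feature table by a Boruta result
#'
#' Retains confirmed features (plus tentative ones if requested), preserving
#' column order.
#'
#' @param x a \linkS4class{FeatureTable}
#' @param result a \linkS4class{BorutaResult} covering exactly x's features
#' @param includeTentative also keep tentative features
#' @return filtered \linkS4class{FeatureTable} (with a warning when nothing
#'   is retained)
#' @export
applySelection <- function(x, result, includeTentative = FALSE) {
    stopifnot(is(x, "FeatureTable"), is(result, "BorutaResult"))
    if (!setequal(featureNames(x), names(result@status)))
        stop("feature mismatch between table and Boruta result")
    keepStatus <- if (includeTentative) c("confirmed", "tentative")
                  else "confirmed"
    keep <- featureNames(x)[result@status[featureNames(x)] %in% keepStatus]
    if (!length(keep))
        warning("no features retained by the selection")
    x[, keep]
}

#' Fit a standardized PCA preprocessing model
#'
#' Features are centred and scaled to unit variance before the decomposition
#' (descriptor scales span orders of magnitude). Retains the smallest number
#' of components whose cumulative explained-variance ratio reaches
#' \code{varianceThreshold}.
#'
#' @param x a \linkS4class{FeatureTable} with no missing values and >= 2 rows
#' @param varianceThreshold cumulative explained-variance target in (0, 1]
#' @return a \linkS4class{PCAModel}
#' @export
pcaFit <- function(x, varianceThreshold = 0.99) {
    stopifnot(is(x, "FeatureTable"))
    v <- x@values
    if (nrow(v) < 2) stop("PCA needs >= 2 rows")
    if (any(x@missingMask)) stop("missing values present; run cleanFeatures")
    sds <- apply(v, 2, stats::sd)
    if (all(sds == 0)) stop("all features have zero variance")
    scl <- ifelse(sds > 0, sds, 1)
    pr <- stats::prcomp(v, center = TRUE, scale. = scl)
    ratio <- pr$sdev^2 / sum(pr$sdev^2)
    ncomp <- which(cumsum(ratio) >= varianceThreshold - 1e-12)[1]
    if (is.na(ncomp)) ncomp <- length(ratio)
    new("PCAModel", center = pr$center, scaleFactor = scl,
        loadings = pr$rotation, explainedVarRatio = ratio,
        nComponents = as.integer(ncomp), featureNames = colnames(v))
}

#' Project a feature table onto a fitted PCA model
#'
#' @param model a \linkS4class{PCAModel}
#' @param x a \linkS4class{FeatureTable} containing the model's features
#' @return a \linkS4class{FeatureTable} of \code{nComponents} score columns
#'   (block \code{"pca"})
#' @export
pcaTransform <- function(model, x) {
    stopifnot(is(model, "PCAModel"), is(x, "FeatureTable"))
    miss <- setdiff(model@featureNames, featureNames(x))
    if (length(miss))
        stop("feature mismatch: table lacks ", paste(miss, collapse = ", "))
    v <- x@values[, model@featureNames, drop = FALSE]
    z <- sweep(sweep(v, 2, model@center), 2, model@scaleFactor, "/")
    comp <- seq_len(model@nComponents)
    scores <- z %*% model@loadings[, comp, drop = FALSE]
    colnames(scores) <- paste0("PC", comp)
    new("FeatureTable", values = scores,
        missingMask = matrix(FALSE, nrow(scores), ncol(scores),
                             dimnames = dimnames(scores)),
        blockOf = structure(rep("pca", ncol(scores)),
                            names = colnames(scores)))
}

#' Aggregate feature importances by descriptor block
#'
#' @param importances named numeric vector of per-feature importances
#' @param blockOf named character mapping every feature to a block (e.g.
#'   \code{featureBlocks(table)}); blocks with no features are reported with
#'   count 0
#' @param allBlocks optional character vector of blocks to always report
#' @return data.frame: block, n, sum, median, q1, q3
#' @export
blockImportance <- function(importances, blockOf,
                            allBlocks = unique(blockOf)) {
    un <- setdiff(names(importances), names(blockOf))
    if (length(un))
        stop("feature(s) without block assignment: ",
             paste(un, collapse = ", "))
    blocks <- unique(c(allBlocks, unname(blockOf[names(importances)])))
    rows <- lapply(blocks, function(b) {
        f <- names(importances)[blockOf[names(importances)] == b]
        v <- importances[f]
        if (!length(v))
            data.frame(block = b, n = 0L, sum = 0, median = NA_real_,
                       q1 = NA_real_, q3 = NA_real_)
        else
            data.frame(block = b, n = length(v), sum = sum(v),
                       median = .midpointMedian(v),
                       q1 = unname(stats::quantile(v, 0.25)),
                       q3 = unname(stats::quantile(v, 0.75)))
    })
    do.call(rbind, rows)
}

#' Serialize a BorutaResult to JSON
#' @param x a BorutaResult
#' @param path output file
#' @return invisibly, the path
#' @export
writeBorutaResult <- function(x, path) {
    jsonlite::write_json(
        list(status = as.list(x@status), hits = as.list(x@hits),
             n_iterations = x@nIterations,
             z_scores = as.list(round(x@zScores, 6)),
             shadow_max_history = x@shadowMaxHistory),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
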