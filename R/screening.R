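#' @include AllClasses.R methods.R models.R domain.R fingerprints.R
NULL

#' Screen a chemical library with bitter and sweet predictors
#'
#' Each molecule goes through feature computation (unless a precomputed table
#' is supplied), the applicability-domain check of both predictors, scoring
#' by both models, and calling at each predictor's decision threshold. A
#' molecule is in-domain when it is inside every predictor's domain. Calls
#' are made only for in-domain, successfully predicted molecules; feature
#' failures are recorded with a reason and excluded from tallies. No
#' per-molecule failure is fatal.
#'
#' @param x a curated \linkS4class{TasteDataset} (or anything
#'   \code{featurizeDataset} accepts) -- ignored when \code{features} is given
#' @param bitter,sweet fitted \linkS4class{TastePredictor} objects
#' @param features optional precomputed \linkS4class{FeatureTable} covering
#'   both predictors' features
#' @param cleanMissing impute/drop missing descriptor values before scoring
#'   (uses the predictors' feature lists; default TRUE)
#' @return data.frame, one row per molecule: id, in_domain, median distances,
#'   bitter/sweet probabilities and calls, failure reason
#' @export
screenLibrary <- function(x, bitter, sweet, features = NULL,
                          cleanMissing = FALSE) {
    stopifnot(is(bitter, "TastePredictor"), is(sweet, "TastePredictor"))
    if (is.null(features)) {
        if (!length(x))
            return(.emptyScreening())
        features <- featurizeDataset(x)
    }
    if (!nrow(features@values)) return(.emptyScreening())
    ids <- rownames(features@values)
    n <- length(ids)
    res <- data.frame(
        id = ids, in_domain = NA, bitter_distance = NA_real_,
        sweet_distance = NA_real_, bitter_prob = NA_real_,
        sweet_prob = NA_real_, bitter_call = NA, sweet_call = NA,
        failure = NA_character_, stringsAsFactors = FALSE)
    rownames(res) <- NULL

    need <- unique(c(featureNames(bitter), featureNames(sweet)))
    missingFeat <- setdiff(need, featureNames(features))
    if (length(missingFeat))
        stop("library features lack: ", paste(missingFeat, collapse = ", "))
    sub <- features[, need]
    bad <- rowSums(sub@missingMask) > 0
    res$failure[bad] <- "descriptor computation failed"

    okIdx <- which(!bad)
    if (!length(okIdx)) return(res)
    ok <- features[okIdx, ]

    dom <- rep(TRUE, length(okIdx))
    for (pr in list(bitter, sweet)) {
        if (is.null(pr@domain)) next
        tab <- if (pr@preprocessing == "pca")
            pcaTransform(pr@preprocessor, ok[, featureNames(pr)])
        else ok
        dd <- inDomain(pr@domain, tab)
        col <- paste0(pr@task, "_distance")
        res[[col]][okIdx] <- dd$median_distance
        dom <- dom & dd$in_domain
    }
    res$in_domain[okIdx] <- dom

    pb <- predictProba(bitter, ok)
    ps <- predictProba(sweet, ok)
    res$bitter_prob[okIdx] <- unname(pb)
    res$sweet_prob[okIdx] <- unname(ps)
    inIdx <- okIdx[dom]
    res$bitter_call[inIdx] <-
        res$bitter_prob[inIdx] >= decisionThreshold(bitter)
    res$sweet_call[inIdx] <-
        res$sweet_prob[inIdx] >= decisionThreshold(sweet)
    res
}

.emptyScreening <- function() {
    data.frame(id = character(0), in_domain = logical(0),
               bitter_distance = numeric(0), sweet_distance = numeric(0),
               bitter_prob = numeric(0), sweet_prob = numeric(0),
               bitter_call = logical(0), sweet_call = logical(0),
               failure = character(0), stringsAsFactors = FALSE)
}

#' Summarize screening results
#'
#' Tallies in-domain molecules and those called bitter, sweet, and both
#' (above both thresholds simultaneously; counted within in-domain molecules
#' only). Percentages are integer percents of the in-domain count, rounded
#' half away from zero. With zero in-domain molecules the summary is flagged
#' and percentages are NA -- no division is attempted.
#'
#' @param results data.frame from \code{screenLibrary}, or the raw counts via
#'   \code{nInDomain}/\code{nBitter}/\code{nSweet}/\code{nBoth} (then
#'   \code{results} may be NULL)
#' @param nInDomain,nBitter,nSweet,nBoth,nTotal optional direct counts
#' @return a \linkS4class{ScreeningSummary}
#' @export
summarizeScreening <- function(results = NULL, nInDomain = NULL,
                               nBitter = NULL, nSweet = NULL, nBoth = NULL,
                               nTotal = NULL) {
    if (!is.null(results)) {
        nTotal <- nrow(results)
        inD <- results$in_domain %in% TRUE
        nInDomain <- sum(inD)
        nBitter <- sum(results$bitter_call %in% TRUE & inD)
        nSweet <- sum(results$sweet_call %in% TRUE & inD)
        nBoth <- sum(results$bitter_call %in% TRUE &
                     results$sweet_call %in% TRUE & inD)
    } else {
        if (is.null(nInDomain)) stop("supply results or counts")
        if (is.null(nBitter)) nBitter <- 0L
        if (is.null(nSweet)) nSweet <- 0L
        if (is.null(nBoth)) nBoth <- min(nBitter, nSweet) * 0L
        if (is.null(nTotal)) nTotal <- nInDomain
    }
    pct <- function(cnt) {
        if (nInDomain == 0) NA_integer_
        else as.integer(.roundHalfAway(100 * cnt / nInDomain))
    }
    new("ScreeningSummary",
        nTotal = as.integer(nTotal), nInDomain = as.integer(nInDomain),
        nBitter = as.integer(nBitter), nSweet = as.integer(nSweet),
        nBoth = as.integer(nBoth),
        pctBitter = pct(nBitter), pctSweet = pct(nSweet),
        pctBoth = pct(nBoth), flagged = nInDomain == 0)
}

#' Write screening outputs
#' @param results data.frame from \code{screenLibrary}
#' @param summary a \linkS4class{ScreeningSummary}
#' @param resultPath CSV output for per-molecule rows
#' @param summaryPath JSON output for the summary
#' @return invisibly, NULL
#' @export
writeScreening <- function(results, summary, resultPath, summaryPath) {
    utils::write.csv(results, resultPath, row.names = FALSE, na = "")
    jsonlite::write_json(
        list(n_total = summary@nTotal, n_in_domain = summary@nInDomain,
             n_bitter = summary@nBitter, n_sweet = summary@nSweet,
             n_both = summary@nBoth, pct_bitter = summary@pctBitter,
             pct_sweet = summary@pctSweet, pct_both = summary@pctBoth,
             flagged = summary@flagged),
        summaryPath, auto_unbox = TRUE, digits = NA)
    invisible(NULL)
}
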