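#' @include AllClasses.R methods.R
NULL

#' Build a nearest-neighbour applicability-domain reference
#'
#' Keeps the k features with the highest importance (ties broken by name
#' order), standardizes the training rows by their mean and standard
#' deviation (raw descriptor scales differ by orders of magnitude, so the
#' distance threshold is only meaningful on a normalized scale), and stores
#' the standardized reference matrix.
#'
#' @param x training \linkS4class{FeatureTable} (no missing values)
#' @param importances named numeric importances covering x's features
#' @param k number of features to keep (default 25)
#' @param N neighbour count for the median distance (default 5)
#' @param delta distance threshold (default 3)
#' @return a \linkS4class{DomainReference}
#' @export
buildDomain <- function(x, importances, k = 25L, N = 5L, delta = 3) {
    stopifnot(is(x, "FeatureTable"))
    if (!nrow(x@values)) stop("empty training table")
    feats <- featureNames(x)
    miss <- setdiff(feats, names(importances))
    if (length(miss))
        stop("importances missing for: ", paste(miss, collapse = ", "))
    if (k > length(feats))
        stop("k exceeds the number of available features")
    imp <- importances[feats]
    keep <- feats[order(-imp, feats)][seq_len(k)]
    keep <- keep[order(match(keep, feats))]
    v <- x@values[, keep, drop = FALSE]
    ctr <- colMeans(v)
    sds <- apply(v, 2, stats::sd)
    scl <- ifelse(is.finite(sds) & sds > 0, sds, 1)
    ref <- sweep(sweep(v, 2, ctr), 2, scl, "/")
    new("DomainReference", reference = ref, center = ctr, scaleFactor = scl,
        k = as.integer(k), N = as.integer(N), delta = delta,
        featureNames = keep)
}

#' Applicability-domain membership
#'
#' Standardizes each query with the training statistics, finds its N nearest
#' training rows by Euclidean distance over the k domain features, and takes
#' the median (midpoint convention for even N) of those N distances. A query
#' is in-domain iff that median is <= delta.
#'
#' @param reference a \linkS4class{DomainReference}
#' @param x a \linkS4class{FeatureTable}, numeric matrix, or single named
#'   numeric vector covering the reference's features
#' @return data.frame with columns \code{median_distance} and
#'   \code{in_domain}, one row per query
#' @export
inDomain <- function(reference, x) {
    stopifnot(is(reference, "DomainReference"))
    if (is(x, "FeatureTable")) {
        miss <- setdiff(reference@featureNames, featureNames(x))
        if (length(miss))
            stop("query lacks domain feature(s): ",
                 paste(miss, collapse = ", "))
        q <- x@values[, reference@featureNames, drop = FALSE]
    } else if (is.matrix(x)) {
        q <- x[, reference@featureNames, drop = FALSE]
    } else {
        if (!all(reference@featureNames %in% names(x)))
            stop("query lacks domain feature(s)")
        q <- matrix(x[reference@featureNames], nrow = 1,
                    dimnames = list(NULL, reference@featureNames))
    }
    z <- sweep(sweep(q, 2, reference@center), 2, reference@scaleFactor, "/")
    ref <- reference@reference
    N <- min(reference@N, nrow(ref))
    med <- vapply(seq_len(nrow(z)), function(i) {
        d2 <- colSums((t(ref) - z[i, ])^2)
        .midpointMedian(sqrt(sort(d2)[seq_len(N)]))
    }, numeric(1))
    data.frame(median_distance = med, in_domain = med <= reference@delta,
               row.names = rownames(q))
}
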