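#' @include AllClasses.R methods.R
NULL

.asBinary <- function(y) {
    if (is.factor(y)) y <- as.character(y)
    if (is.logical(y)) return(as.integer(y))
    if (is.character(y)) {
        if (all(y %in% c("positive", "negative")))
            return(as.integer(y == "positive"))
        if (all(y %in% c("0", "1"))) return(as.integer(y))
        stop("labels must be binary (0/1, logical, or positive/negative)")
    }
    y <- as.numeric(y)
    if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1")
    as.integer(y)
}

#' Confusion counts of a binary classification
#'
#' @param labels binary truth (0/1, logical, or positive/negative)
#' @param calls binary predictions, same encoding and length
#' @return named integer vector \code{c(TP, FP, TN, FN)}
#' @examples confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))  # TP 1 FP 1 TN 1 FN 1
#' @export
confusionCounts <- function(labels, calls) {
    y <- .asBinary(labels); p <- .asBinary(calls)
    if (length(y) != length(p)) stop("labels and calls differ in length")
    c(TP = sum(y == 1L & p == 1L), FP = sum(y == 0L & p == 1L),
      TN = sum(y == 0L & p == 0L), FN = sum(y == 1L & p == 0L))
}

#' Threshold-dependent metrics from confusion counts
#'
#' Precision = TP/(TP+FP); sensitivity (recall) = TP/(TP+FN); specificity =
#' TN/(TN+FP); F1 = 2 PR/(P+R); NER (non-error rate, balanced accuracy) =
#' (Sn+Sp)/2. A 0/0 case returns 0 and sets the \code{"degenerate"}
#' attribute, so batch sweeps complete instead of erroring.
#'
#' @param counts named vector with TP, FP, TN, FN (as from
#'   \code{confusionCounts}), or the TP count when the four are given
#'   separately
#' @param FP,TN,FN optional separate counts
#' @return named numeric: precision, sensitivity, specificity, f1, ner; with
#'   attribute \code{degenerate}
#' @examples
#' m <- thresholdMetrics(c(TP = 1, FP = 0, TN = 0, FN = 1))
#' m[["f1"]]  # 2/3
#' @export
thresholdMetrics <- function(counts, FP = NULL, TN = NULL, FN = NULL) {
    if (!is.null(FP))
        counts <- c(TP = as.numeric(counts), FP = FP, TN = TN, FN = FN)
    tp <- counts[["TP"]]; fp <- counts[["FP"]]
    tn <- counts[["TN"]]; fn <- counts[["FN"]]
    degenerate <- FALSE
    safe <- function(num, den) {
        if (den == 0) { degenerate <<- TRUE; 0 } else num / den
    }
    precision <- safe(tp, tp + fp)
    sensitivity <- safe(tp, tp + fn)
    specificity <- safe(tn, tn + fp)
    f1 <- if (precision + sensitivity == 0) { degenerate <- TRUE; 0 } else
        2 * precision * sensitivity / (precision + sensitivity)
    out <- c(precision = precision, sensitivity = sensitivity,
             specificity = specificity, f1 = f1,
             ner = (sensitivity + specificity) / 2)
    attr(out, "degenerate") <- degenerate
    out
}

#' Area under the ROC curve
#'
#' Equals the probability that a random positive outscores a random negative,
#' with ties counted 1/2 (rank/Mann-Whitney form). Invariant under strictly
#' monotone transforms of the scores.
#'
#' @param labels binary truth
#' @param scores real-valued scores, higher = more positive
#' @return numeric(1) in [0, 1]
#' @examples aurocScore(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))  # 0.75
#' @export
aurocScore <- function(labels, scores) {
    y <- .asBinary(labels)
    if (length(y) != length(scores)) stop("length mismatch")
    n1 <- sum(y == 1L); n0 <- sum(y == 0L)
    if (n1 == 0L || n0 == 0L)
        stop("AUROC undefined: both classes must be present")
    r <- rank(scores, ties.method = "average")
    (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average of precision over recall increments at descending unique
#' score cuts (never trapezoidal interpolation): tied scores enter together.
#'
#' @param labels binary truth (at least one positive)
#' @param scores real-valued scores
#' @return numeric(1) in (0, 1]
#' @examples auprScore(c(1, 1, 0), c(0.9, 0.8, 0.1))  # 1
#' @export
auprScore <- function(labels, scores) {
    y <- .asBinary(labels)
    if (length(y) != length(scores)) stop("length mismatch")
    nPos <- sum(y == 1L)
    if (nPos == 0L) stop("AUPR undefined: no positive instances")
    cuts <- sort(unique(scores), decreasing = TRUE)
    ap <- 0; prevRecall <- 0
    tp <- 0; called <- 0
    for (cut in cuts) {
        sel <- scores == cut
        tp <- tp + sum(y[sel] == 1L)
        called <- called + sum(sel)
        recall <- tp / nPos
        precision <- tp / called
        ap <- ap + (recall - prevRecall) * precision
        prevRecall <- recall
    }
    ap
}

#' Full metric report for scored predictions
#'
#' Threshold metrics are computed on the predicted molecules only; the NA
#' fraction records the molecules left unpredicted. Scores at the threshold
#' are called positive (the cut is closed on the positive side).
#'
#' @param labels binary truth for the predicted molecules
#' @param scores probabilities for the predicted molecules
#' @param threshold decision cut in [0, 1]
#' @param nUnpredicted number of molecules with no prediction (default 0)
#' @return a \linkS4class{MetricReport}
#' @export
evaluateScores <- function(labels, scores, threshold = 0.5,
                           nUnpredicted = 0L) {
    if (threshold < 0 || threshold > 1) stop("threshold must be in [0,1]")
    y <- .asBinary(labels)
    calls <- as.integer(scores >= threshold)
    tm <- thresholdMetrics(confusionCounts(y, calls))
    both <- length(unique(y)) == 2L
    new("MetricReport",
        precision = tm[["precision"]], sensitivity = tm[["sensitivity"]],
        specificity = tm[["specificity"]], f1 = tm[["f1"]], ner = tm[["ner"]],
        auroc = if (both) aurocScore(y, scores) else NA_real_,
        aupr = if (any(y == 1L)) auprScore(y, scores) else NA_real_,
        naFraction = nUnpredicted / (length(y) + nUnpredicted),
        degenerate = isTRUE(attr(tm, "degenerate")))
}

#' Write a MetricReport as JSON
#' @param x a MetricReport
#' @param path output file
#' @return invisibly, the path
#' @export
writeMetricReport <- function(x, path) {
    jsonlite::write_json(
        list(aupr = x@aupr, auroc = x@auroc, f1 = x@f1, ner = x@ner,
             sensitivity = x@sensitivity, specificity = x@specificity,
             na_fraction = x@naFraction, degenerate = x@degenerate),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
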