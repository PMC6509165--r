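# Independent brute-force oracles used to validate the fast metric
# implementations. Deliberately naive: O(n^2) pair enumeration for AUROC and
# a per-score-group precision recomputation for average precision.

oracleAuroc <- function(labels, scores) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    tot / (length(pos) * length(neg))
}

oracleAupr <- function(labels, scores) {
    nPos <- sum(labels == 1)
    cuts <- sort(unique(scores), decreasing = TRUE)
    ap <- 0
    for (cut in cuts) {
        above <- scores > cut
        at <- scores == cut
        posGained <- sum(labels[at] == 1)
        if (posGained == 0) next
        precision <- (sum(labels[above] == 1) + posGained) /
            (sum(above) + sum(at))
        ap <- ap + (posGained / nPos) * precision
    }
    ap
}

# exhaustive scan oracle for the balance threshold: every observed score as a
# candidate cut (closed on the positive side), minimal |Sn - Sp|, ties to the
# higher-sensitivity (i.e. lower) cut
oracleBalanceThreshold <- function(labels, scores) {
    best <- NULL; bestGap <- Inf; bestSn <- -Inf
    for (t in sort(unique(scores))) {
        sn <- mean(scores[labels == 1] >= t)
        sp <- mean(scores[labels == 0] < t)
        gap <- abs(sn - sp)
        if (gap < bestGap - 1e-12 || (gap <= bestGap + 1e-12 && sn > bestSn)) {
            best <- t; bestGap <- gap; bestSn <- sn
        }
    }
    best
}

# Correlated feature fixture: features are linear images of a bounded
# low-dimensional latent (plus slight noise), mimicking the strong
# collinearity of real molecular descriptors. Labels split the first latent
# coordinate. Dense bounded sampling keeps every row close to its
# neighbours, which is what a nearest-neighbour applicability domain with
# fixed delta presumes.
makeCorrelatedTable <- function(n = 300, d = 40, rank = 2, seed = 1) {
    set.seed(seed)
    Z <- matrix(runif(n * rank), n, rank)
    B <- matrix(rnorm(rank * d), rank, d)
    v <- Z %*% B + 0.02 * matrix(rnorm(n * d), n, d)
    colnames(v) <- sprintf("f%02d", seq_len(d))
    rownames(v) <- sprintf("m%04d", seq_len(n))
    tab <- FeatureTable(v, blockOf = structure(
        rep(c("constitution", "topology"), length.out = d),
        names = colnames(v)))
    list(table = tab, labels = as.integer(Z[, 1] > 0.5))
}

# a small fully numeric FeatureTable fixture
makeTinyTable <- function(n = 12, d = 4, seed = 42) {
    set.seed(seed)
    v <- matrix(rnorm(n * d), n, d,
                dimnames = list(paste0("m", seq_len(n)),
                                paste0("f", seq_len(d))))
    FeatureTable(v, blockOf = structure(
        rep(c("constitution", "topology"), length.out = d),
        names = colnames(v)))
}
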