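#' @include AllClasses.R methods.R structure.R
NULL

#' Descriptor block registry
#'
#' The nine 2D descriptor blocks the package computes, in the style of the
#' open structural/physicochemical descriptor families: constitution,
#' topology, connectivity, kappa shape, (partial) charge, Burden/BCUT
#' eigenvalues, electrotopological state, bulk molecular properties and
#' MOE-type surface-area descriptors. The special block \code{"fingerprint"}
#' is reserved for hashed circular fingerprints.
#'
#' @return data.frame with columns \code{block} and \code{description}
#' @export
descriptorBlocks <- function() {
    data.frame(
        block = c("constitution", "topology", "connectivity", "kappa",
                  "charge", "burden", "estate", "molecular_properties",
                  "moe_type"),
        description = c(
            "atom/bond/ring counts and composition",
            "distance-matrix indices (Wiener, Balaban J, Zagreb, ...)",
            "Kier-Hall molecular connectivity chi indices",
            "Kier kappa shape indices",
            "Gasteiger partial-charge statistics and formal charge",
            "Burden matrix (BCUT) extreme eigenvalues (mass/charge/EN weights)",
            "electrotopological-state (E-state) statistics",
            "bulk properties (MW, logP, TPSA, MR, H-bonding, F count)",
            "approximate van der Waals surface area partitioned by charge"),
        stringsAsFactors = FALSE)
}

## ---- per-block descriptor functions (each: mol -> named numeric) ----------

.descConstitution <- function(mol) {
    el <- mol$elements
    nBonds <- nrow(mol$bonds)
    orders <- if (nBonds) mol$bonds[, "order"] else numeric(0)
    nRings <- nBonds - length(el) + 1L  # cyclomatic number, connected graph
    c(nHeavyAtoms = length(el),
      nC = sum(el == "C"), nN = sum(el == "N"), nO = sum(el == "O"),
      nS = sum(el == "S"), nP = sum(el == "P"),
      nHalogen = sum(el %in% c("F", "Cl", "Br", "I")),
      nHetero = sum(!el %in% c("C", "H")),
      nH = sum(mol$nH),
      nBonds = nBonds,
      nDoubleBonds = sum(orders == 2), nTripleBonds = sum(orders == 3),
      nAromaticAtoms = sum(mol$arom),
      nRings = max(nRings, 0L),
      nAromaticRings = mol$aromRings,
      nRotatableBonds = mol$nRot,
      fracHetero = sum(!el %in% c("C", "H")) / length(el))
}

.descTopology <- function(mol) {
    D <- mol$D
    n <- nrow(D)
    if (any(!is.finite(D)))
        stop("disconnected structure: topological indices undefined")
    if (n < 2) stop("topology needs >= 2 atoms")
    upper <- D[upper.tri(D)]
    W <- sum(upper)
    ecc <- apply(D, 1, max)
    radius <- min(ecc); diameter <- max(ecc)
    deg <- mol$degree
    m <- nrow(mol$bonds)
    mu <- m - n + 1L
    s <- rowSums(D)
    J <- if (m) m / (mu + 1) *
        sum(1 / sqrt(s[mol$bonds[, 1]] * s[mol$bonds[, 2]])) else 0
    c(wiener = W,
      meanWiener = W / (n * (n - 1) / 2),
      harary = sum(1 / upper),
      radius = radius, diameter = diameter,
      petitjean = if (radius > 0) (diameter - radius) / radius else 0,
      zagreb1 = sum(deg^2),
      zagreb2 = if (m) sum(deg[mol$bonds[, 1]] * deg[mol$bonds[, 2]]) else 0,
      platt = if (m) sum(deg[mol$bonds[, 1]] + deg[mol$bonds[, 2]] - 2) else 0,
      balabanJ = J)
}

.descConnectivity <- function(mol) {
    if (!all(mol$known)) stop("unsupported element for connectivity indices")
    deg <- mol$degree
    if (any(deg == 0) && length(deg) > 1)
        stop("disconnected structure")
    ed <- .ELEMENT_DATA[mol$elements, ]
    Z <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
           Cl = 17, As = 33, Se = 34, Br = 35, I = 53)[mol$elements]
    dv <- ifelse(ed$row <= 2, ed$zv - mol$nH,
                 (ed$zv - mol$nH) / (Z - ed$zv - 1))
    dv[dv <= 0] <- NA
    bonds <- mol$bonds
    paths2 <- .pathsLen2(mol)
    chi <- function(d) {
        d[d <= 0] <- NA
        c(sum(1 / sqrt(d)),
          if (nrow(bonds)) sum(1 / sqrt(d[bonds[, 1]] * d[bonds[, 2]])) else 0,
          if (nrow(paths2)) sum(1 / sqrt(d[paths2[, 1]] * d[paths2[, 2]] *
                                          d[paths2[, 3]])) else 0)
    }
    simple <- chi(deg); valence <- chi(dv)
    out <- c(chi0 = simple[1], chi1 = simple[2], chi2 = simple[3],
             chi0v = valence[1], chi1v = valence[2], chi2v = valence[3],
             meanRandic = if (nrow(bonds)) simple[2] / nrow(bonds) else 0)
    if (anyNA(out)) stop("valence delta undefined")
    out
}

# all simple paths of length 2 (i-j-k, i < k)
.pathsLen2 <- function(mol) {
    res <- list()
    for (j in seq_along(mol$adj)) {
        nb <- mol$adj[[j]]
        if (length(nb) >= 2) {
            cmb <- utils::combn(sort(nb), 2)
            res[[length(res) + 1L]] <-
                cbind(cmb[1, ], rep(j, ncol(cmb)), cmb[2, ])
        }
    }
    if (!length(res)) matrix(integer(0), 0, 3) else do.call(rbind, res)
}

.descKappa <- function(mol) {
    A <- length(mol$elements)
    P1 <- nrow(mol$bonds)
    P2 <- nrow(.pathsLen2(mol))
    # paths of length 3 = sum over edges (deg_i-1)(deg_j-1) - 3 * triangles
    deg <- mol$degree
    Adj <- matrix(0, A, A)
    if (P1) {
        Adj[mol$bonds[, 1:2]] <- 1; Adj[mol$bonds[, 2:1]] <- 1
    }
    tri <- sum(diag(Adj %*% Adj %*% Adj)) / 6
    P3 <- if (P1) sum((deg[mol$bonds[, 1]] - 1) * (deg[mol$bonds[, 2]] - 1)) -
        3 * tri else 0
    k1 <- if (P1 > 0) A * (A - 1)^2 / P1^2 else NA_real_
    k2 <- if (P2 > 0) (A - 1) * (A - 2)^2 / P2^2 else NA_real_
    k3 <- if (P3 > 0) {
        if (A %% 2 == 1) (A - 1) * (A - 3)^2 / P3^2
        else (A - 3) * (A - 2)^2 / P3^2
    } else NA_real_
    out <- c(kappa1 = k1, kappa2 = k2, kappa3 = k3,
             flexibility = if (!is.na(k1) && !is.na(k2)) k1 * k2 / A
                           else NA_real_)
    if (anyNA(out)) stop("kappa indices undefined for this size")
    out
}

.descCharge <- function(mol) {
    q <- mol$gasteiger
    if (is.null(q) || anyNA(q)) stop("Gasteiger charges unavailable")
    totPos <- sum(q[q > 0]); totNeg <- sum(q[q < 0])
    c(totalFormalCharge = sum(mol$charge),
      maxPartialCharge = max(q), minPartialCharge = min(q),
      totalPositiveCharge = totPos, totalNegativeCharge = totNeg,
      totalAbsCharge = sum(abs(q)),
      meanAbsCharge = mean(abs(q)),
      chargeRange = max(q) - min(q),
      relPositiveCharge = if (totPos > 0) max(q) / totPos else 0,
      relNegativeCharge = if (totNeg < 0) min(q) / totNeg else 0,
      squaredChargeSum = sum(q^2))
}

.burdenEigen <- function(mol, w) {
    n <- length(mol$elements)
    B <- matrix(0.001, n, n)
    if (nrow(mol$bonds)) for (b in seq_len(nrow(mol$bonds))) {
        i <- mol$bonds[b, 1]; j <- mol$bonds[b, 2]
        v <- 0.1 * mol$bonds[b, 3]
        if (mol$degree[i] == 1L || mol$degree[j] == 1L) v <- v + 0.01
        B[i, j] <- B[j, i] <- v
    }
    diag(B) <- w
    sort(eigen(B, symmetric = TRUE, only.values = TRUE)$values)
}

.descBurden <- function(mol) {
    if (!all(mol$known)) stop("unsupported element for Burden eigenvalues")
    ed <- .ELEMENT_DATA[mol$elements, ]
    q <- mol$gasteiger
    if (is.null(q)) stop("Gasteiger charges unavailable")
    n <- length(mol$elements)
    take <- function(ev, tag) {
        hi <- rev(ev)[seq_len(min(2, n))]; lo <- ev[seq_len(min(2, n))]
        if (n < 2) { hi <- c(hi, hi); lo <- c(lo, lo) }
        structure(c(hi[1], hi[2], lo[1], lo[2]),
                  names = paste0("bcut", tag, c("High1", "High2",
                                                "Low1", "Low2")))
    }
    c(take(.burdenEigen(mol, ed$mass / 12.011), "Mass"),
      take(.burdenEigen(mol, q), "Charge"),
      take(.burdenEigen(mol, ed$en / 2.55), "EN"))
}

.descEState <- function(mol) {
    if (!all(mol$known)) stop("unsupported element for E-state")
    ed <- .ELEMENT_DATA[mol$elements, ]
    Z <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
           Cl = 17, As = 33, Se = 34, Br = 35, I = 53)[mol$elements]
    dv <- ifelse(ed$row <= 2, ed$zv - mol$nH,
                 (ed$zv - mol$nH) / (Z - ed$zv - 1))
    delta <- mol$degree
    if (any(delta == 0) && length(delta) > 1) stop("disconnected structure")
    delta[delta == 0] <- 1
    I <- ((2 / ed$row)^2 * dv + 1) / delta
    D <- mol$D
    S <- I
    n <- length(I)
    if (n > 1) for (i in seq_len(n))
        S[i] <- I[i] + sum((I[i] - I[-i]) / (D[i, -i] + 1)^2)
    el <- mol$elements
    c(sumEState = sum(S), maxEState = max(S), minEState = min(S),
      meanEState = mean(S), rangeEState = max(S) - min(S),
      sumEStateO = sum(S[el == "O"]), sumEStateN = sum(S[el == "N"]),
      sumEStateHetero = sum(S[!el %in% c("C", "H")]))
}

.labuteASA <- function(mol) {
    ed <- .ELEMENT_DATA[mol$elements, ]
    r <- ed$rvdw
    area <- 4 * pi * r^2
    if (nrow(mol$bonds)) for (b in seq_len(nrow(mol$bonds))) {
        i <- mol$bonds[b, 1]; j <- mol$bonds[b, 2]
        d <- ed$rcov[i] + ed$rcov[j]
        hi <- max(0, min(2 * r[i], r[i] - (d^2 + r[i]^2 - r[j]^2) / (2 * d)))
        hj <- max(0, min(2 * r[j], r[j] - (d^2 + r[j]^2 - r[i]^2) / (2 * d)))
        area[i] <- area[i] - 2 * pi * r[i] * hi
        area[j] <- area[j] - 2 * pi * r[j] * hj
    }
    pmax(area, 0)
}

.descMoeType <- function(mol) {
    if (!all(mol$known)) stop("unsupported element for surface descriptors")
    q <- mol$gasteiger
    if (is.null(q)) stop("Gasteiger charges unavailable")
    a <- .labuteASA(mol)
    breaks <- c(-Inf, -0.25, -0.10, 0, 0.10, 0.25, Inf)
    bin <- cut(q, breaks, labels = FALSE)
    vsa <- vapply(1:6, function(k) sum(a[bin == k]), numeric(1))
    c(labuteASA = sum(a),
      structure(vsa, names = paste0("peoeVSA", 1:6)))
}

.BLOCK_FUNS <- list(
    constitution = .descConstitution,
    topology = .descTopology,
    connectivity = .descConnectivity,
    kappa = .descKappa,
    charge = .descCharge,
    burden = .descBurden,
    estate = .descEState,
    moe_type = .descMoeType)

## molecular_properties comes from OpenBabel bulk properties, computed in batch
.molecularProperties <- function(canon, nm) {
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(structure(canon, names = nm)))
    pr <- ChemmineR::propOB(sdf)
    m <- cbind(MW = pr$MW, logP = pr$logP, TPSA = pr$TPSA, MR = pr$MR,
               HBA = pr$HBA1, HBD = pr$HBD, nFluorine = pr$nF)
    rownames(m) <- nm
    m
}

#' Compute 2D descriptor blocks for a molecule set
#'
#' One row per molecule in input order. Descriptor values are a pure function
#' of the canonical structure. A descriptor that cannot be computed for a
#' molecule (unsupported element, undefined index, missing partial charges)
#' is flagged in the missing mask for its whole block, never silently zeroed.
#'
#' @param x a curated \linkS4class{TasteDataset} (valid canonical SMILES), or
#'   a character vector of canonical SMILES
#' @param blocks subset of \code{descriptorBlocks()$block}
#' @return a \linkS4class{FeatureTable}
#' @examples
#' \dontrun{
#' ds <- TasteDataset(id = "ethane", smiles = "CC",
#'                    canonical_smiles = canonicalizeSmiles("CC"))
#' ft <- computeDescriptorTable(ds, blocks = "constitution")
#' featureValues(ft)[, "nHeavyAtoms"]  # 2
#' }
#' @export
computeDescriptorTable <- function(x, blocks = descriptorBlocks()$block) {
    if (is(x, "TasteDataset")) {
        canon <- x@records$canonical_smiles
        ids <- x@records$id
    } else {
        canon <- as.character(x)
        ids <- if (!is.null(names(x))) names(x) else
            paste0("mol", seq_along(canon))
    }
    if (!length(canon)) stop("empty molecule set")
    if (anyNA(canon))
        stop("canonical SMILES missing; curate the dataset first")
    blocks <- unique(blocks)
    bad <- setdiff(blocks, descriptorBlocks()$block)
    if (length(bad)) stop("unknown block(s): ", paste(bad, collapse = ", "))
    if (!length(blocks)) stop("empty block selection")

    mols <- .parseStructures(canon, ids)
    graphBlocks <- intersect(blocks, names(.BLOCK_FUNS))
    pieces <- list()
    for (blk in graphBlocks) {
        rows <- lapply(mols, function(m) {
            if (is.null(m)) return(NULL)
            tryCatch(.BLOCK_FUNS[[blk]](m), error = function(e) NULL)
        })
        proto <- rows[!vapply(rows, is.null, logical(1))]
        if (!length(proto))
            stop("block ", sQuote(blk), " failed for every molecule")
        nms <- names(proto[[1]])
        mat <- do.call(rbind, lapply(rows, function(r) {
            if (is.null(r) || !identical(names(r), nms))
                rep(NA_real_, length(nms))
            else as.numeric(r)
        }))
        dimnames(mat) <- list(ids, nms)
        pieces[[blk]] <- mat
    }
    if ("molecular_properties" %in% blocks) {
        mp <- tryCatch(.molecularProperties(canon, ids),
                       error = function(e) NULL)
        if (is.null(mp))
            mp <- matrix(NA_real_, length(ids), 7,
                         dimnames = list(ids, c("MW", "logP", "TPSA", "MR",
                                                "HBA", "HBD", "nFluorine")))
        pieces[["molecular_properties"]] <- mp
    }
    pieces <- pieces[intersect(blocks, names(pieces))]
    values <- do.call(cbind, pieces)
    blockOf <- unlist(lapply(names(pieces), function(b)
        structure(rep(b, ncol(pieces[[b]])), names = colnames(pieces[[b]]))))
    new("FeatureTable", values = values, missingMask = is.na(values),
        blockOf = blockOf)
}

#' Drop unusable features and impute the rest
#'
#' Features missing in more than \code{maxMissingFraction} of molecules are
#' dropped; remaining missing entries are imputed with the per-feature median
#' of the non-missing rows (median is robust to the heavy-tailed scales
#' typical of topological descriptors); zero-variance features are dropped.
#' Values at non-missing positions are never changed.
#'
#' @param x a \linkS4class{FeatureTable}
#' @param maxMissingFraction tolerated missing fraction per feature
#' @return a \linkS4class{FeatureTable} with an all-FALSE mask; dropped
#'   feature names are recorded in \code{attr(, "dropped")}
#' @export
cleanFeatures <- function(x, maxMissingFraction = 0.1) {
    stopifnot(is(x, "FeatureTable"))
    v <- x@values; m <- x@missingMask
    if (!nrow(v)) stop("feature table has zero rows")
    missFrac <- colMeans(m)
    keep <- missFrac <= maxMissingFraction
    v <- v[, keep, drop = FALSE]; m <- m[, keep, drop = FALSE]
    for (j in seq_len(ncol(v))) {
        if (any(m[, j])) {
            med <- stats::median(v[!m[, j], j])
            v[m[, j], j] <- med
        }
    }
    vars <- apply(v, 2, stats::var)
    keep2 <- is.finite(vars) & vars > 0
    dropped <- c(colnames(x@values)[!keep], colnames(v)[!keep2])
    v <- v[, keep2, drop = FALSE]
    out <- new("FeatureTable", values = v,
               missingMask = matrix(FALSE, nrow(v), ncol(v),
                                    dimnames = dimnames(v)),
               blockOf = x@blockOf[colnames(v)])
    attr(out, "dropped") <- dropped
    out
}
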