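#' @include AllClasses.R methods.R structure.R utils.R
NULL

# Circular (Morgan-style) fingerprint of one parsed molecule: iteratively
# hashed atom environments up to the configured radius, folded onto nBits by
# modulus. Atom invariants are graph-intrinsic (element, degree, H count,
# formal charge, aromaticity, ring membership), so the bit vector does not
# depend on the SMILES writing of the structure. The hashing is seedless and
# deterministic; it is not bit-compatible with any proprietary fingerprint.
.circularBits <- function(mol, nBits, radius) {
    n <- length(mol$elements)
    inRing <- .ringAtoms(mol)
    Z <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
           Cl = 17, As = 33, Se = 34, Br = 35, I = 53)[mol$elements]
    Z[is.na(Z)] <- 0
    ids <- vapply(seq_len(n), function(i) .hash32(c(
        Z[i], mol$degree[i],
        if (is.na(mol$nH[i])) 99 else mol$nH[i],
        mol$charge[i] + 8, as.integer(mol$arom[i]), as.integer(inRing[i]))),
        numeric(1))
    seen <- unique(ids)
    if (radius > 0) for (r in seq_len(radius)) {
        nxt <- ids
        for (i in seq_len(n)) {
            nb <- mol$adj[[i]]
            if (length(nb)) {
                orders <- vapply(nb, function(j) {
                    b <- mol$bonds
                    hit <- (b[, 1] == i & b[, 2] == j) |
                           (b[, 1] == j & b[, 2] == i)
                    b[which(hit)[1], 3]
                }, numeric(1))
                pairs <- cbind(orders, ids[nb])
                pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
                nxt[i] <- .hash32(c(r, ids[i], as.vector(t(pairs))))
            }
            # an atom with no neighbours has the same environment at every
            # radius; keep its identifier instead of minting a new one
        }
        ids <- nxt
        seen <- unique(c(seen, ids))
    }
    bits <- integer(nBits)
    bits[(seen %% nBits) + 1L] <- 1L
    bits
}

# atoms lying on at least one cycle: iteratively strip degree-1 atoms
.ringAtoms <- function(mol) {
    n <- length(mol$elements)
    deg <- mol$degree
    alive <- rep(TRUE, n)
    repeat {
        leaves <- which(alive & deg <= 1)
        if (!length(leaves)) break
        for (v in leaves) {
            alive[v] <- FALSE
            for (u in mol$adj[[v]]) if (alive[u]) deg[u] <- deg[u] - 1L
        }
    }
    alive
}

#' Compute hashed circular fingerprints
#'
#' Binary table with exactly \code{nBits(config)} columns, one row per
#' molecule in input order. Bits encode hashed circular atom environments up
#' to the configured radius (default 2), folded by modulus. Two SMILES of the
#' same structure give identical bit vectors. All fingerprint columns belong
#' to block \code{"fingerprint"}.
#'
#' @param x a curated \linkS4class{TasteDataset} or character vector of
#'   canonical SMILES
#' @param config a \linkS4class{FingerprintConfig}
#' @return a \linkS4class{FeatureTable} of 0/1 values
#' @export
computeFingerprints <- function(x, config = fingerprintConfig()) {
    stopifnot(is(config, "FingerprintConfig"))
    validObject(config)
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
    mols <- .parseStructures(canon, ids)
    nB <- config@nBits
    rows <- lapply(mols, function(m) {
        if (is.null(m)) return(rep(NA_integer_, nB))
        tryCatch(.circularBits(m, nB, config@radius),
                 error = function(e) rep(NA_integer_, nB))
    })
    values <- do.call(rbind, rows)
    dimnames(values) <- list(ids, sprintf("fp%04d", seq_len(nB)))
    new("FeatureTable", values = values, missingMask = is.na(values),
        blockOf = structure(rep("fingerprint", nB),
                            names = colnames(values)))
}

#' Compute descriptors and fingerprints in one table
#'
#' Convenience featurizer used by the screening pipeline: column-binds the 2D
#' descriptor blocks and the circular fingerprint for the same molecules.
#'
#' @param x a curated \linkS4class{TasteDataset}
#' @param what "descriptors", "fingerprints" or "both"
#' @param blocks descriptor blocks to compute (when requested)
#' @param config fingerprint configuration (when requested)
#' @return a \linkS4class{FeatureTable}
#' @export
featurizeDataset <- function(x, what = c("both", "descriptors", "fingerprints"),
                             blocks = descriptorBlocks()$block,
                             config = fingerprintConfig()) {
    what <- match.arg(what)
    if (what == "descriptors") return(computeDescriptorTable(x, blocks))
    if (what == "fingerprints") return(computeFingerprints(x, config))
    combineFeatures(computeDescriptorTable(x, blocks),
                    computeFingerprints(x, config))
}
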