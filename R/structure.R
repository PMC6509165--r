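# Internal molecular-graph model built on ChemmineR/ChemmineOB (OpenBabel).
# Molecules are parsed from canonical SMILES into a heavy-atom graph with
# formal charges, perceived aromaticity, implicit hydrogen counts (standard
# valence model) and Gasteiger partial charges.

.ELEMENT_DATA <- local({
    sym <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl",
             "As", "Se", "Br", "I")
    data.frame(
        symbol = sym,
        mass = c(1.008, 10.81, 12.011, 14.007, 15.999, 18.998, 28.085,
                 30.974, 32.06, 35.45, 74.922, 78.971, 79.904, 126.904),
        en = c(2.20, 2.04, 2.55, 3.04, 3.44, 3.98, 1.90, 2.19, 2.58, 3.16,
               2.18, 2.55, 2.96, 2.66),
        valence = c(1, 3, 4, 3, 2, 1, 4, 3, 2, 1, 3, 2, 1, 1),
        zv = c(1, 3, 4, 5, 6, 7, 4, 5, 6, 7, 5, 6, 7, 7),
        row = c(1, 2, 2, 2, 2, 2, 3, 3, 3, 3, 4, 4, 4, 5),
        rvdw = c(1.20, 1.92, 1.70, 1.55, 1.52, 1.47, 2.10, 1.80, 1.80, 1.75,
                 1.85, 1.90, 1.85, 1.98),
        rcov = c(0.37, 0.82, 0.77, 0.75, 0.73, 0.71, 1.17, 1.10, 1.03, 0.99,
                 1.21, 1.16, 1.14, 1.33),
        row.names = sym, stringsAsFactors = FALSE)
})

.MDL_CHARGE <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
                 `6` = -2, `7` = -3)

# implicit hydrogens under the standard valence model, with hypervalent P/S
# bumped to the next standard valence and charge adjustments for N/P (+1 adds
# a bond), O/S (+/- shifts capacity) and C/B
.implicitH <- function(elem, charge, boSum) {
    ed <- .ELEMENT_DATA[elem, ]
    val <- ed$valence
    val[elem == "P" & boSum > 3] <- 5
    val[elem == "S" & boSum > 2 & boSum <= 4] <- 4
    val[elem == "S" & boSum > 4] <- 6
    adj <- ifelse(elem %in% c("N", "P", "O", "S", "Se"), charge,
           ifelse(elem %in% c("C", "Si"), -abs(charge),
           ifelse(elem == "B", charge, 0)))
    pmax(0, round(val + adj - boSum))
}

# parse Gasteiger charges out of MOL2 text written by OpenBabel
.gasteigerCharges <- function(canon) {
    txt <- tryCatch(
        ChemmineOB::convertFormat(
            "SMI", "MOL2",
            paste0(paste(canon, paste0("m", seq_along(canon)), sep = "\t"),
                   "\n", collapse = "")),
        error = function(e) "")
    out <- vector("list", length(canon))
    if (!nzchar(txt)) return(out)
    blocks <- strsplit(txt, "@<TRIPOS>MOLECULE", fixed = TRUE)[[1]][-1]
    if (length(blocks) != length(canon)) return(out)
    for (i in seq_along(blocks)) {
        lines <- strsplit(blocks[i], "\n", fixed = TRUE)[[1]]
        a0 <- which(lines == "@<TRIPOS>ATOM")
        if (!length(a0)) next
        j <- a0[1] + 1L
        q <- numeric(0)
        while (j <= length(lines) && !startsWith(lines[j], "@")) {
            f <- strsplit(trimws(lines[j]), "[ \t]+")[[1]]
            if (length(f) >= 9) q <- c(q, suppressWarnings(as.numeric(f[9])))
            j <- j + 1L
        }
        out[[i]] <- q
    }
    out
}

# BFS topological distance matrix of the heavy-atom graph
.distanceMatrix <- function(adj) {
    n <- length(adj)
    D <- matrix(Inf, n, n)
    for (s in seq_len(n)) {
        D[s, s] <- 0
        frontier <- s
        d <- 0
        while (length(frontier)) {
            d <- d + 1
            nxt <- unique(unlist(adj[frontier]))
            nxt <- nxt[D[s, nxt] == Inf]
            D[s, nxt] <- d
            frontier <- nxt
        }
    }
    D
}

# Single heavy-atom structures ("C", "[Na+]", "[O-2]", ...) are built
# directly from the SMILES: ChemmineR misparses molblocks with zero bonds.
.singleAtomMol <- function(smi, gast) {
    m <- regmatches(smi, regexec(
        "^\\[?([A-Z][a-z]?)H?[0-9]?([+-][0-9]?|[+]+|[-]+)?\\]?$", smi))[[1]]
    if (!length(m)) return(NULL)
    elem <- m[2]
    chg <- m[3]
    charge <- if (!nzchar(chg)) 0
        else if (grepl("^[+-][0-9]$", chg))
            as.integer(substr(chg, 2, 2)) * if (startsWith(chg, "-")) -1 else 1
        else nchar(chg) * if (startsWith(chg, "-")) -1 else 1
    known <- elem %in% rownames(.ELEMENT_DATA)
    nH <- if (known) .implicitH(elem, charge, 0) else NA_real_
    # bare single-letter SMILES atoms carry implicit hydrogens; bracket
    # atoms suppress them unless written out
    if (startsWith(smi, "[") && !grepl("H", smi)) nH <- 0
    q <- if (!is.null(gast) && length(gast) == 1L) gast else NULL
    list(elements = elem, charge = charge, arom = FALSE,
         bonds = matrix(numeric(0), 0, 3,
                        dimnames = list(NULL, c("from", "to", "order"))),
         adj = list(integer(0)), degree = 0L, boSum = 0,
         nH = nH, gasteiger = q, aromRings = 0L, nRot = 0L,
         D = matrix(0, 1, 1), known = known)
}

# Parse canonical SMILES into internal molecule objects. Returns a list with
# one entry per molecule (NULL where parsing failed); each entry carries:
# elements, charge, arom, bonds (from/to/order), adj, degree, boSum, nH,
# gasteiger, aromRings, nRot, D (distance matrix).
.parseStructures <- function(canon, ids = NULL) {
    stopifnot(length(canon) >= 1L)
    if (is.null(ids)) ids <- paste0("m", seq_along(canon))
    nm <- paste0("m", seq_along(canon))
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(structure(canon, names = nm)))
    gast <- .gasteigerCharges(canon)
    nrot <- tryCatch(
        as.integer(ChemmineR::smartsSearchOB(
            sdf, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]", uniqueMatches = TRUE)),
        error = function(e) rep(NA_integer_, length(canon)))
    out <- vector("list", length(canon))
    names(out) <- ids
    for (i in seq_along(canon)) {
        single <- .singleAtomMol(canon[i], gast[[i]])
        if (!is.null(single)) {
            out[i] <- list(single)
            next
        }
        mol <- tryCatch({
            m <- sdf[[i]]
            ab <- ChemmineR::atomblock(m)
            elements <- sub("_.*$", "", rownames(ab))
            if (!all(grepl("^[A-Za-z]", elements)))
                stop("degenerate atom block")
            nA <- length(elements)
            chargeCode <- if ("C6" %in% colnames(ab)) ab[, "C6"] else
                rep(0, nA)
            charge <- unname(.MDL_CHARGE[as.character(chargeCode)])
            charge[is.na(charge)] <- 0
            bb <- ChemmineR::bondblock(m)
            bonds <- if (nrow(bb)) cbind(from = unname(bb[, 1]),
                                         to = unname(bb[, 2]),
                                         order = unname(bb[, 3]))
                     else matrix(numeric(0), 0, 3,
                                 dimnames = list(NULL,
                                                 c("from", "to", "order")))
            adj <- vector("list", nA)
            boSum <- numeric(nA)
            degree <- integer(nA)
            if (nrow(bonds)) for (b in seq_len(nrow(bonds))) {
                f <- bonds[b, 1]; t <- bonds[b, 2]; o <- bonds[b, 3]
                adj[[f]] <- c(adj[[f]], t); adj[[t]] <- c(adj[[t]], f)
                boSum[f] <- boSum[f] + o; boSum[t] <- boSum[t] + o
                degree[f] <- degree[f] + 1L; degree[t] <- degree[t] + 1L
            }
            arom <- rep(FALSE, nA)
            aromRings <- 0L
            rr <- tryCatch(ChemmineR::rings(m, upper = 7, type = "all",
                                            arom = TRUE),
                           error = function(e) NULL)
            if (!is.null(rr) && length(rr$RINGS)) {
                aromFlags <- rr$AROMATIC
                aromRings <- sum(aromFlags)
                idxOf <- structure(seq_len(nA), names = rownames(ab))
                for (k in seq_along(rr$RINGS)) {
                    if (isTRUE(aromFlags[[k]]))
                        arom[idxOf[rr$RINGS[[k]]]] <- TRUE
                }
            }
            known <- elements %in% rownames(.ELEMENT_DATA)
            nH <- rep(NA_real_, nA)
            nH[known] <- .implicitH(elements[known], charge[known],
                                    boSum[known])
            q <- gast[[i]]
            if (!is.null(q) && length(q) != nA) q <- NULL
            list(elements = elements, charge = charge, arom = arom,
                 bonds = bonds, adj = adj, degree = degree, boSum = boSum,
                 nH = nH, gasteiger = q, aromRings = aromRings,
                 nRot = nrot[i], D = .distanceMatrix(adj),
                 known = known)
        }, error = function(e) NULL)
        out[i] <- list(mol)
    }
    out
}
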