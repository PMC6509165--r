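#' @include AllClasses.R methods.R
NULL

## SMILES sanity pre-check. OpenBabel silently repairs some malformed inputs
## (e.g. an unclosed branch), so structural balance is enforced here before
## conversion: parentheses must nest, brackets must pair without nesting, and
## ring-closure labels outside brackets must pair up.
.smilesBalanced <- function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    depth <- 0L; inBracket <- FALSE
    rings <- character(); i <- 1L; n <- length(chars)
    while (i <= n) {
        ch <- chars[i]
        if (inBracket) {
            if (ch == "[") return(FALSE)
            if (ch == "]") inBracket <- FALSE
        } else if (ch == "[") {
            inBracket <- TRUE
        } else if (ch == "]") {
            return(FALSE)
        } else if (ch == "(") {
            depth <- depth + 1L
        } else if (ch == ")") {
            depth <- depth - 1L
            if (depth < 0L) return(FALSE)
        } else if (ch == "%") {
            if (i + 2L > n) return(FALSE)
            rings <- c(rings, paste0(chars[i + 1L], chars[i + 2L]))
            i <- i + 2L
        } else if (grepl("[0-9]", ch)) {
            rings <- c(rings, ch)
        }
        i <- i + 1L
    }
    if (depth != 0L || inBracket) return(FALSE)
    all(table(rings) %% 2L == 0L)
}

#' Canonicalize SMILES strings
#'
#' Converts each SMILES to its OpenBabel canonical form, so that different
#' encodings of the same structure (including Kekule vs aromatic forms) map to
#' one string. Idempotent.
#'
#' @param smiles character vector
#' @param strict if TRUE (default), an unparseable SMILES raises an error
#'   naming the offending string; if FALSE it yields NA
#' @return character vector of canonical SMILES (NA for failures when
#'   \code{strict = FALSE})
#' @examples
#' \dontrun{canonicalizeSmiles(c("C(C)O", "CCO"))  # both "CCO"}
#' @export
canonicalizeSmiles <- function(smiles, strict = TRUE) {
    out <- vapply(as.character(smiles), function(s) {
        if (!.smilesBalanced(s)) return(NA_character_)
        res <- tryCatch(
            ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n")),
            error = function(e) "")
        res <- sub("[ \t].*$", "", sub("\n.*$", "", res))
        if (!nzchar(res)) NA_character_ else res
    }, character(1), USE.NAMES = FALSE)
    if (strict && anyNA(out)) {
        bad <- smiles[is.na(out)]
        stop("unparseable SMILES: ", paste(sQuote(bad), collapse = ", "))
    }
    out
}

.mapLabel <- function(x) {
    x <- tolower(trimws(as.character(x)))
    pos <- c("1", "true", "positive", "yes", "bitter", "sweet")
    neg <- c("0", "false", "negative", "no", "non-bitter", "non-sweet",
             "nonbitter", "nonsweet", "tasteless")
    out <- rep("unknown", length(x))
    out[x %in% pos] <- "positive"
    out[x %in% neg] <- "negative"
    out
}

#' Read a molecule table
#'
#' Reads CSV/TSV (header row required, UTF-8) or SMI (one SMILES per line,
#' optional whitespace-separated id) into a \linkS4class{TasteDataset}. Row
#' order is preserved; labels are mapped onto positive/negative/unknown
#' (accepted encodings: 1/0, true/false, yes/no, bitter/non-bitter,
#' sweet/non-sweet, tasteless).
#'
#' @param path input file
#' @param format "csv", "tsv" or "smi"
#' @param smilesColumn column holding SMILES (csv/tsv)
#' @param idColumn optional id column; defaults to "id" when present, else
#'   sequential ids are generated
#' @param labelColumns optional named character, e.g.
#'   \code{c(bitter = "bitter", sweet = "sweet_flag")}
#' @param source provenance tag stored on every record
#' @return a \linkS4class{TasteDataset}
#' @export
readMoleculeTable <- function(path, format = c("csv", "tsv", "smi"),
                              smilesColumn = "smiles", idColumn = "id",
                              labelColumns = NULL, source = basename(path)) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "smi") {
        lines <- readLines(path, encoding = "UTF-8")
        lines <- lines[nzchar(trimws(lines))]
        if (!length(lines)) stop("empty SMI file: ", path)
        parts <- strsplit(trimws(lines), "[ \t]+")
        smi <- vapply(parts, `[`, character(1), 1L)
        ids <- vapply(seq_along(parts), function(i) {
            if (length(parts[[i]]) > 1L) parts[[i]][2L] else paste0("mol", i)
        }, character(1))
        return(TasteDataset(id = ids, smiles = smi, source = source))
    }
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                            stringsAsFactors = FALSE, comment.char = "",
                            fileEncoding = "UTF-8", check.names = FALSE)
    if (!nrow(df)) stop("empty molecule table: ", path)
    if (!smilesColumn %in% colnames(df))
        stop("SMILES column ", sQuote(smilesColumn), " not found in ", path)
    ids <- if (idColumn %in% colnames(df)) as.character(df[[idColumn]])
           else sprintf("mol%d", seq_len(nrow(df)))
    bit <- swt <- rep("unknown", nrow(df))
    if (!is.null(labelColumns)) {
        for (task in names(labelColumns)) {
            col <- labelColumns[[task]]
            if (!col %in% colnames(df))
                stop("label column ", sQuote(col), " not found in ", path)
            if (task == "bitter") bit <- .mapLabel(df[[col]])
            if (task == "sweet") swt <- .mapLabel(df[[col]])
        }
    } else {
        if ("bitter" %in% colnames(df)) bit <- .mapLabel(df$bitter)
        if ("sweet" %in% colnames(df)) swt <- .mapLabel(df$sweet)
    }
    spl <- if ("split" %in% colnames(df)) {
        s <- as.character(df$split); s[!s %in% .SPLIT_LEVELS] <- "unassigned"; s
    } else "unassigned"
    TasteDataset(id = ids, smiles = as.character(df[[smilesColumn]]),
                 canonical_smiles =
                     if ("canonical_smiles" %in% colnames(df))
                         as.character(df$canonical_smiles) else NA_character_,
                 bitter_label = bit, sweet_label = swt,
                 source = if ("source" %in% colnames(df))
                     as.character(df$source) else source,
                 split = spl)
}

## heavy-atom count and organic (carbon-containing) flag per SMILES, via the
## parsed structure; returns data.frame(heavy, organic)
.fragmentStats <- function(frags) {
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(
        structure(frags, names = paste0("f", seq_along(frags)))))
    counts <- ChemmineR::atomcount(sdf)
    heavy <- vapply(counts, sum, numeric(1))
    organic <- vapply(counts, function(x) "C" %in% names(x), logical(1))
    data.frame(heavy = heavy, organic = organic)
}

.countResidues <- function(canon) {
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(
        structure(canon, names = paste0("m", seq_along(canon)))))
    res <- ChemmineR::smartsSearchOB(sdf, "[NX3][CX4][CX3](=O)",
                                     uniqueMatches = TRUE)
    ami <- ChemmineR::smartsSearchOB(sdf, "[CX3](=O)[NX3]",
                                     uniqueMatches = TRUE)
    data.frame(residues = as.integer(res), amides = as.integer(ami))
}

#' Curate a molecule dataset
#'
#' Applies, in order: canonicalization (invalid structures logged), salt/ion
#' reduction (disconnected records are reduced to their largest
#' carbon-containing fragment and dropped when none exists), a minimum
#' heavy-atom filter, a peptide filter (at least \code{minResidues}
#' alpha-amino-acid residue units joined by an amide bond), and duplicate
#' pruning on canonical SMILES (first record kept; conflicting labels among
#' duplicates reset the kept record's label to unknown for that task).
#'
#' Problems are logged, never raised; curation is idempotent.
#'
#' @param x a \linkS4class{TasteDataset}
#' @param minHeavyAtoms molecules with fewer heavy (non-hydrogen) atoms are
#'   removed (default 3)
#' @param minResidues residue-unit count at which a molecule counts as a
#'   peptide (default 2; a dipeptide is removed)
#' @return list with elements \code{dataset} (curated
#'   \linkS4class{TasteDataset}) and \code{log} (a \linkS4class{CurationLog})
#' @export
curateDataset <- function(x, minHeavyAtoms = 3L, minResidues = 2L) {
    stopifnot(is(x, "TasteDataset"))
    rec <- x@records
    n0 <- nrow(rec)
    mk <- function(inv = 0L, dup = 0L, salt = 0L, small = 0L, pep = 0L,
                   kept = 0L)
        new("CurationLog", nInput = n0, nInvalid = inv,
            nDuplicatesRemoved = dup, nSaltOrIonRemoved = salt,
            nTooSmallRemoved = small, nPeptideRemoved = pep, nRetained = kept)
    if (!n0) return(list(dataset = x, log = mk()))

    canon <- canonicalizeSmiles(rec$smiles, strict = FALSE)
    invalid <- is.na(canon)
    nInvalid <- sum(invalid)
    rec <- rec[!invalid, , drop = FALSE]
    canon <- canon[!invalid]

    ## salt / multi-fragment reduction
    nSalt <- 0L
    if (nrow(rec)) {
        multi <- grepl(".", canon, fixed = TRUE)
        dropSalt <- rep(FALSE, nrow(rec))
        for (i in which(multi)) {
            frags <- strsplit(canon[i], ".", fixed = TRUE)[[1]]
            st <- .fragmentStats(frags)
            org <- which(st$organic)
            if (!length(org)) {
                dropSalt[i] <- TRUE
            } else {
                best <- org[which.max(st$heavy[org])]
                canon[i] <- canonicalizeSmiles(frags[best])
            }
        }
        nSalt <- sum(dropSalt)
        rec <- rec[!dropSalt, , drop = FALSE]
        canon <- canon[!dropSalt]
    }

    ## size filter
    nSmall <- 0L
    if (nrow(rec)) {
        st <- .fragmentStats(canon)
        small <- st$heavy < minHeavyAtoms
        nSmall <- sum(small)
        rec <- rec[!small, , drop = FALSE]
        canon <- canon[!small]
    }

    ## peptide filter
    nPep <- 0L
    if (nrow(rec)) {
        pe <- .countResidues(canon)
        pep <- pe$residues >= minResidues & pe$amides >= 1L
        nPep <- sum(pep)
        rec <- rec[!pep, , drop = FALSE]
        canon <- canon[!pep]
    }

    ## duplicate pruning (first seen kept; label conflicts -> unknown)
    nDup <- 0L
    if (nrow(rec)) {
        keep <- !duplicated(canon)
        nDup <- sum(!keep)
        for (task in c("bitter_label", "sweet_label")) {
            lab <- rec[[task]]
            agg <- tapply(lab, canon, function(v) {
                v <- unique(v[v != "unknown"])
                if (length(v) == 1L) v else if (length(v) > 1L) "conflict"
                else "unknown"
            })
            merged <- unname(agg[canon[keep]])
            conflicted <- merged == "conflict"
            if (any(conflicted))
                warning(sum(conflicted), " duplicate group(s) with conflicting ",
                        sub("_label", "", task), " labels; set to unknown")
            merged[conflicted] <- "unknown"
            rec[[task]][keep] <- merged
        }
        rec <- rec[keep, , drop = FALSE]
        canon <- canon[keep]
    }

    rec$canonical_smiles <- canon
    rownames(rec) <- NULL
    list(dataset = new("TasteDataset", records = rec),
         log = mk(inv = nInvalid, dup = nDup, salt = nSalt, small = nSmall,
                  pep = nPep, kept = nrow(rec)))
}

#' Split a dataset into train and test sets
#'
#' @param x a curated \linkS4class{TasteDataset}
#' @param assignment named character vector, id -> "train"/"test"
#' @return list(train = TasteDataset, test = TasteDataset); unassigned ids are
#'   left out of both
#' @export
splitDataset <- function(x, assignment) {
    stopifnot(is(x, "TasteDataset"))
    if (!length(assignment)) {
        warning("empty split assignment; returning two empty datasets")
        return(list(train = x[integer(0)], test = x[integer(0)]))
    }
    if (!all(assignment %in% c("train", "test")))
        stop("assignment values must be 'train' or 'test'")
    unknown <- setdiff(names(assignment), x@records$id)
    if (length(unknown))
        stop("unknown molecule id(s) in assignment: ",
             paste(unknown, collapse = ", "))
    rec <- x@records
    side <- assignment[rec$id]
    canon <- rec$canonical_smiles
    both <- intersect(canon[which(side == "train")],
                      canon[which(side == "test")])
    both <- both[!is.na(both)]
    if (length(both))
        stop("train/test leakage: structure(s) assigned to both splits: ",
             paste(both, collapse = ", "))
    tr <- x[which(side == "train")]
    te <- x[which(side == "test")]
    tr@records$split <- "train"
    te@records$split <- "test"
    list(train = tr, test = te)
}

#' Write a molecule table as CSV
#' @param x a TasteDataset
#' @param path output file
#' @return invisibly, the path
#' @export
writeMoleculeTable <- function(x, path) {
    utils::write.csv(x@records, path, row.names = FALSE, na = "")
    invisible(path)
}

#' Write a curation log as JSON
#' @param log a CurationLog
#' @param path output file
#' @return invisibly, the path
#' @export
writeCurationLog <- function(log, path) {
    jsonlite::write_json(as.list(log), path, auto_unbox = TRUE)
    invisible(path)
}
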