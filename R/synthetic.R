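#' @include AllClasses.R methods.R descriptors.R
NULL

#' Synthetic labelled feature table with planted signal
#'
#' Gaussian class-conditional generator for testing the selection and model
#' pipeline against known ground truth: the relevant features carry a
#' standardized mean shift of \code{effectSize} between the classes (unit
#' variance within class), noise features are independent of the labels.
#' Block labels are assigned round-robin across the descriptor-block
#' registry so block-aggregation code can be exercised. Pure function of the
#' seed and settings.
#'
#' @param nSamples number of rows
#' @param dRelevant number of planted informative features
#' @param dNoise number of pure-noise features
#' @param effectSize standardized between-class mean shift of the relevant
#'   features (0 = null data)
#' @param classBalance positive-class fraction in (0, 1)
#' @param seed RNG seed
#' @param heavyTailed draw from a t(3) distribution (rescaled to unit
#'   variance) instead of a normal, for robustness checks
#' @return list: \code{table} (a \linkS4class{FeatureTable}), \code{labels}
#'   (integer 0/1), \code{truth} (names of planted features and the
#'   generating settings; \code{informative = FALSE} when
#'   \code{effectSize == 0})
#' @export
makeClassificationTable <- function(nSamples = 500L, dRelevant = 10L,
                                    dNoise = 90L, effectSize = 1,
                                    classBalance = 0.5, seed = 1L,
                                    heavyTailed = FALSE) {
    stopifnot(nSamples > 0, dRelevant > 0, dNoise >= 0, effectSize >= 0,
              classBalance > 0, classBalance < 1)
    set.seed(seed)
    nPos <- max(1L, min(nSamples - 1L, round(nSamples * classBalance)))
    y <- sample(rep(c(1L, 0L), c(nPos, nSamples - nPos)))
    d <- dRelevant + dNoise
    rdraw <- function(n) {
        if (heavyTailed) stats::rt(n, df = 3) / sqrt(3)
        else stats::rnorm(n)
    }
    v <- matrix(rdraw(nSamples * d), nSamples, d)
    relNames <- sprintf("rel%02d", seq_len(dRelevant))
    noiseNames <- if (dNoise) sprintf("noise%03d", seq_len(dNoise))
                  else character(0)
    colnames(v) <- c(relNames, noiseNames)
    rownames(v) <- sprintf("s%04d", seq_len(nSamples))
    v[, seq_len(dRelevant)] <- v[, seq_len(dRelevant)] + effectSize * y
    blocks <- descriptorBlocks()$block
    blockOf <- structure(rep(blocks, length.out = d), names = colnames(v))
    tab <- new("FeatureTable", values = v,
               missingMask = matrix(FALSE, nSamples, d, dimnames = dimnames(v)),
               blockOf = blockOf)
    list(table = tab, labels = y,
         truth = list(relevant = relNames,
                      informative = effectSize > 0,
                      settings = list(nSamples = nSamples,
                                      dRelevant = dRelevant, dNoise = dNoise,
                                      effectSize = effectSize,
                                      classBalance = classBalance,
                                      seed = seed)))
}

# version-pinned toy molecule fixture: ids, SMILES, pseudo-labels, and the
# curation outcome each row is designed to exercise
.TOY_MOLECULES <- local({
    m <- rbind(
        c("ethanol",        "CCO",                          "unknown", "negative"),
        c("ethanol_alt",    "C(C)O",                        "unknown", "negative"),
        c("benzene",        "c1ccccc1",                     "unknown", "negative"),
        c("benzene_alt",    "C1=CC=CC=C1",                  "unknown", "negative"),
        c("halite",         "[Na+].[Cl-]",                  "unknown", "unknown"),
        c("sodium_acetate", "CC(=O)[O-].[Na+]",             "unknown", "negative"),
        c("methanol",       "CO",                           "unknown", "negative"),
        c("glycylglycine",  "NCC(=O)NCC(=O)O",              "unknown", "unknown"),
        c("broken",         "C1CC",                         "unknown", "unknown"),
        c("caffeine",       "Cn1cnc2c1c(=O)n(C)c(=O)n2C",   "positive", "negative"),
        c("quinine",  "COc1ccc2nccc(C(O)C3CC4CCN3CC4C=C)c2c1", "positive", "negative"),
        c("saccharin",      "O=C1NS(=O)(=O)c2ccccc21",      "negative", "positive"),
        c("glucose",        "OCC1OC(O)C(O)C(O)C1O",         "negative", "positive"),
        c("sucrose", "OCC1OC(OC2(CO)OC(CO)C(O)C2O)C(O)C(O)C1O", "negative", "positive"),
        c("fructose",       "OCC1(O)OCC(O)C(O)C1O",         "negative", "positive"),
        c("citric_acid",    "OC(=O)CC(O)(C(=O)O)CC(=O)O",   "negative", "negative"),
        c("nicotine",       "CN1CCCC1c1cccnc1",             "positive", "negative"),
        c("menthol",        "CC(C)C1CCC(C)CC1O",            "negative", "negative"),
        c("vanillin",       "COc1cc(C=O)ccc1O",             "negative", "positive"),
        c("limonene",       "CC1=CCC(CC1)C(=C)C",           "negative", "negative"),
        c("acetamide",      "CC(=O)N",                      "unknown", "unknown"),
        c("aspirin",        "CC(=O)Oc1ccccc1C(=O)O",        "positive", "negative"),
        c("naringenin", "Oc1ccc2c(c1)OC(c1ccc(O)cc1)CC2=O", "positive", "negative"),
        c("glycerol",       "OCC(O)CO",                     "negative", "positive"),
        c("xylitol",        "OCC(O)C(O)C(O)CO",             "negative", "positive"),
        c("sorbitol",       "OCC(O)C(O)C(O)C(O)CO",         "negative", "positive"),
        c("ethyl_acetate",  "CCOC(C)=O",                    "negative", "negative"),
        c("toluene",        "Cc1ccccc1",                    "negative", "negative"),
        c("phenol",         "Oc1ccccc1",                    "negative", "negative"),
        c("pyridine",       "c1ccncc1",                     "positive", "negative"),
        c("acetone",        "CC(C)=O",                      "negative", "negative"),
        c("butanol",        "CCCCO",                        "negative", "negative"),
        c("benzaldehyde",   "O=Cc1ccccc1",                  "negative", "negative"),
        c("anethole",       "COc1ccc(C=CC)cc1",             "negative", "positive"),
        c("eugenol",        "COc1cc(CC=C)ccc1O",            "negative", "negative"),
        c("coumarin",       "O=C1C=Cc2ccccc2O1",            "negative", "positive"),
        c("theobromine",    "Cn1cnc2c1c(=O)[nH]c(=O)n2C",   "positive", "negative"),
        c("chloroform",     "ClC(Cl)Cl",                    "negative", "negative"),
        c("urea",           "NC(N)=O",                      "negative", "negative"),
        c("alanine",        "CC(N)C(=O)O",                  "unknown", "negative"))
    colnames(m) <- c("id", "smiles", "bitter", "sweet")
    as.data.frame(m, stringsAsFactors = FALSE)
})

#' Built-in toy molecule fixture
#'
#' Forty hand-written SMILES spanning small organics, one inorganic salt
#' pair, one reducible organic salt, one dipeptide, one two-heavy-atom
#' molecule, one malformed SMILES and two structures duplicated under
#' different SMILES spellings, plus pseudo-labels. Designed so that
#' curation removes a known subset: 1 invalid, 1 salt, 1 too-small,
#' 1 peptide, 2 duplicates, leaving 34 molecules.
#'
#' @return a \linkS4class{TasteDataset} of 40 records
#' @export
makeToyMolecules <- function() {
    TasteDataset(id = .TOY_MOLECULES$id, smiles = .TOY_MOLECULES$smiles,
                 bitter_label = .TOY_MOLECULES$bitter,
                 sweet_label = .TOY_MOLECULES$sweet,
                 source = "builtin-toy")
}

#' Synthetic score/label pairs with a target AUROC
#'
#' Binormal model: negatives ~ N(0, 1), positives ~ N(mu, 1) with
#' mu = sqrt(2) * qnorm(aucTarget), for which the expected AUROC equals
#' \code{aucTarget}. Used to test the metric estimators.
#'
#' @param n total number of instances (balanced classes)
#' @param aucTarget expected AUROC in [0.5, 1]; 1 gives full separation
#' @param seed RNG seed
#' @return list: \code{labels} (integer 0/1), \code{scores} (numeric)
#' @export
makeScoreLabelPairs <- function(n, aucTarget, seed = 1L) {
    stopifnot(aucTarget >= 0.5, aucTarget <= 1)
    set.seed(seed)
    nPos <- n %/% 2L
    mu <- if (aucTarget >= 1) 20 else sqrt(2) * stats::qnorm(aucTarget)
    y <- sample(rep(c(1L, 0L), c(nPos, n - nPos)))
    s <- stats::rnorm(n) + mu * y
    list(labels = y, scores = s)
}
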