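test_that("canonicalizeSmiles unifies equivalent SMILES spellings", {
    expect_identical(canonicalizeSmiles("C(C)O"), canonicalizeSmiles("CCO"))
    expect_identical(canonicalizeSmiles("c1ccccc1"),
                     canonicalizeSmiles("C1=CC=CC=C1"))
    # idempotent
    can <- canonicalizeSmiles("CC(=O)Oc1ccccc1C(=O)O")
    expect_identical(canonicalizeSmiles(can), can)
})

test_that("canonicalizeSmiles rejects malformed input", {
    expect_error(canonicalizeSmiles("C1CC"), "pars|invalid|SMILES")
    expect_error(canonicalizeSmiles("C(C"), "pars|invalid|SMILES")
    expect_true(is.na(canonicalizeSmiles("C1CC", strict = FALSE)))
    expect_true(is.na(canonicalizeSmiles("C(C", strict = FALSE)))
})

test_that("molecule tables round-trip through CSV", {
    ds <- makeToyMolecules()
    path <- withr::local_tempfile(fileext = ".csv")
    writeMoleculeTable(ds, path)
    back <- readMoleculeTable(path, format = "csv",
                              labelColumns = c(bitter = "bitter_label",
                                               sweet = "sweet_label"))
    expect_equal(length(back), length(ds))
    expect_identical(moleculeIds(back), moleculeIds(ds))
    expect_identical(tasteLabels(back, "bitter"), tasteLabels(ds, "bitter"))
    expect_identical(tasteLabels(back, "sweet"), tasteLabels(ds, "sweet"))
})

test_that("curation removes the designed toy subset and reconciles", {
    res <- curateDataset(makeToyMolecules())
    log <- res$log
    expect_equal(log@nInput, 40L)
    expect_equal(log@nInvalid, 1L)
    expect_equal(log@nDuplicatesRemoved, 2L)
    expect_equal(log@nSaltOrIonRemoved, 1L)
    expect_equal(log@nTooSmallRemoved, 1L)
    expect_equal(log@nPeptideRemoved, 1L)
    expect_equal(log@nRetained, 34L)
    # the log reconciles: removals + retained == input
    l <- as.list(log)
    removed <- l$n_invalid + l$n_duplicates_removed + l$n_salt_or_ion_removed +
        l$n_too_small_removed + l$n_peptide_removed
    expect_equal(removed + l$n_retained, l$n_input)
    expect_equal(length(res$dataset), 34L)
    # the specific rows designed to fall
    gone <- c("ethanol_alt", "benzene_alt", "halite", "methanol",
              "glycylglycine", "broken")
    expect_length(intersect(moleculeIds(res$dataset), gone), 0)
})

test_that("curation is idempotent on a curated set", {
    first <- curateDataset(makeToyMolecules())
    second <- curateDataset(first$dataset)
    expect_equal(second$log@nRetained, first$log@nRetained)
    expect_equal(second$log@nInvalid + second$log@nDuplicatesRemoved +
                 second$log@nSaltOrIonRemoved + second$log@nTooSmallRemoved +
                 second$log@nPeptideRemoved, 0L)
    expect_identical(canonicalSmiles(second$dataset),
                     canonicalSmiles(first$dataset))
})

test_that("salt stripping keeps the largest organic fragment", {
    res <- curateDataset(TasteDataset(id = c("naac", "filler1", "filler2"),
                                      smiles = c("CC(=O)[O-].[Na+]",
                                                 "CCO", "CCCO")))
    canon <- canonicalSmiles(res$dataset)
    expect_identical(unname(canon[moleculeIds(res$dataset) == "naac"]),
                     canonicalizeSmiles("CC(=O)[O-]"))
    expect_equal(res$log@nSaltOrIonRemoved, 0L)
})

test_that("duplicate resolution keeps the first row and flags label conflicts", {
    ds <- TasteDataset(id = c("a", "b"), smiles = c("CCO", "C(C)O"),
                       bitter_label = c("positive", "negative"))
    expect_warning(res <- curateDataset(ds), "conflict")
    expect_equal(length(res$dataset), 1L)
    expect_identical(moleculeIds(res$dataset), "a")
    expect_identical(unname(tasteLabels(res$dataset, "bitter")), "unknown")
})

test_that("single amino acids and simple amides survive the peptide filter", {
    res <- curateDataset(makeToyMolecules())
    kept <- moleculeIds(res$dataset)
    expect_true("alanine" %in% kept)
    expect_true("acetamide" %in% kept)
    expect_true("urea" %in% kept)
})

test_that("splitDataset assigns and guards against leakage", {
    res <- curateDataset(makeToyMolecules())
    ds <- res$dataset
    n <- length(ds)
    assignment <- rep(c("train", "test"), length.out = n)
    names(assignment) <- moleculeIds(ds)
    sp <- splitDataset(ds, assignment)
    expect_equal(length(sp$train) + length(sp$test), n)
    expect_true(all(datasetRecords(sp$train)$split == "train"))
    expect_true(all(datasetRecords(sp$test)$split == "test"))
    # duplicate structures may not straddle the split
    dup <- TasteDataset(id = c("x", "y"), smiles = c("CCO", "CCO"),
                        canonical_smiles = c("CCO", "CCO"))
    expect_error(splitDataset(dup, structure(c("train", "test"),
                                             names = c("x", "y"))),
                 "leak")
})

test_that("writeCurationLog emits the JSON counters", {
    res <- curateDataset(makeToyMolecules())
    path <- withr::local_tempfile(fileext = ".json")
    writeCurationLog(res$log, path)
    j <- jsonlite::read_json(path)
    expect_equal(j$n_input, 40L)
    expect_equal(j$n_retained, 34L)
})
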