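canon <- function(s) canonicalizeSmiles(s)

test_that("constitution block matches hand counts on tiny molecules", {
    ft <- computeDescriptorTable(c(ethane = canon("CC"),
                                   benzene = canon("c1ccccc1"),
                                   butane = canon("CCCC")),
                                 blocks = "constitution")
    v <- featureValues(ft)
    expect_equal(v["ethane", "nHeavyAtoms"], 2)
    expect_equal(v["ethane", "nRings"], 0)
    expect_equal(v["benzene", "nHeavyAtoms"], 6)
    expect_equal(v["benzene", "nRings"], 1)
    expect_equal(v["benzene", "nAromaticRings"], 1)
    expect_equal(v["butane", "nRotatableBonds"], 1)
})

test_that("topology block matches hand-computed graph invariants", {
    ft <- computeDescriptorTable(c(butane = canon("CCCC"),
                                   cyclohexane = canon("C1CCCCC1")),
                                 blocks = "topology")
    v <- featureValues(ft)
    # n-butane path graph: distance sum over pairs = 1+2+3+1+2+1 = 10
    expect_equal(v["butane", "wiener"], 10)
    # first Zagreb index of butane: 1^2+2^2+2^2+1^2 = 10
    expect_equal(v["butane", "zagreb1"], 10)
    expect_equal(v["butane", "diameter"], 3)
    # cyclohexane: all degrees 2, diameter 3, radius 3
    expect_equal(v["cyclohexane", "zagreb1"], 24)
    expect_equal(v["cyclohexane", "radius"], 3)
    expect_equal(v["cyclohexane", "petitjean"], 0)
})

test_that("connectivity and kappa blocks match closed forms on butane", {
    ft <- computeDescriptorTable(c(butane = canon("CCCC"),
                                   ethane = canon("CC")),
                                 blocks = c("connectivity", "kappa"))
    v <- featureValues(ft)
    # chi0 = sum 1/sqrt(deg): 1 + 1/sqrt(2) + 1/sqrt(2) + 1
    expect_equal(v["butane", "chi0"], 2 + 2 / sqrt(2), tolerance = 1e-12)
    # chi1 over the 3 edges: 1/sqrt(1*2) + 1/sqrt(2*2) + 1/sqrt(2*1)
    expect_equal(v["butane", "chi1"], 2 / sqrt(2) + 0.5, tolerance = 1e-12)
    expect_equal(v["ethane", "chi0"], 2, tolerance = 1e-12)
    expect_equal(v["ethane", "chi1"], 1, tolerance = 1e-12)
    # kappa1 for a path graph on A atoms: A(A-1)^2/P1^2 with P1 = A-1
    expect_equal(v["butane", "kappa1"], 4 * 9 / 9, tolerance = 1e-12)
})

test_that("charge block is neutral and consistent for benzene", {
    ft <- computeDescriptorTable(c(benzene = canon("c1ccccc1")),
                                 blocks = "charge")
    v <- featureValues(ft)
    expect_equal(v[1, "totalFormalCharge"], 0)
    # Gasteiger charges of a neutral molecule sum to ~0
    expect_lt(abs(v[1, "totalPositiveCharge"] + v[1, "totalNegativeCharge"]),
              1e-3)
})

test_that("molecular properties come back on a sane scale", {
    ft <- computeDescriptorTable(c(ethane = canon("CC"),
                                   ethanol = canon("CCO")),
                                 blocks = "molecular_properties")
    v <- featureValues(ft)
    expect_equal(v["ethane", "MW"], 30.07, tolerance = 1e-3)
    expect_equal(v["ethanol", "MW"], 46.07, tolerance = 1e-3)
    expect_equal(v["ethanol", "HBD"], 1)
    expect_equal(v["ethane", "TPSA"], 0)
})

test_that("full descriptor table covers all registered blocks", {
    reg <- descriptorBlocks()
    expect_true(all(c("constitution", "topology", "connectivity", "kappa",
                      "charge", "burden", "estate", "moe_type",
                      "molecular_properties") %in% reg$block))
    cur <- curateDataset(makeToyMolecules())$dataset
    ft <- computeDescriptorTable(cur)
    expect_equal(nrow(featureValues(ft)), length(cur))
    expect_setequal(unique(unname(featureBlocks(ft))),
                    setdiff(reg$block, "fingerprint"))
    # a failed block marks features missing rather than erroring
    expect_identical(dim(missingMask(ft)), dim(featureValues(ft)))
    expect_error(computeDescriptorTable(cur, blocks = "no_such_block"),
                 "block")
})

test_that("cleanFeatures imputes medians and drops bad columns", {
    v <- cbind(good = c(1, 2, 4, 5),
               holey = c(1, 2, NA, 4),
               mostlyNA = c(1, NA, NA, NA),
               constant = c(7, 7, 7, 7))
    rownames(v) <- paste0("m", 1:4)
    ft <- FeatureTable(v, blockOf = structure(rep("constitution", 4),
                                              names = colnames(v)))
    out <- cleanFeatures(ft, maxMissingFraction = 0.5)
    expect_setequal(featureNames(out), c("good", "holey"))
    # median of the observed {1, 2, 4} is 2
    expect_equal(featureValues(out)["m3", "holey"], 2)
    expect_false(any(missingMask(out)))
    expect_setequal(attr(out, "dropped"), c("mostlyNA", "constant"))
})

test_that("fingerprints are binary, sized and spelling-invariant", {
    cfg <- fingerprintConfig(nBits = 2048L, radius = 2L)
    fp <- computeFingerprints(c(a = canon("CCO"), b = canon("C(C)O"),
                                c = canon("Cn1cnc2c1c(=O)n(C)c(=O)n2C")),
                              cfg)
    v <- featureValues(fp)
    expect_identical(dim(v), c(3L, 2048L))
    expect_true(all(v %in% c(0, 1)))
    expect_identical(unname(v["a", ]), unname(v["b", ]))
    expect_gt(sum(v["c", ]), sum(v["a", ]))  # larger molecule, more bits
    expect_true(all(unname(featureBlocks(fp)) == "fingerprint"))
})

test_that("fingerprint radius-0 edge case and config validation", {
    # single heavy atom (methane) has only radius-0 environments
    fp <- computeFingerprints(c(methane = canon("C")),
                              fingerprintConfig(nBits = 64L, radius = 2L))
    expect_equal(sum(featureValues(fp)), 1)
    expect_error(fingerprintConfig(nBits = 100L), "power")
    expect_error(fingerprintConfig(nBits = 32L), "power|64")
})

test_that("featurizeDataset concatenates descriptors and fingerprints", {
    cur <- curateDataset(makeToyMolecules())$dataset
    sub <- cur[1:6]
    both <- featurizeDataset(sub, what = "both",
                             config = fingerprintConfig(nBits = 128L))
    des <- featurizeDataset(sub, what = "descriptors")
    expect_equal(ncol(featureValues(both)),
                 ncol(featureValues(des)) + 128L)
    expect_identical(moleculeIds(both), moleculeIds(sub))
})
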