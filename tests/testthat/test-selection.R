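test_that("borutaSelect recovers planted features on easy data", {
    d <- makeClassificationTable(nSamples = 200, dRelevant = 5, dNoise = 20,
                                 effectSize = 2, seed = 3)
    cfg <- borutaConfig(nIterations = 30, numTrees = 50, seed = 3)
    res <- borutaSelect(d$table, d$labels, cfg)
    cf <- confirmedFeatures(res)
    expect_gte(sum(cf %in% d$truth$relevant), 4)
    expect_lte(sum(!cf %in% d$truth$relevant), 2)
    expect_equal(res@nIterations, 30L)
    expect_equal(nrow(res@importanceHistory), 30L)
    # hits can never exceed the iteration count
    expect_true(all(res@hits <= 30L))
})

test_that("borutaSelect is deterministic given the config seed", {
    d <- makeClassificationTable(nSamples = 100, dRelevant = 3, dNoise = 10,
                                 effectSize = 1.5, seed = 5)
    cfg <- borutaConfig(nIterations = 12, numTrees = 30, seed = 9)
    r1 <- borutaSelect(d$table, d$labels, cfg)
    r2 <- borutaSelect(d$table, d$labels, cfg)
    expect_identical(r1@status, r2@status)
    expect_identical(r1@importanceHistory, r2@importanceHistory)
    expect_identical(r1@shadowMaxHistory, r2@shadowMaxHistory)
})

test_that("boruta input validation", {
    d <- makeClassificationTable(nSamples = 40, dRelevant = 2, dNoise = 4,
                                 seed = 1)
    expect_error(borutaSelect(d$table, rep(1, 40)), "both classes")
    expect_error(borutaSelect(d$table, d$labels[-1]), "mismatch")
    expect_error(borutaConfig(nIterations = 5), "10")
})

test_that("resolveTentative honours each policy", {
    d <- makeClassificationTable(nSamples = 60, dRelevant = 2, dNoise = 6,
                                 effectSize = 0.5, seed = 7)
    res <- borutaSelect(d$table, d$labels,
                        borutaConfig(nIterations = 10, numTrees = 30,
                                     seed = 7))
    inc <- resolveTentative(res, "include")
    exc <- resolveTentative(res, "exclude")
    med <- resolveTentative(res, "median_test")
    expect_false(any(inc == "tentative"))
    expect_false(any(exc == "tentative"))
    expect_false(any(med == "tentative"))
    tent <- tentativeFeatures(res)
    expect_true(all(inc[tent] == "confirmed"))
    expect_true(all(exc[tent] == "rejected"))
    # non-tentative statuses are left untouched
    firm <- setdiff(names(res@status), tent)
    expect_identical(inc[firm], res@status[firm])
})

test_that("applySelection filters columns in order and warns when empty", {
    d <- makeClassificationTable(nSamples = 150, dRelevant = 4, dNoise = 10,
                                 effectSize = 2, seed = 11)
    res <- borutaSelect(d$table, d$labels,
                        borutaConfig(nIterations = 15, numTrees = 50,
                                     seed = 11))
    kept <- applySelection(d$table, res)
    expect_identical(featureNames(kept),
                     intersect(featureNames(d$table), confirmedFeatures(res)))
    # force an all-rejected result
    allRej <- res
    allRej@status[] <- "rejected"
    expect_warning(empty <- applySelection(d$table, allRej), "no features")
    expect_equal(ncol(featureValues(empty)), 0L)
})

test_that("pcaFit produces an orthonormal, variance-ordered basis", {
    tab <- makeTinyTable(n = 40, d = 6, seed = 2)
    pm <- pcaFit(tab, varianceThreshold = 1)
    L <- pm@loadings
    expect_equal(t(L) %*% L, diag(ncol(L)), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(sum(pm@explainedVarRatio), 1, tolerance = 1e-8)
    expect_true(all(diff(pm@explainedVarRatio) <= 1e-12))
    # scores reproduce prcomp on the standardized data
    sc <- pcaTransform(pm, tab)
    ref <- prcomp(featureValues(tab), center = TRUE, scale. = TRUE)
    expect_equal(abs(unname(featureValues(sc))), abs(unname(ref$x)),
                 tolerance = 1e-8)
})

test_that("pcaFit truncates at the cumulative variance threshold", {
    set.seed(4)
    base <- matrix(rnorm(60 * 2), 60, 2)
    v <- cbind(base, base %*% matrix(rnorm(8), 2, 4) +
                   0.01 * matrix(rnorm(60 * 4), 60, 4))
    colnames(v) <- paste0("f", 1:6)
    rownames(v) <- paste0("m", 1:60)
    tab <- FeatureTable(v, blockOf = structure(rep("topology", 6),
                                               names = colnames(v)))
    pm <- pcaFit(tab, varianceThreshold = 0.9)
    expect_lt(pm@nComponents, 6)
    expect_gte(sum(pm@explainedVarRatio[seq_len(pm@nComponents)]), 0.9)
    full <- pcaFit(tab, varianceThreshold = 1)
    expect_equal(full@nComponents, 6L)
})

test_that("blockImportance aggregates exactly as a by-hand computation", {
    imp <- c(a = 3, b = 1, c = 4, d = 1, e = 5)
    blocks <- c(a = "charge", b = "charge", c = "charge",
                d = "topology", e = "topology")
    bi <- blockImportance(imp, blocks)
    ch <- bi[bi$block == "charge", ]
    expect_equal(ch$n, 3)
    expect_equal(ch$sum, 8)
    expect_equal(ch$median, 3)
    expect_equal(ch$q1, unname(quantile(c(3, 1, 4), 0.25)))
    expect_equal(ch$q3, unname(quantile(c(3, 1, 4), 0.75)))
    tp <- bi[bi$block == "topology", ]
    expect_equal(tp$sum, 6)
    expect_equal(tp$median, 3)
    expect_error(blockImportance(c(imp, z = 1), blocks), "block")
})

test_that("writeBorutaResult serializes the decision table", {
    d <- makeClassificationTable(nSamples = 60, dRelevant = 2, dNoise = 4,
                                 effectSize = 2, seed = 13)
    res <- borutaSelect(d$table, d$labels,
                        borutaConfig(nIterations = 10, numTrees = 30,
                                     seed = 13))
    path <- withr::local_tempfile(fileext = ".json")
    writeBorutaResult(res, path)
    j <- jsonlite::read_json(path)
    expect_equal(length(j$status), ncol(featureValues(d$table)))
    expect_equal(j$n_iterations, 10L)
})
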