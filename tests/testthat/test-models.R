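test_that("cross-validation folds partition the rows and stratify", {
    d <- makeClassificationTable(nSamples = 103, dRelevant = 4, dNoise = 6,
                                 effectSize = 1.5, classBalance = 0.4,
                                 seed = 21)
    spec <- classifierSpec("random_forest", list(num_trees = 60), seed = 21)
    cv <- crossValidate(d$table, d$labels, spec, "none", k = 5)
    all <- sort(unlist(cv@folds))
    expect_identical(all, seq_len(103L))
    # per-fold positive counts within one molecule of an even share
    posPerFold <- vapply(cv@folds, function(f) sum(d$labels[f]), numeric(1))
    expect_lte(diff(range(posPerFold)), 1)
    expect_false(anyNA(cv@scores))
    expect_equal(nrow(cv@foldMetrics), 5)
})

test_that("cross-validation is deterministic and separates easy data", {
    d <- makeClassificationTable(nSamples = 120, dRelevant = 5, dNoise = 10,
                                 effectSize = 2, seed = 23)
    spec <- classifierSpec("random_forest", list(num_trees = 80), seed = 23)
    cv1 <- crossValidate(d$table, d$labels, spec, "none", k = 5)
    cv2 <- crossValidate(d$table, d$labels, spec, "none", k = 5)
    expect_identical(cv1@scores, cv2@scores)
    expect_gt(aurocScore(cv1@labels, cv1@scores), 0.9)
})

test_that("all three classifier families train and score", {
    d <- makeClassificationTable(nSamples = 100, dRelevant = 4, dNoise = 4,
                                 effectSize = 2, seed = 25)
    for (alg in c("random_forest", "ridge_logistic", "adaboost_trees")) {
        spec <- classifierSpec(alg, seed = 25)
        fit <- fitFinal(d$table, d$labels, spec, "none", task = "bitter",
                        threshold = 0.5, domainK = 8L)
        p <- predictProba(fit, d$table)
        expect_length(p, 100)
        expect_true(all(p >= 0 & p <= 1))
        expect_gt(aurocScore(d$labels, p), 0.9)
    }
})

test_that("ridge logistic refuses a single-feature table", {
    d <- makeClassificationTable(nSamples = 60, dRelevant = 1, dNoise = 0,
                                 effectSize = 2, seed = 27)
    one <- d$table[, "rel01"]
    expect_error(
        fitFinal(one, d$labels, classifierSpec("ridge_logistic", seed = 1),
                 "none", task = "bitter", threshold = 0.5,
                 buildDomainRef = FALSE),
        "2|two|feature")
})

test_that("calibrateThreshold matches the exhaustive-scan oracle", {
    set.seed(31)
    for (i in 1:25) {
        n <- sample(10:40, 1)
        y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
        s <- round(runif(n), 2)
        got <- as.numeric(calibrateThreshold(y, s))
        expect_equal(got, min(max(oracleBalanceThreshold(y, s), 0), 1))
    }
    # constant scores are flagged degenerate
    t0 <- calibrateThreshold(c(0, 1), c(0.5, 0.5))
    expect_true(attr(t0, "degenerate"))
})

test_that("fitFinal calibrates a threshold from out-of-fold scores", {
    d <- makeClassificationTable(nSamples = 90, dRelevant = 5, dNoise = 5,
                                 effectSize = 2, seed = 33)
    spec <- classifierSpec("random_forest", list(num_trees = 60), seed = 33)
    fit <- fitFinal(d$table, d$labels, spec, "none", task = "sweet",
                    domainK = 10L)
    th <- decisionThreshold(fit)
    expect_true(th >= 0 && th <= 1)
    # refitting with the same seed reproduces identical predictions
    fit2 <- fitFinal(d$table, d$labels, spec, "none", task = "sweet",
                     domainK = 10L)
    expect_identical(predictProba(fit, d$table), predictProba(fit2, d$table))
})

test_that("featureImportances normalizes tree importances; ridge refuses", {
    d <- makeClassificationTable(nSamples = 80, dRelevant = 3, dNoise = 5,
                                 effectSize = 2, seed = 35)
    rf <- fitFinal(d$table, d$labels,
                   classifierSpec("random_forest", list(num_trees = 60),
                                  seed = 35),
                   "none", task = "bitter", threshold = 0.5, domainK = 8L)
    imp <- featureImportances(rf)
    expect_equal(sum(imp), 1, tolerance = 1e-12)
    expect_true(all(imp >= 0))
    # planted features dominate
    expect_gt(sum(imp[d$truth$relevant]), 0.5)
    rr <- fitFinal(d$table, d$labels, classifierSpec("ridge_logistic", seed = 1),
                   "none", task = "bitter", threshold = 0.5,
                   buildDomainRef = FALSE)
    expect_error(featureImportances(rr), "importance")
})

test_that("PCA preprocessing is refit inside each fold", {
    d <- makeClassificationTable(nSamples = 80, dRelevant = 4, dNoise = 8,
                                 effectSize = 2, seed = 37)
    spec <- classifierSpec("random_forest", list(num_trees = 60), seed = 37)
    cv <- crossValidate(d$table, d$labels, spec, "pca", k = 4,
                        varianceThreshold = 0.95)
    expect_false(anyNA(cv@scores))
    expect_gt(aurocScore(cv@labels, cv@scores), 0.85)
})

test_that("missing-feature rows predict NA, absent features error", {
    d <- makeClassificationTable(nSamples = 60, dRelevant = 3, dNoise = 3,
                                 effectSize = 2, seed = 39)
    fit <- fitFinal(d$table, d$labels,
                    classifierSpec("random_forest", list(num_trees = 40),
                                   seed = 39),
                    "none", task = "bitter", threshold = 0.5, domainK = 6L)
    tab <- d$table
    tab@missingMask[1, 1] <- TRUE
    p <- predictProba(fit, tab)
    expect_true(is.na(p[1]))
    expect_false(anyNA(p[-1]))
    expect_error(predictProba(fit, d$table[, 1:2]), "lacks")
})

test_that("save/load reproduces bitwise-identical probabilities", {
    d <- makeClassificationTable(nSamples = 70, dRelevant = 4, dNoise = 6,
                                 effectSize = 1.5, seed = 41)
    fit <- fitFinal(d$table, d$labels,
                    classifierSpec("random_forest", list(num_trees = 50),
                                   seed = 41),
                    "none", task = "bitter", threshold = 0.5, domainK = 10L)
    path <- withr::local_tempfile(fileext = ".rds")
    savePredictor(fit, path)
    back <- loadPredictor(path)
    expect_identical(predictProba(back, d$table), predictProba(fit, d$table))
    expect_identical(decisionThreshold(back), decisionThreshold(fit))
    expect_identical(featureNames(back), featureNames(fit))
})

test_that("loadPredictor rejects corrupted and future-version archives", {
    path <- withr::local_tempfile(fileext = ".rds")
    writeLines("not an archive", path)
    expect_error(loadPredictor(path), "corrupt")
    saveRDS(list(manifest = list(format_version = 999L)), path)
    expect_error(loadPredictor(path), "version")
    saveRDS(list(no_manifest = TRUE), path)
    expect_error(loadPredictor(path), "manifest")
})

test_that("hyperparameter calibration returns a spec from its grid", {
    d <- makeClassificationTable(nSamples = 60, dRelevant = 3, dNoise = 3,
                                 effectSize = 2, seed = 43)
    best <- calibrateHyperparameters(d$table, d$labels, "ridge_logistic",
                                     k = 3, seed = 43)
    expect_s4_class(best, "ClassifierSpec")
    expect_true(best@params$lambda %in% c(0.001, 0.01, 0.1, 1))
    g <- attr(best, "grid")
    expect_equal(nrow(g), 4)
    expect_equal(max(g$aupr), g$aupr[which.max(g$aupr)])
})
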