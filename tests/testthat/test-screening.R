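# two small predictors trained once on the synthetic table, shared across
# the screening tests
.screenFixture <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        d <- makeCorrelatedTable(n = 200, d = 12, rank = 2, seed = 61)
        spec <- classifierSpec("random_forest", list(num_trees = 50),
                               seed = 61)
        bitter <- fitFinal(d$table, d$labels, spec, "none", task = "bitter",
                           threshold = 0.5, domainK = 10L)
        sweet <- fitFinal(d$table, 1L - d$labels, spec, "none", task = "sweet",
                          threshold = 0.5, domainK = 10L)
        cache <<- list(data = d, bitter = bitter, sweet = sweet)
        cache
    }
})

test_that("screenLibrary scores, domain-checks and calls each molecule", {
    fx <- .screenFixture()
    res <- screenLibrary(NULL, fx$bitter, fx$sweet, features = fx$data$table)
    expect_equal(nrow(res), 200)
    expect_true(all(res$in_domain))  # training rows are inside the domain
    expect_true(all(is.na(res$failure)))
    expect_true(all(res$bitter_prob >= 0 & res$bitter_prob <= 1))
    # calls agree with thresholding the probabilities
    expect_identical(res$bitter_call,
                     res$bitter_prob >= decisionThreshold(fx$bitter))
    # bitter and sweet were trained on opposite labels
    expect_lt(cor(res$bitter_prob, res$sweet_prob), 0)
})

test_that("feature failures are recorded per molecule, never fatal", {
    fx <- .screenFixture()
    tab <- fx$data$table
    tab@missingMask[3, 2] <- TRUE
    res <- screenLibrary(NULL, fx$bitter, fx$sweet, features = tab)
    expect_match(res$failure[3], "failed")
    expect_true(is.na(res$bitter_prob[3]))
    expect_true(is.na(res$bitter_call[3]))
    expect_false(anyNA(res$bitter_prob[-3]))
    # an incomplete feature table is a caller error, though
    expect_error(screenLibrary(NULL, fx$bitter, fx$sweet,
                               features = tab[, 1:3]), "lack")
})

test_that("out-of-domain molecules are scored but not called", {
    fx <- .screenFixture()
    v <- featureValues(fx$data$table)[1:5, , drop = FALSE]
    v[1, ] <- v[1, ] + 100 * apply(featureValues(fx$data$table), 2, sd)
    rownames(v) <- paste0("q", 1:5)
    tab <- FeatureTable(v, blockOf = featureBlocks(fx$data$table))
    res <- screenLibrary(NULL, fx$bitter, fx$sweet, features = tab)
    expect_false(res$in_domain[1])
    expect_false(is.na(res$bitter_prob[1]))
    expect_true(is.na(res$bitter_call[1]))
    expect_true(all(res$in_domain[-1]))
})

test_that("summarizeScreening computes integer percentages of in-domain", {
    s <- summarizeScreening(nInDomain = 200L, nBitter = 37L, nSweet = 101L,
                            nBoth = 12L, nTotal = 250L)
    expect_equal(s@pctBitter, 19L)   # 18.5 rounds half away from zero
    expect_equal(s@pctSweet, 51L)    # 50.5 likewise
    expect_equal(s@pctBoth, 6L)
    expect_equal(s@nTotal, 250L)
    expect_false(s@flagged)
})

test_that("a zero in-domain summary is flagged with NA percentages", {
    s <- summarizeScreening(nInDomain = 0L, nBitter = 0L, nSweet = 0L,
                            nBoth = 0L, nTotal = 10L)
    expect_true(s@flagged)
    expect_true(is.na(s@pctBitter))
    expect_true(is.na(s@pctSweet))
})

test_that("summarizeScreening over results matches direct counting", {
    fx <- .screenFixture()
    res <- screenLibrary(NULL, fx$bitter, fx$sweet, features = fx$data$table)
    s <- summarizeScreening(res)
    inD <- res$in_domain %in% TRUE
    expect_equal(s@nInDomain, sum(inD))
    expect_equal(s@nBitter, sum(res$bitter_call %in% TRUE & inD))
    expect_equal(s@nBoth, sum(res$bitter_call %in% TRUE &
                              res$sweet_call %in% TRUE & inD))
})

test_that("writeScreening emits CSV and JSON artifacts", {
    fx <- .screenFixture()
    res <- screenLibrary(NULL, fx$bitter, fx$sweet, features = fx$data$table)
    s <- summarizeScreening(res)
    csv <- withr::local_tempfile(fileext = ".csv")
    js <- withr::local_tempfile(fileext = ".json")
    writeScreening(res, s, csv, js)
    back <- read.csv(csv)
    expect_equal(nrow(back), nrow(res))
    j <- jsonlite::read_json(js)
    expect_equal(j$n_in_domain, s@nInDomain)
    expect_equal(j$pct_bitter, s@pctBitter)
})

test_that("an empty library yields an empty result frame", {
    fx <- .screenFixture()
    res <- screenLibrary(TasteDataset(character(0), character(0)),
                         fx$bitter, fx$sweet)
    expect_equal(nrow(res), 0)
    expect_setequal(colnames(res),
                    c("id", "in_domain", "bitter_distance", "sweet_distance",
                      "bitter_prob", "sweet_prob", "bitter_call",
                      "sweet_call", "failure"))
})
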