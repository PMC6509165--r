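#' @include AllClasses.R methods.R evaluation.R selection.R
NULL

.FORMAT_VERSION <- 1L

## ---- classifier backends ---------------------------------------------------

.trainClassifier <- function(v, y, spec) {
    yf <- factor(y, levels = c(0, 1))
    p <- spec@params
    switch(spec@algorithm,
        random_forest = {
            fit <- ranger::ranger(
                x = data.frame(v, check.names = FALSE), y = yf,
                num.trees = if (!is.null(p$num_trees)) p$num_trees else 500L,
                mtry = p$mtry, probability = TRUE, importance = "impurity",
                num.threads = 1L, seed = spec@seed)
            list(kind = "random_forest", fit = fit, features = colnames(v))
        },
        ridge_logistic = {
            if (ncol(v) < 2)
                stop("ridge logistic regression needs >= 2 features")
            lambda <- if (!is.null(p$lambda)) p$lambda else 0.01
            fit <- glmnet::glmnet(v, yf, family = "binomial", alpha = 0,
                                  lambda = lambda, standardize = TRUE)
            list(kind = "ridge_logistic", fit = fit, features = colnames(v))
        },
        adaboost_trees = .trainAdaBoost(v, y, spec))
}

# AdaBoost (discrete, two-class) over depth-limited CART trees; probability
# output through the logistic link of the ensemble margin.
.trainAdaBoost <- function(v, y, spec) {
    p <- spec@params
    M <- if (!is.null(p$n_rounds)) p$n_rounds else 100L
    depth <- if (!is.null(p$max_depth)) p$max_depth else 1L
    n <- nrow(v)
    df <- data.frame(.y = factor(y, levels = c(0, 1)), v, check.names = FALSE)
    w <- rep(1 / n, n)
    trees <- list(); alphas <- numeric(0)
    ctl <- rpart::rpart.control(maxdepth = depth, cp = -1, minsplit = 2,
                                xval = 0, maxcompete = 0, maxsurrogate = 0)
    set.seed(spec@seed)
    for (m in seq_len(M)) {
        fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                            control = ctl)
        pred <- as.integer(as.character(predict(fit, df, type = "class")))
        err <- sum(w[pred != y])
        err <- min(max(err, 1e-10), 1 - 1e-10)
        a <- 0.5 * log((1 - err) / err)
        w <- w * exp(a * ifelse(pred != y, 1, -1))
        w <- w / sum(w)
        trees[[m]] <- fit
        alphas[m] <- a
        if (err < 1e-9) break
    }
    list(kind = "adaboost_trees", trees = trees, alphas = alphas,
         features = colnames(v))
}

.predictClassifier <- function(model, v) {
    v <- v[, model$features, drop = FALSE]
    switch(model$kind,
        random_forest = {
            pr <- predict(model$fit, data = data.frame(v, check.names = FALSE),
                          num.threads = 1L)$predictions
            unname(pr[, "1"])
        },
        ridge_logistic =
            as.numeric(predict(model$fit, newx = v, type = "response")),
        adaboost_trees = {
            df <- data.frame(v, check.names = FALSE)
            margin <- rep(0, nrow(v))
            for (m in seq_along(model$trees)) {
                h <- as.integer(as.character(
                    predict(model$trees[[m]], df, type = "class")))
                margin <- margin + model$alphas[m] * (2 * h - 1)
            }
            1 / (1 + exp(-2 * margin))
        })
}

.rawImportances <- function(model) {
    switch(model$kind,
        random_forest = {
            imp <- model$fit$variable.importance
            imp[model$features]
        },
        adaboost_trees = {
            imp <- structure(numeric(length(model$features)),
                             names = model$features)
            for (m in seq_along(model$trees)) {
                vi <- model$trees[[m]]$variable.importance
                if (!is.null(vi))
                    imp[names(vi)] <- imp[names(vi)] +
                        model$alphas[m] * vi
            }
            imp
        },
        stop("impurity importances unsupported for ", model$kind,
             " (no tree ensemble)"))
}

## ---- folds ------------------------------------------------------------------

.stratifiedFolds <- function(y, k, seed) {
    set.seed(seed)
    folds <- vector("list", k)
    for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        grp <- rep(seq_len(k), length.out = length(idx))
        for (f in seq_len(k))
            folds[[f]] <- c(folds[[f]], idx[grp == f])
    }
    lapply(folds, sort)
}

## ---- public API -------------------------------------------------------------

#' Stratified k-fold cross-validation of a taste classifier
#'
#' Folds are stratified (per-fold class counts within one molecule of the
#' global ratio). When \code{preprocessing = "pca"} the PCA model is refit on
#' each fold's training part and applied to its validation part; when
#' \code{preprocessing = "boruta"} the selection is run once on the full
#' training set before folding (the selection is computationally heavy and
#' stable, so it is not refit per fold). Every row is scored exactly once
#' out-of-fold. Deterministic given \code{spec@seed}.
#'
#' @param x a \linkS4class{FeatureTable} with no missing values
#' @param labels binary labels (>= k members per class)
#' @param spec a \linkS4class{ClassifierSpec}
#' @param preprocessing "none", "boruta" or "pca"
#' @param k number of folds
#' @param borutaConf a \linkS4class{BorutaConfig} (used when
#'   \code{preprocessing = "boruta"})
#' @param varianceThreshold PCA cumulative-variance target
#' @param includeTentative keep tentative Boruta features
#' @return a \linkS4class{CVReport}
#' @export
crossValidate <- function(x, labels, spec,
                          preprocessing = c("none", "boruta", "pca"),
                          k = 5L, borutaConf = borutaConfig(seed = spec@seed),
                          varianceThreshold = 0.99,
                          includeTentative = FALSE) {
    stopifnot(is(x, "FeatureTable"), is(spec, "ClassifierSpec"))
    preprocessing <- match.arg(preprocessing)
    y <- .asBinary(labels)
    if (any(table(y) < k))
        stop("each class needs at least k members")
    if (preprocessing == "boruta") {
        res <- borutaSelect(x, y, borutaConf)
        x <- applySelection(x, res, includeTentative)
        if (!ncol(x@values)) stop("empty feature set after preprocessing")
    }
    folds <- .stratifiedFolds(y, k, spec@seed)
    scores <- rep(NA_real_, length(y))
    fm <- list()
    for (f in seq_len(k)) {
        val <- folds[[f]]
        tr <- setdiff(seq_along(y), val)
        xtr <- x[tr, ]; xva <- x[val, ]
        if (preprocessing == "pca") {
            pm <- pcaFit(xtr, varianceThreshold)
            xtr <- pcaTransform(pm, xtr)
            xva <- pcaTransform(pm, xva)
        }
        model <- .trainClassifier(xtr@values, y[tr],
                                  initialize(spec,
                                             seed = .seedFrom(spec@seed, f)))
        scores[val] <- .predictClassifier(model, xva@values)
        rep <- evaluateScores(y[val], scores[val], threshold = 0.5)
        fm[[f]] <- metricRow(rep)
    }
    new("CVReport", folds = folds, foldMetrics = do.call(rbind, fm),
        scores = scores, labels = y, spec = spec,
        preprocessing = preprocessing)
}

#' Balance-sensitivity/specificity decision threshold
#'
#' Scans candidate cuts at the observed score values and returns the one
#' minimizing |Sn - Sp| (computed with the cut closed on the positive side);
#' ties are broken toward higher sensitivity.
#'
#' @param labels binary labels (both classes present)
#' @param scores pooled out-of-fold probabilities
#' @return numeric(1) threshold; attribute \code{"degenerate"} is TRUE when
#'   all scores are equal
#' @export
calibrateThreshold <- function(labels, scores) {
    y <- .asBinary(labels)
    if (length(unique(y)) < 2L)
        stop("threshold calibration needs both classes")
    cuts <- sort(unique(scores))
    nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
    best <- NULL; bestGap <- Inf; bestSn <- -Inf
    for (t in cuts) {
        calls <- scores >= t
        sn <- sum(calls & y == 1L) / nPos
        sp <- sum(!calls & y == 0L) / nNeg
        gap <- abs(sn - sp)
        if (gap < bestGap - 1e-12 ||
            (gap <= bestGap + 1e-12 && sn > bestSn)) {
            best <- t; bestGap <- gap; bestSn <- sn
        }
    }
    out <- min(max(best, 0), 1)
    attr(out, "degenerate") <- length(cuts) == 1L
    out
}

#' Fit a final taste predictor on all training rows
#'
#' Runs the chosen preprocessing (Boruta once, or PCA on the full training
#' table), trains the classifier on all rows, calibrates the decision
#' threshold on pooled out-of-fold cross-validation scores when none is
#' given, and (for tree ensembles) anchors a nearest-neighbour applicability
#' domain on the k most important features. Refitting with the same seed
#' reproduces identical predictions.
#'
#' @inheritParams crossValidate
#' @param task "bitter" or "sweet"
#' @param threshold decision cut in [0,1]; NULL calibrates it by 5-fold CV
#' @param domainK,domainN,domainDelta applicability-domain parameters
#'   (defaults 25 / 5 / 3); \code{domainK} is capped at the processed feature
#'   count
#' @param buildDomainRef set FALSE to skip the applicability domain
#' @return a \linkS4class{TastePredictor}
#' @export
fitFinal <- function(x, labels, spec, preprocessing = c("none", "boruta", "pca"),
                     task = c("bitter", "sweet"), threshold = NULL,
                     borutaConf = borutaConfig(seed = spec@seed),
                     varianceThreshold = 0.99, includeTentative = FALSE,
                     domainK = 25L, domainN = 5L, domainDelta = 3,
                     buildDomainRef = TRUE, k = 5L) {
    preprocessing <- match.arg(preprocessing)
    task <- match.arg(task)
    stopifnot(is(x, "FeatureTable"), is(spec, "ClassifierSpec"))
    y <- .asBinary(labels)
    if (is.null(threshold)) {
        cv <- crossValidate(x, y, spec, preprocessing, k = k,
                            borutaConf = borutaConf,
                            varianceThreshold = varianceThreshold,
                            includeTentative = includeTentative)
        threshold <- as.numeric(calibrateThreshold(cv@labels, cv@scores))
    }
    preproc <- NULL
    xin <- x
    if (preprocessing == "boruta") {
        preproc <- borutaSelect(x, y, borutaConf)
        xin <- applySelection(x, preproc, includeTentative)
        if (!ncol(xin@values)) stop("empty feature set after preprocessing")
    }
    inputFeatures <- featureNames(xin)
    xproc <- xin
    if (preprocessing == "pca") {
        preproc <- pcaFit(xin, varianceThreshold)
        xproc <- pcaTransform(preproc, xin)
    }
    model <- .trainClassifier(xproc@values, y, spec)
    domain <- NULL
    if (buildDomainRef) {
        imp <- tryCatch(.rawImportances(model), error = function(e) NULL)
        if (is.null(imp))  # no impurity importances: weight features equally
            imp <- structure(rep(1, ncol(xproc@values)),
                             names = colnames(xproc@values))
        domain <- buildDomain(xproc, imp,
                              k = min(domainK, ncol(xproc@values)),
                              N = domainN, delta = domainDelta)
    }
    new("TastePredictor", task = task, algorithm = spec@algorithm,
        preprocessing = preprocessing, preprocessor = preproc,
        model = model, featureNames = inputFeatures,
        threshold = threshold, domain = domain,
        provenance = list(
            format_version = .FORMAT_VERSION,
            algorithm = spec@algorithm, params = spec@params,
            seed = spec@seed, n_training_rows = nrow(x@values),
            n_input_features = ncol(x@values),
            trained = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
}

#' @rdname predictProba
setMethod("predictProba", signature("TastePredictor", "FeatureTable"),
          function(object, x) {
    miss <- setdiff(object@featureNames, featureNames(x))
    if (length(miss))
        stop("feature mismatch: table lacks ",
             paste(utils::head(miss, 5), collapse = ", "),
             if (length(miss) > 5) ", ...")
    if (!nrow(x@values)) return(numeric(0))
    xt <- x[, object@featureNames]
    bad <- rowSums(xt@missingMask) > 0
    out <- rep(NA_real_, nrow(xt@values))
    if (any(!bad)) {
        xin <- xt[which(!bad), ]
        if (object@preprocessing == "pca")
            xin <- pcaTransform(object@preprocessor, xin)
        out[!bad] <- .predictClassifier(object@model, xin@values)
    }
    structure(out, names = rownames(x@values))
})

#' Gini (mean decrease in impurity) feature importances
#'
#' Available for tree-ensemble predictors (random forest, AdaBoost trees);
#' importances are normalized to sum to one. Ridge logistic regression has no
#' impurity importances and raises an error.
#'
#' @param object a \linkS4class{TastePredictor}
#' @return named numeric vector summing to 1 over the processed features
#' @export
featureImportances <- function(object) {
    stopifnot(is(object, "TastePredictor"))
    imp <- .rawImportances(object@model)
    imp <- pmax(imp, 0)
    s <- sum(imp)
    if (s <= 0) stop("degenerate importances (all zero)")
    imp / s
}

#' Pick hyperparameters on a documented grid by mean CV average precision
#'
#' Grids: random forest trees in {100, 300, 500}; ridge penalty lambda in
#' {0.001, 0.01, 0.1, 1}; AdaBoost rounds in {50, 100, 200} x depth {1, 3}.
#'
#' @inheritParams crossValidate
#' @param algorithm classifier family
#' @param seed RNG seed
#' @return the winning \linkS4class{ClassifierSpec}; the searched grid with
#'   scores is in \code{attr(, "grid")}
#' @export
calibrateHyperparameters <- function(x, labels,
                                     algorithm = c("random_forest",
                                                   "ridge_logistic",
                                                   "adaboost_trees"),
                                     preprocessing = "none", k = 5L,
                                     seed = 1L) {
    algorithm <- match.arg(algorithm)
    grid <- switch(algorithm,
        random_forest = lapply(c(100L, 300L, 500L),
                               function(t) list(num_trees = t)),
        ridge_logistic = lapply(c(0.001, 0.01, 0.1, 1),
                                function(l) list(lambda = l)),
        adaboost_trees = {
            g <- expand.grid(n_rounds = c(50L, 100L, 200L),
                             max_depth = c(1L, 3L))
            lapply(seq_len(nrow(g)), function(i)
                list(n_rounds = g$n_rounds[i], max_depth = g$max_depth[i]))
        })
    scores <- vapply(grid, function(par) {
        cv <- crossValidate(x, labels, classifierSpec(algorithm, par, seed),
                            preprocessing, k = k)
        auprScore(cv@labels, cv@scores)
    }, numeric(1))
    best <- classifierSpec(algorithm, grid[[which.max(scores)]], seed)
    attr(best, "grid") <- data.frame(
        params = vapply(grid, function(p)
            paste(names(p), unlist(p), sep = "=", collapse = ","),
            character(1)),
        aupr = scores)
    best
}

## ---- persistence ------------------------------------------------------------

#' Save a fitted taste predictor
#'
#' Single-file archive holding a JSON-compatible manifest (format version,
#' algorithm, seed, threshold, feature list, provenance) plus the serialized
#' model, preprocessor and domain reference. \code{loadPredictor} of a saved
#' archive reproduces bitwise-identical predictions.
#'
#' @param object a \linkS4class{TastePredictor}
#' @param path output file
#' @return invisibly, the path
#' @export
savePredictor <- function(object, path) {
    stopifnot(is(object, "TastePredictor"))
    payload <- list(
        manifest = list(
            format_version = .FORMAT_VERSION, task = object@task,
            algorithm = object@algorithm,
            preprocessing = object@preprocessing,
            threshold = object@threshold,
            feature_names = object@featureNames,
            provenance = object@provenance),
        blobs = list(model = serialize(object@model, NULL),
                     preprocessor = serialize(object@preprocessor, NULL),
                     domain = serialize(object@domain, NULL)))
    saveRDS(payload, path)
    invisible(path)
}

#' @rdname savePredictor
#' @param path archive written by \code{savePredictor}
#' @return a \linkS4class{TastePredictor}
#' @export
loadPredictor <- function(path) {
    payload <- tryCatch(readRDS(path), error = function(e)
        stop("corrupted predictor archive: ", conditionMessage(e)))
    man <- payload$manifest
    if (is.null(man$format_version))
        stop("corrupted predictor archive: no manifest")
    if (man$format_version > .FORMAT_VERSION)
        stop("predictor archive format version ", man$format_version,
             " is newer than supported version ", .FORMAT_VERSION)
    new("TastePredictor", task = man$task, algorithm = man$algorithm,
        preprocessing = man$preprocessing,
        preprocessor = unserialize(payload$blobs$preprocessor),
        model = unserialize(payload$blobs$model),
        featureNames = man$feature_names, threshold = man$threshold,
        domain = unserialize(payload$blobs$domain),
        provenance = man$provenance)
}
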