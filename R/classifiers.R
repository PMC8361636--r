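# Classifier registry. A classifier factory is a function
# (trainX, trainY, testX) -> factor of predicted labels, where trainX
# and testX are samples x features numeric matrices that have already
# been imputed and scaled by the cross-validation driver.

.registries <- new.env(parent = emptyenv())
.registries$classifiers <- list()
.registries$selectors <- list()

#' Register a classifier
#'
#' Makes a classification algorithm available to [kfoldCV()] and to
#' config-driven benchmark runs under the given name.
#'
#' @param name unused classifier name.
#' @param factory function \code{(trainX, trainY, testX)} returning the
#'   predicted labels for the rows of \code{testX}; \code{trainX},
#'   \code{testX} are samples-by-features matrices, \code{trainY} a
#'   factor.
#' @return The name, invisibly.
#' @seealso [listClassifiers()], [registerSelector()]
#' @export
registerClassifier <- function(name, factory) {
    stopifnot(is.character(name), length(name) == 1L,
              is.function(factory))
    if (name %in% names(.registries$classifiers))
        stop("classifier '", name, "' is already registered")
    .registries$classifiers[[name]] <- factory
    invisible(name)
}

#' Registered classifier names
#' @return Character vector of registered classifier names.
#' @export
listClassifiers <- function() sort(names(.registries$classifiers))

.getClassifier <- function(name) {
    f <- .registries$classifiers[[name]]
    if (is.null(f)) stop("unknown classifier: ", name)
    f
}

# built-in classifiers, conventional defaults; registered at load time
.builtinClassifiers <- function() list(
    naive_bayes = function(trainX, trainY, testX) {
        fit <- e1071::naiveBayes(as.data.frame(trainX), trainY)
        stats::predict(fit, as.data.frame(testX))
    },
    # the classical "linear regression" entry of classifier panels,
    # realized as multinomial logistic regression (a linear classifier)
    logistic_regression = function(trainX, trainY, testX) {
        df <- data.frame(trainX, check.names = FALSE)
        df$.y <- trainY
        fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE,
                              maxit = 200, MaxNWts = 5000)
        pred <- stats::predict(fit,
                               newdata = data.frame(testX,
                                                    check.names = FALSE))
        factor(as.character(pred), levels = levels(trainY))
    },
    svm = function(trainX, trainY, testX) {
        fit <- e1071::svm(trainX, trainY)
        stats::predict(fit, testX)
    },
    random_forest = function(trainX, trainY, testX) {
        fit <- randomForest::randomForest(trainX, trainY, ntree = 500)
        stats::predict(fit, testX)
    },
    knn3 = function(trainX, trainY, testX) {
        class::knn(trainX, testX, trainY, k = 3)
    })

#' Register a feature selector
#'
#' Makes a selector available to config-driven benchmark runs. A
#' \code{"gene"} selector maps a labeled dataset (plus the knowledge
#' bases and its config parameters) to a [FeatureRanking-class]; a
#' \code{"pathway"} selector returns a [PathwayFeatureSet-class] with a
#' computed activity matrix.
#'
#' @param name unused selector name.
#' @param factory function \code{(ds, kbs, params)} where \code{kbs} is
#'   a list with elements \code{association} ([AssociationKB-class] or
#'   NULL) and \code{network} ([NetworkKB-class] or NULL), and
#'   \code{params} a named list from the config.
#' @param type \code{"gene"} or \code{"pathway"}.
#' @return The name, invisibly.
#' @export
registerSelector <- function(name, factory, type = c("gene", "pathway")) {
    type <- match.arg(type)
    stopifnot(is.character(name), length(name) == 1L,
              is.function(factory))
    if (name %in% names(.registries$selectors))
        stop("selector '", name, "' is already registered")
    .registries$selectors[[name]] <- list(factory = factory, type = type)
    invisible(name)
}

#' Registered selector names
#' @return Character vector of registered selector names.
#' @export
listSelectors <- function() sort(names(.registries$selectors))

.getSelector <- function(name) {
    s <- .registries$selectors[[name]]
    if (is.null(s)) stop("unknown selector: ", name)
    s
}

.num <- function(params, key, default) {
    if (!is.null(params[[key]])) as.numeric(params[[key]]) else default
}

.chr <- function(params, key, default) {
    if (!is.null(params[[key]])) as.character(params[[key]]) else default
}

# built-in selectors available from configs
.builtinSelectors <- function() {
    needKb <- function(kbs) {
        if (is.null(kbs$association))
            stop("selector needs an association knowledge base")
        kbs$association
    }
    terms <- function(params) {
        if (is.null(params$terms)) stop("selector needs search terms")
        params$terms
    }
    list(
        variance = list(type = "gene", factory =
            function(ds, kbs, params) rankByVariance(ds)),
        anova = list(type = "gene", factory =
            function(ds, kbs, params) rankByAnovaF(ds)),
        prefilter_anova = list(type = "gene", factory =
            function(ds, kbs, params)
                prefilterSelect(ds, needKb(kbs), terms(params),
                                minScore = .num(params, "min_score", 0),
                                baseRanker = rankByAnovaF)),
        postfilter_anova = list(type = "gene", factory =
            function(ds, kbs, params)
                postfilterSelect(rankByAnovaF(ds), needKb(kbs),
                                 terms(params),
                                 minScore = .num(params, "min_score", 0))),
        extension_anova = list(type = "gene", factory =
            function(ds, kbs, params)
                extensionSelect(rankByAnovaF(ds), needKb(kbs),
                                terms(params),
                                minScore = .num(params, "min_score", 0),
                                kStat = .num(params, "k_stat", 10),
                                kKb = .num(params, "k_kb", 10))),
        weighted_anova = list(type = "gene", factory =
            function(ds, kbs, params)
                weightedCombine(rankByAnovaF(ds),
                    getGeneScores(needKb(kbs), terms(params),
                        aggregation = .chr(params, "aggregation", "max")),
                    missingPolicy = .chr(params, "missing_policy",
                                         "epsilon"),
                    epsilon = .num(params, "epsilon", 0.001))),
        weighted_variance = list(type = "gene", factory =
            function(ds, kbs, params)
                weightedCombine(rankByVariance(ds),
                    getGeneScores(needKb(kbs), terms(params),
                        aggregation = .chr(params, "aggregation", "max")),
                    missingPolicy = .chr(params, "missing_policy",
                                         "epsilon"),
                    epsilon = .num(params, "epsilon", 0.001))),
        kb_lasso = list(type = "gene", factory =
            function(ds, kbs, params)
                kbPenalizedLasso(ds,
                    getGeneScores(needKb(kbs),
                        .chr(params, "terms", kbTerms(needKb(kbs))),
                        aggregation = .chr(params, "aggregation", "max")),
                    lambda = .num(params, "lambda", 0.05))),
        pathway_activity = list(type = "pathway", factory =
            function(ds, kbs, params) {
                if (is.null(kbs$network))
                    stop("selector needs a network knowledge base")
                sel <- selectRelevantPathways(ds, kbs$network,
                    nPathways = .num(params, "n_pathways", 5),
                    nPermutations = .num(params, "n_permutations", 200),
                    seed = .num(params, "seed", 1))
                pathwayActivityMatrix(ds, sel, kbs$network)
            }))
}
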