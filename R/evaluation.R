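# Evaluation of feature sets: stratified k-fold cross-validation over
# multiple classifiers, feature-size sweeps, cross-dataset robustness,
# ranking concordance, overlap counts and local enrichment.

# stratified fold assignment: within each class, samples are shuffled
# (seeded) and folds 0..k-1 dealt round-robin, so per-fold class
# proportions deviate from the global ones by less than one sample
.stratifiedFolds <- function(labels, k, seed) {
    folds <- integer(length(labels))
    names(folds) <- names(labels)
    .withSeed(seed, {
        for (cl in sort(unique(labels))) {
            idx <- which(labels == cl)
            # order by sample id first: the assignment then depends on
            # (labels, ids, seed) only, not on column order
            if (!is.null(names(labels)))
                idx <- idx[order(names(labels)[idx])]
            idx <- idx[sample.int(length(idx))]
            folds[idx] <- (seq_along(idx) - 1L) %% k
        }
    })
    folds
}

# preprocessing fit on the training split only: per-gene mean
# imputation values plus z-scaling parameters
.fitScaler <- function(trainX) {
    mu <- colMeans(trainX, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    filled <- trainX
    idx <- which(is.na(filled), arr.ind = TRUE)
    if (nrow(idx)) filled[idx] <- mu[idx[, 2L]]
    sd <- apply(filled, 2L, stats::sd)
    sd[sd == 0 | is.na(sd)] <- 1
    list(mu = mu, sd = sd)
}

.applyScaler <- function(x, scaler) {
    idx <- which(is.na(x), arr.ind = TRUE)
    if (nrow(idx)) x[idx] <- scaler$mu[idx[, 2L]]
    sweep(sweep(x, 2L, scaler$mu), 2L, scaler$sd, "/")
}

# macro-averaged F1 over the classes present in the truth; per-class
# precision/recall with 0/0 treated as 0
.macroF1 <- function(truth, pred) {
    classes <- unique(as.character(truth))
    f1 <- vapply(classes, function(cl) {
        tp <- sum(truth == cl & pred == cl)
        fp <- sum(truth != cl & pred == cl)
        fn <- sum(truth == cl & pred != cl)
        prec <- if (tp + fp > 0) tp / (tp + fp) else 0
        rec <- if (tp + fn > 0) tp / (tp + fn) else 0
        if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    }, numeric(1))
    mean(f1)
}

# cross-validation core shared by kfoldCV and sweepFeatureSizes: folds
# are precomputed so sweeps reuse identical assignments across sizes
.cvWithFolds <- function(ds, featureSet, classifiers, folds, seed,
                         featureSetSize = length(featureSet),
                         selector = NA_character_) {
    labels <- sampleLabels(ds)
    y <- factor(labels)
    x <- t(exprValues(ds)[featureSet, , drop = FALSE])
    k <- length(unique(folds))
    rows <- list()
    for (fold in sort(unique(folds))) {
        test <- folds == fold
        scaler <- .fitScaler(x[!test, , drop = FALSE])
        trainX <- .applyScaler(x[!test, , drop = FALSE], scaler)
        testX <- .applyScaler(x[test, , drop = FALSE], scaler)
        trainY <- y[!test]
        for (clf in classifiers) {
            f <- .getClassifier(clf)
            pred <- .withSeed(.childSeed(seed, fold * 37L +
                                         match(clf, classifiers)),
                              f(trainX, trainY, testX))
            pred <- factor(as.character(pred), levels = levels(y))
            truth <- y[test]
            rows[[length(rows) + 1L]] <- data.frame(
                selector = selector, classifier = clf,
                feature_set_size = featureSetSize, fold = fold,
                metric = c("accuracy", "macro_f1"),
                value = c(mean(pred == truth), .macroF1(truth, pred)),
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Stratified k-fold cross-validation of a feature set
#'
#' Evaluates a gene set by stratified k-fold cross-validation over one
#' or more classifiers. Folds are drawn from the seed with per-class
#' round-robin assignment; per-gene mean imputation and z-scaling are
#' fit on the training folds only and applied to the test fold, so no
#' information leaks from test to train. Reported metrics are accuracy
#' and macro-averaged F1 per (classifier, fold).
#'
#' @param ds a labeled [ExpressionDataset-class]; every class needs at
#'   least \code{k} samples.
#' @param featureSet character vector of genes, a subset of
#'   \code{geneIds(ds)}.
#' @param classifiers registered classifier names (see
#'   [listClassifiers()]).
#' @param k number of folds (>= 2).
#' @param seed integer seed; the same seed reproduces the exact folds
#'   and metrics.
#' @param selector optional selector name recorded in the table.
#' @return A long-format metrics data.frame with columns
#'   \code{selector}, \code{classifier}, \code{feature_set_size},
#'   \code{fold}, \code{metric}, \code{value}.
#' @seealso [averageMetrics()], [sweepFeatureSizes()]
#' @export
kfoldCV <- function(ds, featureSet, classifiers = listClassifiers(),
                    k = 10L, seed = 1L, selector = NA_character_) {
    labels <- sampleLabels(ds)
    if (is.null(labels)) stop("cross-validation needs labels")
    if (k < 2L) stop("k must be >= 2")
    tab <- table(labels)
    if (any(tab < k))
        stop("class(es) with fewer than k samples: ",
             paste(names(tab)[tab < k], collapse = ", "))
    missing <- setdiff(featureSet, geneIds(ds))
    if (length(missing))
        stop("feature(s) not in dataset: ",
             paste(missing, collapse = ", "))
    for (clf in classifiers) .getClassifier(clf)  # fail fast
    folds <- .stratifiedFolds(labels, k, seed)
    .cvWithFolds(ds, featureSet, classifiers, folds, seed,
                 selector = selector)
}

#' Mean metrics over folds, then over classifiers
#'
#' Collapses a long metrics table into the headline numbers: per
#' (selector, feature set size, metric), fold values are averaged per
#' classifier and the classifier means are then averaged.
#'
#' @param metrics a metrics data.frame from [kfoldCV()] or
#'   [sweepFeatureSizes()].
#' @return A data.frame with columns \code{selector},
#'   \code{feature_set_size}, \code{metric}, \code{value}.
#' @export
averageMetrics <- function(metrics) {
    perClf <- stats::aggregate(
        value ~ selector + classifier + feature_set_size + metric,
        data = transform(metrics,
                         selector = ifelse(is.na(selector), "(none)",
                                           selector)),
        FUN = mean)
    out <- stats::aggregate(
        value ~ selector + feature_set_size + metric, data = perClf,
        FUN = mean)
    out[order(out$selector, out$feature_set_size, out$metric), ,
        drop = FALSE]
}

#' Cross-validated performance across feature-set sizes
#'
#' Runs [kfoldCV()] for nested feature sets of increasing size taken
#' from the top of a ranking. The fold assignment is computed once from
#' the seed and reused for every size, so performance curves differ
#' only in the features used.
#'
#' @param ranking a [FeatureRanking-class].
#' @param ds a labeled [ExpressionDataset-class] containing the ranked
#'   genes.
#' @param classifiers registered classifier names.
#' @param k number of folds.
#' @param sizes integer vector of feature-set sizes (each within the
#'   ranking).
#' @param seed integer seed shared across sizes.
#' @return A long metrics data.frame (one [kfoldCV()] block per size).
#' @export
sweepFeatureSizes <- function(ranking, ds,
                              classifiers = listClassifiers(),
                              k = 10L, sizes = 1:20, seed = 1L) {
    if (max(sizes) > nrow(rankingTable(ranking)))
        stop("sizes exceed the ranking length")
    labels <- sampleLabels(ds)
    if (is.null(labels)) stop("cross-validation needs labels")
    folds <- .stratifiedFolds(labels, k, seed)
    out <- lapply(sizes, function(sz)
        .cvWithFolds(ds, selectTopK(ranking, sz), classifiers, folds,
                     seed, featureSetSize = sz,
                     selector = methodName(ranking)))
    do.call(rbind, out)
}

#' Cross-dataset robustness evaluation
#'
#' Evaluates a feature set selected on one dataset by k-fold
#' cross-validation on a second dataset. Features not measured in the
#' second dataset are dropped with a logged count.
#'
#' @param featureSet genes selected on the first dataset.
#' @param dsB a labeled second [ExpressionDataset-class].
#' @inheritParams kfoldCV
#' @return A long metrics data.frame from [kfoldCV()] on the surviving
#'   features.
#' @export
crossDatasetValidation <- function(featureSet, dsB,
                                   classifiers = listClassifiers(),
                                   k = 10L, seed = 1L,
                                   selector = NA_character_) {
    keep <- intersect(featureSet, geneIds(dsB))
    if (length(keep) == 0L)
        stop("no selected feature is measured in the second dataset")
    dropped <- length(featureSet) - length(keep)
    if (dropped > 0L)
        .log("dropped ", dropped,
             " feature(s) absent from the second dataset")
    kfoldCV(dsB, keep, classifiers, k, seed, selector = selector)
}

#' Kendall's coefficient of concordance (W)
#'
#' Agreement among m rankings of the same n items, in [0, 1]: 1 for
#' identical rankings, 0 for maximal disagreement. Computed as
#' \deqn{W = \frac{12 S}{m^2 (n^3 - n) - m \sum_j T_j}}
#' where S is the sum of squared deviations of the item rank sums from
#' their mean and \eqn{T_j = \sum (t^3 - t)} corrects for tied groups
#' (ties receive average ranks).
#'
#' @param rankings a list (length >= 2) of [FeatureRanking-class]
#'   objects or of ordered character vectors, all covering the same
#'   item set. For FeatureRanking inputs ranks are derived from the
#'   scores with average ranks for ties; character vectors are taken as
#'   tie-free orderings.
#' @return A single number in [0, 1].
#' @export
kendallsW <- function(rankings) {
    stopifnot(is.list(rankings), length(rankings) >= 2L)
    asRanks <- function(r) {
        if (is(r, "FeatureRanking")) {
            tab <- rankingTable(r)
            stats::setNames(rank(-tab$score, ties.method = "average"),
                            tab$gene)
        } else {
            r <- as.character(r)
            stats::setNames(seq_along(r), r)
        }
    }
    rks <- lapply(rankings, asRanks)
    items <- sort(names(rks[[1L]]))
    for (r in rks)
        if (!identical(sort(names(r)), items))
            stop("rankings must cover identical item sets")
    m <- length(rks)
    n <- length(items)
    R <- vapply(rks, function(r) r[items], numeric(n))
    rowsum <- rowSums(R)
    S <- sum((rowsum - mean(rowsum))^2)
    Tj <- vapply(rks, function(r) {
        t <- table(r)
        sum(t^3 - t)
    }, numeric(1))
    denom <- m^2 * (n^3 - n) - m * sum(Tj)
    if (denom <= 0) return(1)   # all items tied in every ranking
    12 * S / denom
}

#' Exclusive overlap counts among named sets
#'
#' Upset-style summary: for every nonempty subset of the set names, the
#' number of elements belonging to exactly those sets. Exclusive counts
#' sum to the size of the union.
#'
#' @param namedSets named list (length >= 2) of character vectors.
#' @return A data.frame with columns \code{subset} (set names joined by
#'   \code{"&"}, in input order), \code{degree}, \code{count}, covering
#'   all nonempty subsets.
#' @export
featureOverlap <- function(namedSets) {
    stopifnot(is.list(namedSets), length(namedSets) >= 2L,
              !is.null(names(namedSets)))
    nm <- names(namedSets)
    sets <- lapply(namedSets, unique)
    universe <- unique(unlist(sets, use.names = FALSE))
    sig <- vapply(universe, function(el)
        paste(nm[vapply(sets, function(s) el %in% s, logical(1))],
              collapse = "&"), character(1))
    combos <- unlist(lapply(seq_along(nm), function(d)
        utils::combn(nm, d, paste, collapse = "&", simplify = FALSE)))
    counts <- vapply(combos, function(cb) sum(sig == cb), integer(1))
    data.frame(subset = combos,
               degree = lengths(strsplit(combos, "&", fixed = TRUE)),
               count = counts, stringsAsFactors = FALSE,
               row.names = NULL)
}

#' Exclusive overlaps of enrichment results
#'
#' [featureOverlap()] applied to the term sets of several enrichment
#' results, e.g. the top enriched terms per selector. Empty results are
#' allowed: their exclusive cells are 0.
#'
#' @param enrichmentResults named list of character vectors of term
#'   names (or of [enrich()] result data.frames, whose \code{term}
#'   column is used).
#' @return As [featureOverlap()].
#' @export
annotationOverlap <- function(enrichmentResults) {
    sets <- lapply(enrichmentResults, function(x)
        if (is.data.frame(x)) as.character(x$term) else as.character(x))
    featureOverlap(sets)
}

#' Local gene-set enrichment with combined scores
#'
#' Tests a query gene set against a GMT library by one-sided Fisher
#' exact tests (hypergeometric tails) on the overlap against a fixed
#' background universe. P-values are Benjamini-Hochberg adjusted;
#' terms with adjusted p above 0.05 are removed and the rest sorted by
#' combined score, \eqn{c = -\ln(p) \cdot z}, where z is the deviation
#' of the observed overlap from its hypergeometric expectation in
#' standard-deviation units.
#'
#' @param query character vector of genes, a subset of
#'   \code{background}.
#' @param library named list of gene sets (e.g. from
#'   \code{fgsea::gmtPathways()}).
#' @param background character vector, the gene universe.
#' @param maxAdjustedP significance cut-off on the adjusted p-value.
#' @return A data.frame sorted by \code{combined_score} descending with
#'   columns \code{term}, \code{overlap_count}, \code{p_value},
#'   \code{adjusted_p}, \code{combined_score}; zero rows when nothing
#'   is enriched.
#' @export
enrich <- function(query, library, background, maxAdjustedP = 0.05) {
    query <- unique(query)
    background <- unique(background)
    if (length(query) == 0L) stop("empty query gene set")
    if (length(background) == 0L) stop("empty background universe")
    if (length(setdiff(query, background)))
        stop("query genes must be part of the background")
    lib <- lapply(library, function(g) intersect(unique(g), background))
    lib <- lib[lengths(lib) > 0L]
    if (length(lib) == 0L)
        stop("no library term intersects the background")
    N <- length(background)
    n <- length(query)
    rows <- lapply(names(lib), function(tm) {
        K <- length(lib[[tm]])
        k <- length(intersect(query, lib[[tm]]))
        p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        expected <- n * K / N
        sdv <- sqrt(n * (K / N) * (1 - K / N) * (N - n) / (N - 1))
        z <- if (sdv > 0) (k - expected) / sdv else 0
        data.frame(term = tm, overlap_count = k, p_value = p,
                   combined_score = -log(p) * z,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
    out <- out[out$adjusted_p <= maxAdjustedP, , drop = FALSE]
    out <- out[order(-out$combined_score, out$term), ,
               drop = FALSE]
    rownames(out) <- NULL
    out[, c("term", "overlap_count", "p_value", "adjusted_p",
            "combined_score")]
}
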