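# Statistical and prior-knowledge feature selectors. All selectors take
# an ExpressionDataset and return a FeatureRanking whose order is
# deterministic: ties in score are broken by gene identifier.

#' Rank genes by sample variance
#'
#' Unsupervised filter: genes are scored by their sample variance across
#' all samples (missing entries ignored per gene).
#'
#' @param ds an [ExpressionDataset-class] with at least 2 samples.
#' @return A [FeatureRanking-class] with method \code{"variance"}.
#' @export
rankByVariance <- function(ds) {
    if (ncol(ds) < 2L) stop("variance ranking needs >= 2 samples")
    v <- .rowVarsNA(exprValues(ds))
    v[is.na(v)] <- 0
    FeatureRanking(geneIds(ds), v, method = "variance")
}

#' Rank genes by one-way ANOVA F statistic
#'
#' Supervised filter: each gene is scored by the one-way ANOVA F
#' statistic of its expression across the sample classes. Missing
#' entries are ignored per gene; a gene whose within-class variance is
#' zero while class means differ receives a large finite score, and a
#' gene left without observations in some class scores 0.
#'
#' @param ds a labeled [ExpressionDataset-class] with >= 2 classes, each
#'   holding >= 2 samples.
#' @return A [FeatureRanking-class] with method \code{"anova"}.
#' @export
rankByAnovaF <- function(ds) {
    labels <- sampleLabels(ds)
    if (is.null(labels)) stop("ANOVA ranking needs a labeled dataset")
    tab <- table(labels)
    if (length(tab) < 2L) stop("ANOVA ranking needs >= 2 classes")
    if (any(tab < 2L))
        stop("class(es) with < 2 samples: ",
             paste(names(tab)[tab < 2L], collapse = ", "))
    f <- .rowAnovaF(exprValues(ds), labels)
    f[is.na(f)] <- 0
    FeatureRanking(geneIds(ds), f, method = "anova")
}

#' Prefilter a dataset by knowledge-base relevance, then rank
#'
#' Modifying selector: the dataset is first restricted to the genes a
#' knowledge base deems relevant for the search terms, then the base
#' ranker runs on the restriction. The resulting ranking contains only
#' knowledge-base-relevant genes.
#'
#' @param ds an [ExpressionDataset-class].
#' @param kb an [AssociationKB-class].
#' @param terms search terms passed to [getRelevantGenes()].
#' @param minScore minimal association score for relevance.
#' @param baseRanker a function `ExpressionDataset -> FeatureRanking`,
#'   e.g. [rankByAnovaF()].
#' @return A [FeatureRanking-class] with method
#'   \code{"prefilter_<base>"}.
#' @export
prefilterSelect <- function(ds, kb, terms, minScore = 0,
                            baseRanker = rankByAnovaF) {
    rel <- getRelevantGenes(kb, terms, minScore)
    keep <- intersect(geneIds(ds), rel)
    if (length(keep) == 0L)
        stop("no dataset gene is knowledge-base relevant")
    sub <- ds[keep, ]
    base <- baseRanker(sub)
    new("FeatureRanking",
        method = paste0("prefilter_", methodName(base)),
        ranking = rankingTable(base),
        metadata = list(kb = kbName(kb), min_score = minScore))
}

#' Drop knowledge-base-irrelevant genes from a ranking
#'
#' Modifying selector: removes ranked genes that are not relevant under
#' the knowledge base, preserving the order of the survivors.
#'
#' @param baseRanking a [FeatureRanking-class].
#' @inheritParams prefilterSelect
#' @return A [FeatureRanking-class] with method
#'   \code{"postfilter_<base>"}.
#' @export
postfilterSelect <- function(baseRanking, kb, terms, minScore = 0) {
    rel <- getRelevantGenes(kb, terms, minScore)
    r <- rankingTable(baseRanking)
    r <- r[r$gene %in% rel, , drop = FALSE]
    if (nrow(r) == 0L)
        stop("no ranked gene is knowledge-base relevant")
    rownames(r) <- NULL
    new("FeatureRanking",
        method = paste0("postfilter_", methodName(baseRanking)),
        ranking = r,
        metadata = list(kb = kbName(kb), min_score = minScore))
}

#' Extend a statistical feature set with knowledge-base genes
#'
#' Modifying selector: takes the top \code{kStat} genes of the base
#' ranking and appends up to \code{kKb} further knowledge-base-relevant
#' genes (ordered by association score descending, ties by gene id)
#' that are not already included. Only genes present in the base ranking
#' (i.e. measured in the dataset) are eligible for extension. Because
#' the two parts have incommensurable scores, the returned ranking
#' carries ordinal scores (n..1) encoding the order.
#'
#' @param baseRanking a [FeatureRanking-class].
#' @param kb an [AssociationKB-class].
#' @param terms search terms.
#' @param minScore minimal association score for the extension genes.
#' @param kStat number of statistical genes to keep (>= 0).
#' @param kKb maximal number of knowledge-base genes to append (>= 0).
#' @return A [FeatureRanking-class] with method
#'   \code{"extension_<base>"}.
#' @export
extensionSelect <- function(baseRanking, kb, terms, minScore = 0,
                            kStat = 10L, kKb = 10L) {
    stopifnot(kStat >= 0L, kKb >= 0L)
    base <- rankedGenes(baseRanking)
    statPart <- utils::head(base, kStat)
    scores <- getGeneScores(kb, terms, aggregation = "max")
    scores <- scores[scores >= minScore]
    cand <- setdiff(intersect(names(scores), base), statPart)
    cand <- cand[order(-scores[cand], cand)]
    kbPart <- utils::head(cand, kKb)
    genes <- c(statPart, kbPart)
    if (length(genes) == 0L) stop("extension selected no gene")
    new("FeatureRanking",
        method = paste0("extension_", methodName(baseRanking)),
        ranking = data.frame(gene = genes,
                             score = rev(seq_along(genes)),
                             stringsAsFactors = FALSE),
        metadata = list(kb = kbName(kb), k_stat = kStat, k_kb = kKb,
                        ordinal_scores = TRUE))
}

#' Weight statistical scores by knowledge-base association scores
#'
#' Combining selector: each gene's statistical relevance score is
#' multiplied by its knowledge-base association score,
#' \eqn{s_i = s_i^{trad} \times s_i^{kb}}, and the genes are re-ranked
#' by the combined score. Genes without a knowledge-base record receive
#' 0 (policy \code{"zero"}) or a small \code{epsilon} (default policy),
#' which keeps them in the ranking but below any covered gene of equal
#' statistical score.
#'
#' @param baseRanking a [FeatureRanking-class] of statistical scores.
#' @param kbScores named numeric vector from [getGeneScores()].
#' @param missingPolicy \code{"epsilon"} or \code{"zero"}.
#' @param epsilon substitute score for uncovered genes (>= 0).
#' @return A [FeatureRanking-class] with method
#'   \code{"weighted_<base>"}; the applied policy is recorded in its
#'   metadata.
#' @export
weightedCombine <- function(baseRanking, kbScores,
                            missingPolicy = c("epsilon", "zero"),
                            epsilon = 0.001) {
    missingPolicy <- match.arg(missingPolicy)
    if (epsilon < 0) stop("epsilon must be non-negative")
    r <- rankingTable(baseRanking)
    fill <- if (missingPolicy == "zero") 0 else epsilon
    skb <- kbScores[r$gene]
    skb[is.na(skb)] <- fill
    FeatureRanking(r$gene, r$score * as.numeric(skb),
                   method = paste0("weighted_",
                                   methodName(baseRanking)),
                   metadata = list(missing_policy = missingPolicy,
                                   epsilon = epsilon))
}

#' Lasso with knowledge-base-shaped penalty factors
#'
#' Combining selector: fits an L1-regularized linear classifier (via
#' \pkg{glmnet}) in which each gene's penalty is scaled by a
#' feature-specific factor \eqn{w_i = 1 - s_i^{kb}} (clipped to
#' [\code{epsilon}, 1]), so strongly disease-associated genes are
#' penalized less and survive at regularization strengths that zero out
#' their unweighted twins. Multiclass labels are handled one-vs-rest;
#' the ranking score of a gene is its maximal absolute coefficient
#' across the one-vs-rest problems. Genes with all-zero coefficients
#' are ranked last, ordered by ascending penalty factor (encoded as
#' small negative scores).
#'
#' @param ds a labeled [ExpressionDataset-class] (>= 2 classes).
#'   Missing entries are imputed with per-gene means before fitting.
#' @param kbScores named numeric vector of association scores in [0, 1].
#' @param lambda positive regularization strength.
#' @param missingPolicy score for genes absent from \code{kbScores}:
#'   \code{"zero"} (penalty 1) or \code{"epsilon"}.
#' @param epsilon lower clip for penalty factors (> 0).
#' @param maxit maximal \pkg{glmnet} iterations.
#' @return A [FeatureRanking-class] with method \code{"kb_lasso"};
#'   metadata records lambda and the nonzero support size.
#' @export
kbPenalizedLasso <- function(ds, kbScores, lambda = 0.05,
                             missingPolicy = c("zero", "epsilon"),
                             epsilon = 0.001, maxit = 1e5) {
    missingPolicy <- match.arg(missingPolicy)
    if (lambda <= 0) stop("lambda must be positive")
    labels <- sampleLabels(ds)
    if (is.null(labels)) stop("penalized Lasso needs a labeled dataset")
    y <- factor(labels)
    if (nlevels(y) < 2L) stop("need >= 2 classes")
    m <- exprValues(ds)
    if (anyNA(m)) {
        mu <- rowMeans(m, na.rm = TRUE)
        mu[is.nan(mu)] <- 0
        idx <- which(is.na(m), arr.ind = TRUE)
        m[idx] <- mu[idx[, 1L]]
    }
    x <- t(m)
    fill <- if (missingPolicy == "zero") 0 else epsilon
    skb <- kbScores[colnames(x)]
    skb[is.na(skb)] <- fill
    w <- .clip(1 - as.numeric(skb), epsilon, 1)
    problems <- if (nlevels(y) == 2L) list(y == levels(y)[2L]) else
        lapply(levels(y), function(lv) y == lv)
    coefAbs <- matrix(0, ncol(x), length(problems),
                      dimnames = list(colnames(x), NULL))
    for (j in seq_along(problems)) {
        fit <- glmnet::glmnet(x, factor(problems[[j]]),
                              family = "binomial", alpha = 1,
                              penalty.factor = w, maxit = maxit,
                              standardize = TRUE)
        beta <- glmnet::coef.glmnet(fit, s = lambda, exact = FALSE)
        coefAbs[, j] <- abs(as.numeric(beta)[-1L])  # drop intercept
    }
    score <- apply(coefAbs, 1L, max)
    # zero-support genes: rank last, lower penalty preferred
    zero <- score == 0
    score[zero] <- -w[zero]
    FeatureRanking(colnames(x), score, method = "kb_lasso",
                   metadata = list(lambda = lambda,
                                   missing_policy = missingPolicy,
                                   epsilon = epsilon,
                                   support_size = sum(!zero)))
}

#' Take the top k genes of a ranking
#'
#' @param ranking a [FeatureRanking-class].
#' @param k number of genes, 1 <= k <= number of ranked genes.
#' @return Character vector of the first \code{k} genes in rank order.
#' @export
selectTopK <- function(ranking, k) {
    n <- nrow(rankingTable(ranking))
    if (k < 1L || k > n)
        stop("k must lie in [1, ", n, "]")
    rankedGenes(ranking)[seq_len(k)]
}

#' Write a ranking as TSV
#'
#' @param ranking a [FeatureRanking-class].
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeRanking <- function(ranking, path) {
    r <- rankingTable(ranking)
    .writeTsv(data.frame(rank = seq_len(nrow(r)), gene_id = r$gene,
                         score = r$score,
                         method_name = methodName(ranking)), path)
    invisible(path)
}
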