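# Network selector: pathways as features. A pathway is class-relevant
# when the expression profiles of its member genes associate with the
# sample classes; relevance is quantified as the mean ANOVA F of the
# measured members and calibrated by a label-permutation null.

#' Select class-relevant pathways
#'
#' Scores every pathway by the mean one-way ANOVA F statistic of its
#' measured member genes and attaches an empirical p-value from a
#' label-permutation null: labels are shuffled \code{nPermutations}
#' times (one seed-derived stream), the pathway statistic is recomputed
#' each time, and p = (1 + #\{permuted >= observed\}) /
#' (nPermutations + 1). The top \code{nPathways} pathways by relevance
#' are returned. Pathways without measured members are excluded
#' (logged).
#'
#' @param ds a labeled [ExpressionDataset-class].
#' @param net a [NetworkKB-class].
#' @param nPathways number of pathways to keep.
#' @param nPermutations permutations for the empirical p-value.
#' @param seed integer seed for the permutation stream.
#' @return A [PathwayFeatureSet-class] with relevance scores and
#'   p-values; its activity matrix is empty until
#'   [pathwayActivityMatrix()] is applied.
#' @export
selectRelevantPathways <- function(ds, net, nPathways = 5L,
                                   nPermutations = 200L, seed = 1L) {
    labels <- sampleLabels(ds)
    if (is.null(labels)) stop("pathway selection needs labels")
    m <- exprValues(ds)
    memb <- lapply(pathwayNames(net), function(p)
        intersect(pathwayMembers(net, p), rownames(m)))
    names(memb) <- pathwayNames(net)
    empty <- names(memb)[lengths(memb) == 0L]
    if (length(empty))
        .log("excluded pathway(s) with no measured member: ",
             paste(empty, collapse = ", "))
    memb <- memb[lengths(memb) > 0L]
    if (length(memb) == 0L)
        stop("no pathway shares a gene with the dataset")

    pathStat <- function(f) vapply(memb, function(g)
        mean(f[g], na.rm = TRUE), numeric(1))
    fobs <- .rowAnovaF(m, labels)
    fobs[is.na(fobs)] <- 0
    obs <- pathStat(fobs)
    exceed <- integer(length(memb))
    .withSeed(seed, {
        for (b in seq_len(nPermutations)) {
            fperm <- .rowAnovaF(m, sample(labels))
            fperm[is.na(fperm)] <- 0
            exceed <- exceed + (pathStat(fperm) >= obs)
        }
    })
    pval <- (1 + exceed) / (nPermutations + 1)
    o <- order(-obs, names(memb))
    keep <- utils::head(o, nPathways)
    df <- data.frame(pathway = names(memb)[keep], score = obs[keep],
                     p_value = pval[keep],
                     n_measured = lengths(memb)[keep],
                     stringsAsFactors = FALSE)
    rownames(df) <- NULL
    new("PathwayFeatureSet", pathways = df,
        activity = matrix(numeric(0), 0, 0))
}

#' Per-sample pathway activity features
#'
#' Computes, for each selected pathway, a per-sample activity score:
#' the mean over the pathway's measured member genes of the gene's
#' z-scored expression (centering and scaling use the mean and standard
#' deviation over the samples provided). The activity matrix replaces
#' genes as the feature space for classification.
#'
#' @param ds an [ExpressionDataset-class].
#' @param pathwaySet a [PathwayFeatureSet-class] from
#'   [selectRelevantPathways()], or a character vector of pathway names.
#' @param net the [NetworkKB-class] defining memberships.
#' @return A [PathwayFeatureSet-class] whose activity matrix has one row
#'   per selected pathway and one column per sample.
#' @export
pathwayActivityMatrix <- function(ds, pathwaySet, net) {
    if (is.character(pathwaySet)) {
        if (length(pathwaySet) == 0L) stop("no pathway selected")
        pathwaySet <- new("PathwayFeatureSet",
            pathways = data.frame(pathway = pathwaySet,
                                  score = NA_real_, p_value = NA_real_,
                                  n_measured = NA_integer_,
                                  stringsAsFactors = FALSE),
            activity = matrix(numeric(0), 0, 0))
    }
    pw <- pathwayScores(pathwaySet)$pathway
    if (length(pw) == 0L) stop("no pathway selected")
    m <- exprValues(ds)
    mu <- rowMeans(m, na.rm = TRUE)
    sd <- sqrt(.rowVarsNA(m))
    sd[is.na(sd) | sd == 0] <- 1   # constant genes contribute z = 0
    z <- (m - mu) / sd
    act <- t(vapply(pw, function(p) {
        g <- intersect(pathwayMembers(net, p), rownames(m))
        if (length(g) == 0L)
            stop("pathway '", p, "' has no measured member gene")
        colMeans(z[g, , drop = FALSE], na.rm = TRUE)
    }, numeric(ncol(m))))
    rownames(act) <- pw
    colnames(act) <- colnames(m)
    new("PathwayFeatureSet", pathways = pathwayScores(pathwaySet),
        activity = act)
}

#' Turn pathway activities into a dataset for classification
#'
#' @param pathwaySet a [PathwayFeatureSet-class] with computed activity.
#' @param labels optional named label vector (sample id -> class).
#' @return An [ExpressionDataset-class] whose "genes" are pathways.
#' @export
activityDataset <- function(pathwaySet, labels = NULL) {
    act <- activityMatrix(pathwaySet)
    if (nrow(act) == 0L) stop("activity matrix not computed yet")
    ExpressionDataset(act, labels = labels)
}
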