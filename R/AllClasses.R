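#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#'   assayNames colData colData<-
NULL

#' ExpressionDataset: a labeled gene expression matrix
#'
#' Container for a normalized gene expression matrix in canonical
#' genes-by-samples orientation, extending
#' \linkS4class{SummarizedExperiment}. The single assay \code{"exprs"}
#' holds expression levels (missing entries allowed); optional per-sample
#' class labels live in \code{colData(x)$label}.
#'
#' @slot .. inherited from \linkS4class{SummarizedExperiment}.
#'
#' @section Validity:
#' Gene and sample identifiers must be present, non-empty and unique;
#' if labels are attached, every sample must carry exactly one
#' non-missing label.
#'
#' @seealso [ExpressionDataset()], [loadExpressionMatrix()],
#'   [attachLabels()]
#' @exportClass ExpressionDataset
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
    msg <- character()
    gid <- rownames(object)
    sid <- colnames(object)
    if (is.null(gid) || is.null(sid))
        msg <- c(msg, "gene and sample identifiers are required")
    if (!is.null(gid) && (anyDuplicated(gid) || any(!nzchar(gid))))
        msg <- c(msg, "gene identifiers must be unique and non-empty")
    if (!is.null(sid) && (anyDuplicated(sid) || any(!nzchar(sid))))
        msg <- c(msg, "sample identifiers must be unique and non-empty")
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    if ("label" %in% colnames(SummarizedExperiment::colData(object))) {
        lab <- SummarizedExperiment::colData(object)$label
        if (anyNA(lab))
            msg <- c(msg, "every sample must have exactly one label")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionDataset
#'
#' @param values numeric matrix, genes in rows and samples in columns,
#'   with row and column names. `NA` entries denote missing measurements.
#' @param labels optional character vector of class labels, either named
#'   by sample identifier or in column order.
#' @return An [ExpressionDataset-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ds <- ExpressionDataset(m, labels = rep(c("a", "b"), 2))
#' sampleLabels(ds)
#' @export
ExpressionDataset <- function(values, labels = NULL) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    se <- SummarizedExperiment(assays = list(exprs = values))
    ds <- new("ExpressionDataset", se)
    if (!is.null(labels)) {
        if (!is.null(names(labels)))
            labels <- labels[colnames(values)]
        if (length(labels) != ncol(values))
            stop("need one label per sample")
        colData(ds)$label <- as.character(labels)
    }
    validObject(ds)
    ds
}

#' AssociationKB: gene-term association scores
#'
#' A local knowledge base of gene-term associations. Each record links a
#' search term (a disease, phenotype or pathway name) to a gene with an
#' association score in [0, 1] quantifying the strength of evidence.
#'
#' @slot name single string naming the knowledge base.
#' @slot records data.frame with columns \code{term}, \code{gene},
#'   \code{score}; (term, gene) pairs are unique, scores lie in [0, 1].
#' @seealso [loadAssociationKB()], [getRelevantGenes()], [getGeneScores()]
#' @exportClass AssociationKB
setClass("AssociationKB",
    representation(name = "character", records = "data.frame"))

setValidity("AssociationKB", function(object) {
    msg <- character()
    r <- object@records
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "'name' must be a single non-empty string")
    need <- c("term", "gene", "score")
    if (!all(need %in% colnames(r)))
        msg <- c(msg, "records need columns term, gene, score")
    else {
        if (nrow(r) == 0L)
            msg <- c(msg, "knowledge base contains no records")
        if (nrow(r) && (anyNA(r$score) ||
                        any(r$score < 0) || any(r$score > 1)))
            msg <- c(msg, "association scores must lie in [0, 1]")
        if (anyDuplicated(r[, c("term", "gene")]))
            msg <- c(msg, "(term, gene) pairs must be unique")
        if (nrow(r) && (any(!nzchar(r$term)) || any(!nzchar(r$gene))))
            msg <- c(msg, "empty term or gene identifiers")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an AssociationKB from a record table
#'
#' @param records data.frame with columns \code{term}, \code{gene},
#'   \code{score} (scores in [0, 1]).
#' @param name knowledge-base name used in reports.
#' @return An [AssociationKB-class] object.
#' @export
AssociationKB <- function(records, name = "kb") {
    records <- as.data.frame(records)[, c("term", "gene", "score")]
    records$term <- as.character(records$term)
    records$gene <- as.character(records$gene)
    records$score <- as.numeric(records$score)
    rownames(records) <- NULL
    new("AssociationKB", name = name, records = records)
}

#' NetworkKB: named pathway graphs
#'
#' A local knowledge base of pathways, each an undirected graph over
#' member genes. Self-loops and duplicate edges are removed on
#' construction; directed input edges are symmetrized.
#'
#' @slot pathways named list of \pkg{igraph} graphs; vertex names are
#'   gene identifiers.
#' @slot annotations data.frame of optional pathway-term annotations
#'   (columns \code{pathway}, \code{term}); may be empty.
#' @seealso [loadNetworkKB()], [connectednessGeneScores()]
#' @exportClass NetworkKB
setClass("NetworkKB",
    representation(pathways = "list", annotations = "data.frame"))

setValidity("NetworkKB", function(object) {
    msg <- character()
    p <- object@pathways
    if (length(p) == 0L)
        msg <- c(msg, "network knowledge base contains no pathways")
    if (is.null(names(p)) || anyDuplicated(names(p)))
        msg <- c(msg, "pathways must be uniquely named")
    ok <- vapply(p, function(g) igraph::is_igraph(g) &&
                     !igraph::is_directed(g) &&
                     !igraph::any_loop(g) && !igraph::any_multiple(g),
                 logical(1))
    if (!all(ok))
        msg <- c(msg, "each pathway must be a simple undirected graph")
    if (length(msg)) msg else TRUE
})

#' FeatureRanking: genes ordered by a relevance score
#'
#' Genes ranked by a relevance score, sorted by score descending with
#' ties broken by gene identifier ascending so rankings are
#' deterministic. Houses both plain statistical scores and
#' knowledge-base-combined scores.
#'
#' @slot method single string naming the selector that produced the
#'   ranking.
#' @slot ranking data.frame with columns \code{gene}, \code{score};
#'   scores finite, genes unique.
#' @slot metadata list of selector parameters worth reporting (e.g. the
#'   missing-score policy of a combined ranking).
#' @seealso [rankByVariance()], [rankByAnovaF()], [weightedCombine()],
#'   [selectTopK()]
#' @exportClass FeatureRanking
setClass("FeatureRanking",
    representation(method = "character", ranking = "data.frame",
                   metadata = "list"))

setValidity("FeatureRanking", function(object) {
    msg <- character()
    r <- object@ranking
    if (!all(c("gene", "score") %in% colnames(r)))
        msg <- c(msg, "ranking needs columns gene, score")
    else {
        if (nrow(r) == 0L)
            msg <- c(msg, "ranking is empty")
        if (anyDuplicated(r$gene))
            msg <- c(msg, "ranked genes must be unique")
        if (nrow(r) && any(!is.finite(r$score)))
            msg <- c(msg, "ranking scores must be finite")
        if (nrow(r) > 1L) {
            o <- order(-r$score, r$gene)
            if (!identical(o, seq_len(nrow(r))))
                msg <- c(msg,
                    "ranking must be sorted by (score desc, gene asc)")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a FeatureRanking
#'
#' Sorts the given per-gene scores into canonical order (score
#' descending, gene ascending on ties).
#'
#' @param genes character vector of gene identifiers.
#' @param scores numeric vector of finite relevance scores.
#' @param method selector name recorded with the ranking.
#' @param metadata optional list of selector parameters.
#' @return A [FeatureRanking-class] object.
#' @export
FeatureRanking <- function(genes, scores, method = "unnamed",
                           metadata = list()) {
    stopifnot(length(genes) == length(scores))
    genes <- as.character(genes)
    scores <- as.numeric(scores)
    o <- order(-scores, genes)
    r <- data.frame(gene = genes[o], score = scores[o],
                    stringsAsFactors = FALSE)
    rownames(r) <- NULL
    new("FeatureRanking", method = method, ranking = r,
        metadata = metadata)
}

#' PathwayFeatureSet: selected pathways with activity features
#'
#' Result of the network selector: pathways scored for class relevance,
#' optionally with a per-sample activity matrix usable as classification
#' features in place of genes.
#'
#' @slot pathways data.frame with columns \code{pathway}, \code{score},
#'   \code{p_value}, \code{n_measured}.
#' @slot activity numeric matrix, pathways by samples; zero rows until
#'   activities are computed, afterwards rows correspond one-to-one to
#'   the selected pathways.
#' @seealso [selectRelevantPathways()], [pathwayActivityMatrix()]
#' @exportClass PathwayFeatureSet
setClass("PathwayFeatureSet",
    representation(pathways = "data.frame", activity = "matrix"))

setValidity("PathwayFeatureSet", function(object) {
    msg <- character()
    p <- object@pathways
    if (!all(c("pathway", "score", "p_value") %in% colnames(p)))
        msg <- c(msg, "pathways need columns pathway, score, p_value")
    if (nrow(object@activity) > 0L &&
        !identical(rownames(object@activity), p$pathway))
        msg <- c(msg, "activity rows must match selected pathways")
    if (length(msg)) msg else TRUE
})
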