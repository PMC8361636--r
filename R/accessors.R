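#' @rdname ExpressionDataset-class
#' @export
setMethod("exprValues", "ExpressionDataset",
          function(x) assay(x, "exprs"))

#' @rdname ExpressionDataset-class
#' @export
setMethod("geneIds", "ExpressionDataset", function(x) rownames(x))

#' @rdname ExpressionDataset-class
#' @export
setMethod("sampleIds", "ExpressionDataset", function(x) colnames(x))

#' @rdname ExpressionDataset-class
#' @export
setMethod("hasLabels", "ExpressionDataset",
          function(x) "label" %in% colnames(colData(x)))

#' @rdname ExpressionDataset-class
#' @export
setMethod("sampleLabels", "ExpressionDataset", function(x) {
    if (!hasLabels(x)) return(NULL)
    stats::setNames(colData(x)$label, colnames(x))
})

setMethod("show", "ExpressionDataset", function(object) {
    cat("ExpressionDataset:", nrow(object), "genes x",
        ncol(object), "samples\n")
    nmiss <- sum(is.na(assay(object, "exprs")))
    if (nmiss > 0)
        cat("  missing entries:", nmiss, "\n")
    if (hasLabels(object)) {
        tab <- table(colData(object)$label)
        cat("  labels:", paste(sprintf("%s (%d)", names(tab), tab),
                               collapse = ", "), "\n")
    } else cat("  labels: none\n")
})

#' @rdname AssociationKB-class
#' @export
setMethod("kbName", "AssociationKB", function(x) x@name)

#' @rdname AssociationKB-class
#' @export
setMethod("kbRecords", "AssociationKB", function(x) x@records)

#' @rdname AssociationKB-class
#' @export
setMethod("kbTerms", "AssociationKB",
          function(x) sort(unique(x@records$term)))

setMethod("show", "AssociationKB", function(object) {
    cat("AssociationKB '", object@name, "': ", nrow(object@records),
        " gene-term records, ", length(unique(object@records$term)),
        " terms, ", length(unique(object@records$gene)), " genes\n",
        sep = "")
})

#' @rdname NetworkKB-class
#' @export
setMethod("pathwayNames", "NetworkKB", function(x) names(x@pathways))

#' @rdname NetworkKB-class
#' @export
setMethod("pathwayGraph", "NetworkKB", function(x, pathway) {
    if (!pathway %in% names(x@pathways))
        stop("unknown pathway: ", pathway)
    x@pathways[[pathway]]
})

#' @rdname NetworkKB-class
#' @export
setMethod("pathwayMembers", "NetworkKB", function(x, pathway) {
    igraph::V(pathwayGraph(x, pathway))$name
})

setMethod("show", "NetworkKB", function(object) {
    sizes <- vapply(object@pathways, igraph::vcount, numeric(1))
    cat("NetworkKB:", length(object@pathways), "pathways,",
        "member genes per pathway", min(sizes), "-", max(sizes), "\n")
})

#' @rdname FeatureRanking-class
#' @export
setMethod("rankingTable", "FeatureRanking", function(x) x@ranking)

#' @rdname FeatureRanking-class
#' @export
setMethod("rankedGenes", "FeatureRanking", function(x) x@ranking$gene)

#' @rdname FeatureRanking-class
#' @export
setMethod("methodName", "FeatureRanking", function(x) x@method)

setMethod("show", "FeatureRanking", function(object) {
    cat("FeatureRanking (", object@method, "): ",
        nrow(object@ranking), " genes\n", sep = "")
    top <- utils::head(object@ranking, 5L)
    for (i in seq_len(nrow(top)))
        cat(sprintf("  %2d. %s  %.4g\n", i, top$gene[i], top$score[i]))
    if (nrow(object@ranking) > 5L) cat("  ...\n")
})

#' @rdname PathwayFeatureSet-class
#' @export
setMethod("pathwayScores", "PathwayFeatureSet", function(x) x@pathways)

#' @rdname PathwayFeatureSet-class
#' @export
setMethod("activityMatrix", "PathwayFeatureSet", function(x) x@activity)

setMethod("show", "PathwayFeatureSet", function(object) {
    cat("PathwayFeatureSet:", nrow(object@pathways),
        "pathways; activity matrix:",
        if (nrow(object@activity)) paste(dim(object@activity),
                                         collapse = " x ") else "absent",
        "\n")
})
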