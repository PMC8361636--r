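#' Load a gene expression matrix from delimited text
#'
#' Reads a delimited expression table (header row, first column = row
#' identifiers) and returns it in the canonical genes-by-samples
#' orientation. Input files may store genes in rows or in columns; the
#' orientation can be detected automatically by matching header labels
#' against a set of known sample identifiers (typically the metadata
#' table's sample column), falling back to treating the longer axis as
#' samples.
#'
#' @param path path to a delimited text file.
#' @param orientation one of \code{"auto"}, \code{"genes_in_rows"},
#'   \code{"samples_in_rows"}.
#' @param knownSampleIds optional character vector of sample identifiers
#'   used to resolve the orientation when \code{orientation = "auto"}.
#' @param sep field delimiter (tab by default).
#' @return An [ExpressionDataset-class] (genes x samples, unlabeled).
#' @details With \code{orientation = "auto"} and \code{knownSampleIds}
#'   given, the axis whose labels overlap the known identifiers is taken
#'   as samples; if neither axis overlaps, loading fails rather than
#'   guessing. Without known identifiers the axis with more entries is
#'   taken as samples.
#' @export
loadExpressionMatrix <- function(path,
                                 orientation = c("auto", "genes_in_rows",
                                                 "samples_in_rows"),
                                 knownSampleIds = NULL, sep = "\t") {
    orientation <- match.arg(orientation)
    if (!file.exists(path)) stop("cannot read expression file: ", path)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, quote = "",
                            comment.char = "", stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("expression file has no data columns")
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate row identifiers in expression file")
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids

    genesInRows <- switch(orientation,
        genes_in_rows = TRUE,
        samples_in_rows = FALSE,
        auto = {
            if (!is.null(knownSampleIds)) {
                colHit <- length(intersect(colnames(m), knownSampleIds))
                rowHit <- length(intersect(rownames(m), knownSampleIds))
                if (colHit == 0L && rowHit == 0L)
                    stop("orientation is ambiguous: neither axis ",
                         "overlaps the known sample identifiers")
                colHit >= rowHit
            } else ncol(m) >= nrow(m)
        })
    if (!genesInRows) m <- t(m)
    if (anyDuplicated(rownames(m)))
        stop("duplicate gene identifiers after orientation")
    if (anyDuplicated(colnames(m)))
        stop("duplicate sample identifiers after orientation")
    .log("loaded expression matrix: ", nrow(m), " genes x ", ncol(m),
         " samples")
    ExpressionDataset(m)
}

#' Load an identifier mapping table
#'
#' Reads a two-column delimited table of (source_id, target_id) pairs
#' used to translate gene identifiers between namespaces (e.g. probe to
#' gene symbol). A source identifier may map to several targets.
#'
#' @param path path to a two-column TSV.
#' @param header whether the file carries a header line.
#' @param sourceNamespace,targetNamespace namespace labels recorded on
#'   the table.
#' @return A data.frame with columns \code{source_id}, \code{target_id}
#'   and attributes \code{sourceNamespace}, \code{targetNamespace}.
#' @export
loadMappingTable <- function(path, header = TRUE,
                             sourceNamespace = "source",
                             targetNamespace = "target") {
    df <- utils::read.table(path, header = header, sep = "\t",
                            quote = "", comment.char = "",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("mapping table needs two columns")
    out <- data.frame(source_id = as.character(df[[1L]]),
                      target_id = as.character(df[[2L]]),
                      stringsAsFactors = FALSE)
    if (nrow(out) == 0L) stop("mapping table is empty")
    if (any(!nzchar(out$source_id)) || any(!nzchar(out$target_id)))
        stop("mapping table contains empty identifiers")
    attr(out, "sourceNamespace") <- sourceNamespace
    attr(out, "targetNamespace") <- targetNamespace
    out
}

#' Attach class labels from a metadata table
#'
#' Labels the samples of a dataset with a user-chosen metadata
#' attribute. Samples absent from the metadata are dropped (their count
#' is logged); the label attribute becomes the dataset's class labels.
#'
#' @param ds an [ExpressionDataset-class].
#' @param metadata a data.frame, or path to a TSV with a header row.
#' @param sampleIdColumn metadata column holding sample identifiers.
#' @param labelAttribute metadata column to use as the class label.
#' @return A labeled [ExpressionDataset-class] restricted to the samples
#'   present in both inputs.
#' @export
attachLabels <- function(ds, metadata, sampleIdColumn, labelAttribute) {
    if (is.character(metadata) && length(metadata) == 1L)
        metadata <- utils::read.table(metadata, header = TRUE,
                                      sep = "\t", quote = "",
                                      comment.char = "",
                                      check.names = FALSE,
                                      stringsAsFactors = FALSE)
    if (!sampleIdColumn %in% colnames(metadata))
        stop("metadata lacks sample id column '", sampleIdColumn, "'")
    if (!labelAttribute %in% colnames(metadata))
        stop("metadata lacks label attribute '", labelAttribute, "'")
    meta <- metadata[!duplicated(metadata[[sampleIdColumn]]), ]
    ids <- as.character(meta[[sampleIdColumn]])
    keep <- intersect(sampleIds(ds), ids)
    if (length(keep) == 0L)
        stop("no dataset sample appears in the metadata")
    dropped <- length(sampleIds(ds)) - length(keep)
    if (dropped > 0L)
        .log("dropped ", dropped, " sample(s) absent from metadata")
    labels <- stats::setNames(as.character(meta[[labelAttribute]]),
                              ids)[keep]
    if (anyNA(labels))
        stop("label attribute '", labelAttribute, "' has missing values")
    ExpressionDataset(exprValues(ds)[, keep, drop = FALSE],
                      labels = labels)
}

#' Filter samples and features by missing-value fraction
#'
#' Removes samples, then features, whose fraction of missing entries
#' exceeds the given thresholds. Filtering samples first makes the
#' result deterministic: a feature's missing fraction is computed on the
#' samples that survived.
#'
#' @param ds an [ExpressionDataset-class].
#' @param maxMissingFractionPerFeature,maxMissingFractionPerSample
#'   tolerated missing fractions in [0, 1]; entities strictly above the
#'   threshold are removed.
#' @return The filtered [ExpressionDataset-class]; retained entries are
#'   unchanged.
#' @export
filterMissing <- function(ds, maxMissingFractionPerFeature = 0.1,
                          maxMissingFractionPerSample = 0.1) {
    stopifnot(maxMissingFractionPerFeature >= 0,
              maxMissingFractionPerFeature <= 1,
              maxMissingFractionPerSample >= 0,
              maxMissingFractionPerSample <= 1)
    m <- exprValues(ds)
    sampFrac <- colMeans(is.na(m))
    keepS <- sampFrac <= maxMissingFractionPerSample
    if (!any(keepS)) stop("missing-value filter removed every sample")
    if (any(!keepS))
        .log("removed ", sum(!keepS), " sample(s) above missing ",
             "threshold ", maxMissingFractionPerSample)
    m <- m[, keepS, drop = FALSE]
    featFrac <- rowMeans(is.na(m))
    keepF <- featFrac <= maxMissingFractionPerFeature
    if (!any(keepF)) stop("missing-value filter removed every feature")
    if (any(!keepF))
        .log("removed ", sum(!keepF), " feature(s) above missing ",
             "threshold ", maxMissingFractionPerFeature)
    m <- m[keepF, , drop = FALSE]
    labels <- sampleLabels(ds)
    ExpressionDataset(m, labels = if (!is.null(labels))
        labels[colnames(m)] else NULL)
}

#' Map gene identifiers through a local mapping table
#'
#' Renames the dataset's genes via a (source_id, target_id) table.
#' Genes without a mapping are dropped (count logged). When several
#' source genes map to the same target, the collision is resolved per
#' policy: \code{"first"} keeps the values of the first mapping record
#' (table order), \code{"drop"} removes all colliding genes.
#'
#' @param ds an [ExpressionDataset-class].
#' @param table mapping table from [loadMappingTable()] (any data.frame
#'   with columns \code{source_id}, \code{target_id} works).
#' @param collisionPolicy \code{"first"} or \code{"drop"}.
#' @return The renamed [ExpressionDataset-class]; every output row
#'   equals some input row (no values are invented).
#' @export
mapIdentifiers <- function(ds, table,
                           collisionPolicy = c("first", "drop")) {
    collisionPolicy <- match.arg(collisionPolicy)
    if (nrow(table) == 0L) stop("mapping table is empty")
    tab <- table[table$source_id %in% geneIds(ds), , drop = FALSE]
    # one target per source: honour table order
    tab <- tab[!duplicated(tab$source_id), , drop = FALSE]
    if (collisionPolicy == "first") {
        tab <- tab[!duplicated(tab$target_id), , drop = FALSE]
    } else {
        dup <- tab$target_id %in% tab$target_id[duplicated(tab$target_id)]
        if (any(dup))
            .log("dropped ", sum(dup), " gene(s) colliding on target ",
                 "identifiers")
        tab <- tab[!dup, , drop = FALSE]
    }
    if (nrow(tab) == 0L) stop("no gene could be mapped")
    unmapped <- length(geneIds(ds)) - nrow(tab)
    if (unmapped > 0L)
        .log("dropped ", unmapped, " unmapped gene(s)")
    m <- exprValues(ds)[tab$source_id, , drop = FALSE]
    rownames(m) <- tab$target_id
    ExpressionDataset(m, labels = sampleLabels(ds))
}
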