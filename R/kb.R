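#' Load a gene-term association knowledge base
#'
#' Reads a local three-column TSV (term, gene, score) of gene-term
#' association records, the offline backend for disease-gene association
#' resources. Scores must lie in [0, 1]; duplicate (term, gene) pairs
#' are rejected.
#'
#' @param path path to a three-column TSV with a header line.
#' @param name knowledge-base name used in reports (defaults to the file
#'   name).
#' @return An [AssociationKB-class] object.
#' @export
loadAssociationKB <- function(path, name = NULL) {
    if (is.null(name))
        name <- tools::file_path_sans_ext(basename(path))
    df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                            comment.char = "", stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop("association file is empty: ", path)
    if (ncol(df) < 3L) stop("association file needs 3 columns")
    AssociationKB(data.frame(term = as.character(df[[1L]]),
                             gene = as.character(df[[2L]]),
                             score = as.numeric(df[[3L]])),
                  name = name)
}

#' Load a pathway network knowledge base
#'
#' Builds per-pathway interaction graphs from a GMT membership file and
#' a pathway-annotated edge list. Each pathway graph contains exactly
#' the GMT member genes as vertices; edges naming non-member genes are
#' dropped with a logged count, self-loops and duplicate edges are
#' removed, and directed input is symmetrized.
#'
#' @param gmtPath GMT file (set name, description, tab-separated genes).
#' @param edgesPath TSV with header and columns pathway, gene_a, gene_b.
#' @return A [NetworkKB-class] object.
#' @export
loadNetworkKB <- function(gmtPath, edgesPath) {
    members <- fgsea::gmtPathways(gmtPath)
    if (length(members) == 0L) stop("GMT file defines no pathway")
    edges <- utils::read.table(edgesPath, header = TRUE, sep = "\t",
                               quote = "", comment.char = "",
                               stringsAsFactors = FALSE)
    if (ncol(edges) < 3L)
        stop("edge list needs columns pathway, gene_a, gene_b")
    colnames(edges)[1:3] <- c("pathway", "gene_a", "gene_b")
    unknown <- setdiff(unique(edges$pathway), names(members))
    if (length(unknown))
        stop("edge list references pathway(s) absent from GMT: ",
             paste(unknown, collapse = ", "))
    graphs <- lapply(names(members), function(p) {
        nodes <- unique(members[[p]])
        e <- edges[edges$pathway == p, c("gene_a", "gene_b"),
                   drop = FALSE]
        ok <- e$gene_a %in% nodes & e$gene_b %in% nodes
        if (any(!ok))
            .log("pathway ", p, ": dropped ", sum(!ok),
                 " edge(s) naming non-member genes")
        g <- igraph::graph_from_data_frame(e[ok, , drop = FALSE],
                                           directed = FALSE,
                                           vertices = nodes)
        igraph::simplify(g)
    })
    names(graphs) <- names(members)
    new("NetworkKB", pathways = graphs,
        annotations = data.frame(pathway = character(),
                                 term = character()))
}

#' Construct a NetworkKB from in-memory edge tables
#'
#' @param members named list of character vectors (pathway members).
#' @param edges data.frame with columns pathway, gene_a, gene_b; may be
#'   empty for edgeless pathways.
#' @return A [NetworkKB-class] object.
#' @export
NetworkKB <- function(members, edges = NULL) {
    gmt <- tempfile(fileext = ".gmt")
    on.exit(unlink(gmt), add = TRUE)
    writeLines(vapply(names(members), function(p)
        paste(c(p, "na", members[[p]]), collapse = "\t"),
        character(1)), gmt)
    edgef <- tempfile(fileext = ".tsv")
    on.exit(unlink(edgef), add = TRUE)
    if (is.null(edges))
        edges <- data.frame(pathway = character(), gene_a = character(),
                            gene_b = character())
    .writeTsv(edges, edgef)
    loadNetworkKB(gmt, edgef)
}

#' Genes relevant to a set of search terms
#'
#' The union, over the given terms, of genes whose association score
#' reaches \code{minScore}. Unknown terms contribute nothing (logged).
#'
#' @param kb an [AssociationKB-class].
#' @param terms non-empty character vector of search terms.
#' @param minScore minimal association score to qualify.
#' @return A character vector of gene identifiers (sorted, unique).
#' @export
getRelevantGenes <- function(kb, terms, minScore = 0) {
    stopifnot(length(terms) >= 1L)
    r <- kbRecords(kb)
    unknown <- setdiff(terms, r$term)
    if (length(unknown))
        .log("term(s) not in knowledge base '", kbName(kb), "': ",
             paste(unknown, collapse = ", "))
    hit <- r$term %in% terms & r$score >= minScore
    sort(unique(r$gene[hit]))
}

#' Per-gene association scores aggregated over search terms
#'
#' For each gene with at least one record under the given terms, the
#' maximum (default) or mean association score across those terms.
#' Genes without a record are absent from the result; consumers choose
#' their own default (see [weightedCombine()]).
#'
#' @param kb an [AssociationKB-class].
#' @param terms non-empty character vector of search terms.
#' @param aggregation \code{"max"} (a gene strongly tied to any term is
#'   relevant) or \code{"mean"}.
#' @return A named numeric vector, gene id -> aggregated score.
#' @export
getGeneScores <- function(kb, terms, aggregation = c("max", "mean")) {
    aggregation <- match.arg(aggregation)
    stopifnot(length(terms) >= 1L)
    r <- kbRecords(kb)
    r <- r[r$term %in% terms, , drop = FALSE]
    if (nrow(r) == 0L) return(stats::setNames(numeric(0), character(0)))
    f <- if (aggregation == "max") max else mean
    agg <- tapply(r$score, r$gene, f)
    stats::setNames(as.numeric(agg), names(agg))
}

#' Connectedness gene scores from pathway topology
#'
#' Scores each gene by how central it is within the pathways containing
#' it. Within a pathway p with n member genes, a gene's percentile
#' connectedness rank is its fractional rank by vertex degree,
#' pr = rank(degree, average ties) / n, a value in (0, 1]. The gene
#' score is the mean of these percentile ranks across the pathways the
#' gene belongs to:
#' \deqn{s_i = \frac{\sum_{p=1}^{|P_i|} pr_{p,i}}{|P_i|}}
#' Hub genes with many interactions therefore score high, and higher
#' still when they are hubs in several pathways. Isolated member genes
#' (degree 0) rank lowest within their pathway.
#'
#' @param net a [NetworkKB-class].
#' @return A named numeric vector in (0, 1], gene id -> score; genes in
#'   no pathway are absent.
#' @export
connectednessGeneScores <- function(net) {
    total <- numeric(0)
    count <- integer(0)
    for (p in pathwayNames(net)) {
        g <- pathwayGraph(net, p)
        deg <- igraph::degree(g)
        pr <- rank(deg, ties.method = "average") / length(deg)
        genes <- names(pr)
        newg <- setdiff(genes, names(total))
        if (length(newg)) {
            total[newg] <- 0
            count[newg] <- 0L
        }
        total[genes] <- total[genes] + pr
        count[genes] <- count[genes] + 1L
    }
    s <- total / count
    s[order(names(s))]
}

#' Coverage statistics for a knowledge base
#'
#' Summarizes, per search term, how much prior knowledge is available:
#' the number of associated genes and the distribution of their
#' association scores. Terms without records are reported with count 0.
#'
#' @param kb an [AssociationKB-class].
#' @param terms non-empty character vector of search terms.
#' @return A data.frame (one row per term) with columns \code{term},
#'   \code{gene_count}, \code{min}, \code{q1}, \code{median}, \code{q3},
#'   \code{max}, \code{mean}; summary columns are \code{NA} for empty
#'   terms.
#' @export
coverageReport <- function(kb, terms) {
    stopifnot(length(terms) >= 1L)
    r <- kbRecords(kb)
    rows <- lapply(terms, function(tm) {
        sc <- r$score[r$term == tm]
        if (length(sc) == 0L)
            return(data.frame(term = tm, gene_count = 0L,
                              min = NA_real_, q1 = NA_real_,
                              median = NA_real_, q3 = NA_real_,
                              max = NA_real_, mean = NA_real_))
        q <- stats::quantile(sc, c(0, .25, .5, .75, 1), names = FALSE)
        data.frame(term = tm, gene_count = length(sc), min = q[1],
                   q1 = q[2], median = q[3], q3 = q[4], max = q[5],
                   mean = mean(sc))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
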