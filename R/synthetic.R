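# Synthetic study generator: class-structured expression with planted
# informative genes, matching association knowledge bases, pathway
# graphs with hub structure, and the file dialects the loaders read.
# Everything derives deterministically from the spec's seed.

#' Specification of a synthetic benchmarking study
#'
#' Bundles the parameters of the synthetic data generator. The defaults
#' describe the study conditions used throughout the package's tests:
#' 1000 genes, 100 samples in 2 balanced classes, 10 informative genes
#' shifted by 2 within-class standard deviations, a knowledge base
#' scoring planted genes 0.9 and covered null genes 0.1, and 10 random
#' pathways of 20 genes with 10% hub nodes.
#'
#' @param nSamples,nGenes,nClasses dataset dimensions.
#' @param nInformative number of planted class-informative genes
#'   (<= nGenes).
#' @param effectSize class-mean shift of informative genes in units of
#'   the within-class standard deviation (which is 1).
#' @param missingRate fraction of entries set missing uniformly at
#'   random, in [0, 1].
#' @param kbSignalScore,kbNoiseScore association scores (centers, small
#'   bounded jitter) given to planted and covered null genes.
#' @param kbCoverage fraction of null genes receiving a KB record.
#' @param nPathways,pathwaySize pathway graph counts and sizes.
#' @param hubFraction fraction of pathway nodes designated as
#'   high-degree hubs.
#' @param seed integer master seed; all generator randomness derives
#'   from it.
#' @return A classed list (\code{"SimulationSpec"}).
#' @export
simulationSpec <- function(nSamples = 100L, nGenes = 1000L,
                           nClasses = 2L, nInformative = 10L,
                           effectSize = 2, missingRate = 0,
                           kbSignalScore = 0.9, kbNoiseScore = 0.1,
                           kbCoverage = 0.5, nPathways = 10L,
                           pathwaySize = 20L, hubFraction = 0.1,
                           seed = 1L) {
    spec <- list(nSamples = as.integer(nSamples),
                 nGenes = as.integer(nGenes),
                 nClasses = as.integer(nClasses),
                 nInformative = as.integer(nInformative),
                 effectSize = effectSize, missingRate = missingRate,
                 kbSignalScore = kbSignalScore,
                 kbNoiseScore = kbNoiseScore, kbCoverage = kbCoverage,
                 nPathways = as.integer(nPathways),
                 pathwaySize = as.integer(pathwaySize),
                 hubFraction = hubFraction, seed = as.integer(seed))
    stopifnot(spec$nGenes >= 1L, spec$nSamples >= spec$nClasses,
              spec$nClasses >= 2L,
              spec$nInformative >= 0L,
              spec$nInformative <= spec$nGenes,
              spec$missingRate >= 0, spec$missingRate <= 1,
              spec$kbSignalScore >= 0, spec$kbSignalScore <= 1,
              spec$kbNoiseScore >= 0, spec$kbNoiseScore <= 1,
              spec$kbCoverage >= 0, spec$kbCoverage <= 1,
              spec$hubFraction >= 0, spec$hubFraction <= 1,
              spec$pathwaySize >= 1L, spec$nPathways >= 1L)
    class(spec) <- "SimulationSpec"
    spec
}

# deterministic per-gene, per-class mean shifts for informative genes:
# class c is shifted by effectSize * (c - 1) * direction(gene), with a
# random sign per gene so signal is not all one-directional
.plantedShifts <- function(spec) {
    genes <- sprintf("gene_%04d", seq_len(spec$nGenes))
    informative <- utils::head(genes, spec$nInformative)
    .withSeed(.childSeed(spec$seed, 101L), {
        dir <- sample(c(-1, 1), spec$nInformative, replace = TRUE)
    })
    shifts <- outer(dir, seq_len(spec$nClasses) - 1L) * spec$effectSize
    dimnames(shifts) <- list(informative,
                             paste0("class", seq_len(spec$nClasses)))
    list(genes = genes, informative = informative, shifts = shifts)
}

# core expression sampler shared by generateExpression and
# generatePairedDataset
.sampleExpression <- function(spec, truth, noiseSeed, globalShift = 0,
                              samplePrefix = "sample") {
    nS <- spec$nSamples
    classes <- paste0("class", seq_len(spec$nClasses))
    labels <- classes[((seq_len(nS) - 1L) %% spec$nClasses) + 1L]
    samples <- sprintf("%s_%03d", samplePrefix, seq_len(nS))
    names(labels) <- samples
    m <- .withSeed(noiseSeed, {
        mat <- matrix(stats::rnorm(spec$nGenes * nS), spec$nGenes, nS,
                      dimnames = list(truth$genes, samples))
        if (spec$nInformative > 0L)
            mat[truth$informative, ] <- mat[truth$informative, ] +
                truth$shifts[, labels, drop = FALSE]
        if (spec$missingRate > 0) {
            miss <- stats::runif(length(mat)) < spec$missingRate
            mat[miss] <- NA_real_
        }
        mat
    })
    ExpressionDataset(m + globalShift, labels = labels)
}

#' Generate a class-structured expression dataset with planted signal
#'
#' Samples per-gene Gaussian noise with standard deviation 1 and adds
#' class-specific mean shifts of magnitude \code{effectSize} to the
#' planted informative genes (random direction per gene, deterministic
#' from the seed). Missing entries are placed uniformly at rate
#' \code{missingRate}. Classes are balanced via round-robin assignment.
#'
#' @param spec a [simulationSpec()].
#' @return A list with elements \code{dataset} (labeled
#'   [ExpressionDataset-class]) and \code{truth} (list with
#'   \code{informative} gene ids and the planted \code{shifts} matrix).
#' @export
generateExpression <- function(spec) {
    truth <- .plantedShifts(spec)
    ds <- .sampleExpression(spec, truth, .childSeed(spec$seed, 1L))
    list(dataset = ds,
         truth = list(informative = truth$informative,
                      shifts = truth$shifts, genes = truth$genes))
}

#' Generate an association knowledge base for a synthetic study
#'
#' Planted informative genes receive association scores near
#' \code{kbSignalScore}; a random \code{kbCoverage} fraction of null
#' genes receives scores near \code{kbNoiseScore}. Jitter is bounded
#' (+/- 0.05, clipped) so all scores stay in [0, 1]. All records share
#' a single search term, \code{"target_condition"}.
#'
#' @param truth ground-truth list from [generateExpression()].
#' @param spec the matching [simulationSpec()].
#' @return An [AssociationKB-class] named \code{"synthetic_kb"}.
#' @export
generateAssociationKB <- function(truth, spec) {
    nulls <- setdiff(truth$genes, truth$informative)
    .withSeed(.childSeed(spec$seed, 2L), {
        covered <- sample(nulls, round(spec$kbCoverage * length(nulls)))
        jitter <- function(center, n)
            .clip(center + stats::runif(n, -0.05, 0.05), 0, 1)
        rec <- data.frame(
            term = "target_condition",
            gene = c(truth$informative, covered),
            score = c(jitter(spec$kbSignalScore,
                             length(truth$informative)),
                      jitter(spec$kbNoiseScore, length(covered))),
            stringsAsFactors = FALSE)
    })
    AssociationKB(rec, name = "synthetic_kb")
}

#' Generate a pathway network knowledge base for a synthetic study
#'
#' Builds \code{nPathways} random pathway graphs of size
#' \code{pathwaySize} by preferential attachment, which produces the
#' hub structure of real interaction networks. The first pathway is the
#' designated signal pathway: its members are the planted informative
#' genes padded with random null genes. In every pathway,
#' \code{hubFraction} of the member genes are mapped onto the
#' highest-degree vertices.
#'
#' @param truth ground-truth list from [generateExpression()].
#' @param spec the matching [simulationSpec()].
#' @return A list with elements \code{net} ([NetworkKB-class]),
#'   \code{signalPathway} (its name) and \code{hubs} (named list of hub
#'   genes per pathway).
#' @export
generateNetworkKB <- function(truth, spec) {
    nulls <- setdiff(truth$genes, truth$informative)
    members <- list()
    edges <- list()
    hubs <- list()
    .withSeed(.childSeed(spec$seed, 3L), {
        for (i in seq_len(spec$nPathways)) {
            pname <- sprintf("pathway_%02d", i)
            size <- spec$pathwaySize
            mem <- if (i == 1L && spec$nInformative > 0L) {
                pad <- sample(nulls,
                              max(size - spec$nInformative, 0L))
                c(truth$informative, pad)
            } else sample(nulls, min(size, length(nulls)))
            n <- length(mem)
            g <- if (n >= 2L)
                igraph::sample_pa(n, power = 1, m = min(2L, n - 1L),
                                  directed = FALSE)
            else igraph::make_empty_graph(n, directed = FALSE)
            # map the highest-degree vertices to designated hub genes
            nHub <- max(1L, round(spec$hubFraction * n))
            ord <- order(-igraph::degree(g),
                         seq_len(n))        # degree desc, stable
            vertexGene <- character(n)
            hubGenes <- mem[seq_len(nHub)]
            vertexGene[ord[seq_len(nHub)]] <- hubGenes
            vertexGene[ord[-seq_len(nHub)]] <- mem[-seq_len(nHub)]
            el <- igraph::as_edgelist(g, names = FALSE)
            members[[pname]] <- mem
            hubs[[pname]] <- hubGenes
            edges[[pname]] <- data.frame(
                pathway = pname, gene_a = vertexGene[el[, 1L]],
                gene_b = vertexGene[el[, 2L]],
                stringsAsFactors = FALSE)
        }
    })
    net <- NetworkKB(members, do.call(rbind, edges))
    list(net = net, signalPathway = "pathway_01", hubs = hubs)
}

#' Generate a second, related dataset for robustness evaluation
#'
#' Draws a fresh dataset with the same planted informative genes and
#' class structure but independent noise, optionally adding a global
#' mean shift that emulates a cohort effect between studies.
#'
#' @param truth ground-truth list from [generateExpression()].
#' @param spec the matching [simulationSpec()].
#' @param shift global mean shift added to every entry.
#' @return A labeled [ExpressionDataset-class] over the identical gene
#'   set.
#' @export
generatePairedDataset <- function(truth, spec, shift = 0) {
    .sampleExpression(spec, truth, .childSeed(spec$seed, 4L),
                      globalShift = shift, samplePrefix = "sampleB")
}

#' Materialize a complete synthetic benchmark workspace
#'
#' Writes every input file a benchmark run needs, in the exact dialects
#' the loaders read: expression matrix and metadata (TSV), gene-term
#' associations (TSV), pathway membership (GMT), pathway edges (TSV),
#' an identity mapping table (TSV), and a ground-truth file listing the
#' planted genes. File contents are fully determined by the spec.
#'
#' @param spec a [simulationSpec()].
#' @param dir output directory (created if needed).
#' @param secondDataset whether to also write a paired second dataset.
#' @return Invisibly, a list of the written paths plus the ground
#'   truth.
#' @export
writeFixtureWorkspace <- function(spec, dir, secondDataset = TRUE) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    gen <- generateExpression(spec)
    ds <- gen$dataset
    kb <- generateAssociationKB(gen$truth, spec)
    netgen <- generateNetworkKB(gen$truth, spec)

    paths <- list(
        expression = file.path(dir, "expression.tsv"),
        metadata = file.path(dir, "metadata.tsv"),
        associations = file.path(dir, "associations.tsv"),
        gmt = file.path(dir, "pathways.gmt"),
        edges = file.path(dir, "edges.tsv"),
        mapping = file.path(dir, "mapping.tsv"),
        truth = file.path(dir, "ground_truth.tsv"))

    m <- exprValues(ds)
    .writeTsv(data.frame(gene_id = rownames(m), m,
                         check.names = FALSE), paths$expression)
    .writeTsv(data.frame(sample_id = sampleIds(ds),
                         condition = unname(sampleLabels(ds))),
              paths$metadata)
    .writeTsv(stats::setNames(kbRecords(kb),
                              c("term", "gene", "score")),
              paths$associations)
    net <- netgen$net
    writeLines(vapply(pathwayNames(net), function(p)
        paste(c(p, "synthetic", pathwayMembers(net, p)),
              collapse = "\t"), character(1)), paths$gmt)
    edgeRows <- do.call(rbind, lapply(pathwayNames(net), function(p) {
        el <- igraph::as_edgelist(pathwayGraph(net, p))
        if (nrow(el) == 0L) return(NULL)
        data.frame(pathway = p, gene_a = el[, 1L], gene_b = el[, 2L],
                   stringsAsFactors = FALSE)
    }))
    .writeTsv(edgeRows, paths$edges)
    .writeTsv(data.frame(source_id = geneIds(ds),
                         target_id = geneIds(ds)), paths$mapping)
    .writeTsv(data.frame(gene_id = gen$truth$informative,
                         role = "informative"), paths$truth)
    if (secondDataset) {
        dsB <- generatePairedDataset(gen$truth, spec)
        mB <- exprValues(dsB)
        paths$expression_b <- file.path(dir, "expression_b.tsv")
        paths$metadata_b <- file.path(dir, "metadata_b.tsv")
        .writeTsv(data.frame(gene_id = rownames(mB), mB,
                             check.names = FALSE), paths$expression_b)
        .writeTsv(data.frame(sample_id = sampleIds(dsB),
                             condition = unname(sampleLabels(dsB))),
                  paths$metadata_b)
    }
    invisible(c(paths, list(truth = gen$truth,
                            signalPathway = netgen$signalPathway)))
}
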