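# Benchmark orchestration: preprocessing -> knowledge-base coverage ->
# timed selectors -> feature-size-sweep cross-validation -> optional
# cross-dataset robustness -> ranking concordance, overlaps and
# enrichment. Analytic outputs are deterministic given (config, seed,
# inputs); wall-clock runtimes and timestamps live only under logs/.

# restrict a ranking to a gene subset, preserving scores
.restrictRanking <- function(fr, genes) {
    r <- rankingTable(fr)
    r <- r[r$gene %in% genes, , drop = FALSE]
    FeatureRanking(r$gene, r$score, method = methodName(fr))
}

#' Run a configured benchmark
#'
#' Executes the full benchmarking pipeline described by a configuration:
#' loads and preprocesses the expression data, reports knowledge-base
#' coverage, runs every configured feature selector (timed; a failing
#' selector is logged and skipped without aborting the others), sweeps
#' feature-set sizes with stratified cross-validation, optionally
#' validates the selected features on a second dataset, and compares
#' selectors by Kendall's W, feature/annotation overlaps and local
#' enrichment.
#'
#' @param cfg a \code{BenchmarkConfig} from [loadConfig()], or a path
#'   to a config INI.
#' @param outDir output directory; defaults to the configured
#'   \code{[output] dir}, falling back to a temporary directory.
#' @return Invisibly, a list with \code{outDir}, the selector
#'   \code{rankings}, the long \code{metrics} table, selector
#'   \code{runtimes} and \code{failures} (named list of error
#'   messages; empty on full success).
#' @section Output layout: subdirectories \code{preprocessing/},
#'   \code{coverage/}, \code{rankings/}, \code{metrics/},
#'   \code{enrichment/}, \code{logs/}, plus the effective-config
#'   snapshot \code{config_snapshot.ini}, which alone suffices to
#'   reproduce the run.
#' @export
runBenchmark <- function(cfg, outDir = NULL) {
    if (is.character(cfg)) cfg <- loadConfig(cfg)
    if (is.null(outDir))
        outDir <- configParam(cfg, "output", "dir",
                              tempfile("pkbench_run_"))
    dirs <- file.path(outDir, c("preprocessing", "coverage", "rankings",
                                "metrics", "enrichment", "logs"))
    for (d in dirs) dir.create(d, recursive = TRUE,
                               showWarnings = FALSE)
    logPath <- file.path(outDir, "logs", "run.log")
    logCon <- file(logPath, open = "wt")
    on.exit(close(logCon), add = TRUE)
    logLine <- function(...) {
        writeLines(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                          ...), logCon)
    }
    # capture package log messages into the run log
    withLog <- function(expr) withCallingHandlers(expr,
        message = function(m) {
            logLine(trimws(conditionMessage(m)))
            invokeRestart("muffleMessage")
        })
    .writeConfigSnapshot(cfg, file.path(outDir, "config_snapshot.ini"))

    seed <- as.integer(.configNum(cfg, "evaluation", "seed", 1))
    terms <- .configList(cfg, "knowledge", "terms")
    classifiers <- .configList(cfg, "evaluation", "classifiers",
                               listClassifiers())
    sizes <- .configSizes(cfg)
    cvK <- as.integer(.configNum(cfg, "evaluation", "cv_k", 10))
    topN <- as.integer(.configNum(cfg, "evaluation", "top_n",
                                  max(sizes)))

    ## ---- preprocessing (failure here aborts the run) ----
    logLine("stage: preprocessing")
    meta <- utils::read.table(configParam(cfg, "data", "metadata"),
                              header = TRUE, sep = "\t", quote = "",
                              comment.char = "", check.names = FALSE,
                              stringsAsFactors = FALSE)
    idCol <- configParam(cfg, "data", "sample_id_column")
    ds <- withLog(loadExpressionMatrix(
        configParam(cfg, "data", "expression"),
        orientation = configParam(cfg, "data", "orientation", "auto"),
        knownSampleIds = as.character(meta[[idCol]])))
    mappingPath <- configParam(cfg, "data", "mapping")
    if (!is.null(mappingPath))
        ds <- withLog(mapIdentifiers(ds, loadMappingTable(mappingPath)))
    ds <- withLog(filterMissing(ds,
        .configNum(cfg, "preprocessing", "max_missing_feature", 0.5),
        .configNum(cfg, "preprocessing", "max_missing_sample", 0.5)))
    ds <- withLog(attachLabels(ds, meta, idCol,
        configParam(cfg, "data", "label_attribute")))
    m <- exprValues(ds)
    .writeTsv(data.frame(gene_id = rownames(m), m, check.names = FALSE),
              file.path(outDir, "preprocessing", "expression.tsv"))
    .writeTsv(data.frame(sample_id = sampleIds(ds),
                         label = unname(sampleLabels(ds))),
              file.path(outDir, "preprocessing", "labels.tsv"))

    ## ---- knowledge bases and coverage ----
    kbs <- list(association = NULL, network = NULL)
    assocPath <- configParam(cfg, "knowledge", "associations")
    if (!is.null(assocPath)) {
        kbs$association <- loadAssociationKB(assocPath)
        if (length(terms) == 0L) terms <- kbTerms(kbs$association)
        logLine("stage: knowledge-base coverage")
        .writeTsv(coverageReport(kbs$association, terms),
                  file.path(outDir, "coverage", "coverage.tsv"))
    }
    gmtPath <- configParam(cfg, "knowledge", "gmt")
    edgesPath <- configParam(cfg, "knowledge", "edges")
    if (!is.null(gmtPath) && !is.null(edgesPath)) {
        kbs$network <- withLog(loadNetworkKB(gmtPath, edgesPath))
        cs <- connectednessGeneScores(kbs$network)
        .writeTsv(data.frame(gene_id = names(cs), score = unname(cs)),
                  file.path(outDir, "coverage",
                            "connectedness_scores.tsv"))
    }

    ## ---- selectors (timed; failures isolated) ----
    selectorNames <- .configList(cfg, "selection", "selectors")
    selParams <- c(cfg$params$selection,
                   list(terms = terms,
                        min_score = .configNum(cfg, "knowledge",
                                               "min_score", 0),
                        seed = seed))
    rankings <- list()
    pathwaySets <- list()
    runtimes <- list()
    failures <- list()
    metricsList <- list()
    for (nm in selectorNames) {
        logLine("stage: selector ", nm)
        sel <- .getSelector(nm)
        res <- tryCatch(
            runtimeProfile(function()
                withLog(sel$factory(ds, kbs, selParams))),
            error = function(e) e)
        if (inherits(res, "error")) {
            failures[[nm]] <- conditionMessage(res)
            logLine("selector ", nm, " FAILED: ",
                    conditionMessage(res))
            next
        }
        runtimes[[nm]] <- res$seconds
        if (sel$type == "gene") {
            rankings[[nm]] <- res$value
            writeRanking(res$value,
                         file.path(outDir, "rankings",
                                   paste0(nm, ".tsv")))
            sz <- sizes[sizes <= nrow(rankingTable(res$value))]
            metricsList[[nm]] <- withLog(sweepFeatureSizes(
                res$value, ds, classifiers, cvK, sz, seed))
        } else {
            pathwaySets[[nm]] <- res$value
            act <- activityMatrix(res$value)
            .writeTsv(data.frame(pathway = rownames(act), act,
                                 check.names = FALSE),
                      file.path(outDir, "rankings",
                                paste0(nm, "_activity.tsv")))
            .writeTsv(pathwayScores(res$value),
                      file.path(outDir, "rankings",
                                paste0(nm, "_pathways.tsv")))
            actDs <- activityDataset(res$value, sampleLabels(ds))
            metricsList[[nm]] <- withLog(kfoldCV(
                actDs, geneIds(actDs), classifiers, cvK, seed,
                selector = nm))
        }
    }
    metrics <- if (length(metricsList))
        do.call(rbind, c(metricsList, list(make.row.names = FALSE)))
    else NULL

    ## ---- cross-dataset robustness ----
    exprB <- configParam(cfg, "data", "expression_b")
    metaB <- configParam(cfg, "data", "metadata_b")
    doCross <- identical(configParam(cfg, "evaluation",
                                     "cross_dataset", "true"), "true")
    if (doCross && !is.null(exprB) && !is.null(metaB) &&
        length(rankings)) {
        logLine("stage: cross-dataset validation")
        metaBdf <- utils::read.table(metaB, header = TRUE, sep = "\t",
                                     quote = "", comment.char = "",
                                     check.names = FALSE,
                                     stringsAsFactors = FALSE)
        dsB <- withLog(loadExpressionMatrix(exprB,
            knownSampleIds = as.character(metaBdf[[idCol]])))
        dsB <- withLog(attachLabels(dsB, metaBdf, idCol,
            configParam(cfg, "data", "label_attribute")))
        crossRows <- lapply(names(rankings), function(nm) {
            k <- min(topN, nrow(rankingTable(rankings[[nm]])))
            mtb <- withLog(crossDatasetValidation(
                selectTopK(rankings[[nm]], k), dsB, classifiers, cvK,
                seed, selector = nm))
            mtb$selector <- paste0(nm, "_crossds")
            mtb
        })
        cross <- do.call(rbind, crossRows)
        .writeTsv(cross, file.path(outDir, "metrics",
                                   "metrics_cross_dataset.tsv"))
        metrics <- rbind(metrics, cross)
    }

    if (!is.null(metrics) && nrow(metrics)) {
        .writeTsv(metrics, file.path(outDir, "metrics", "metrics.tsv"))
        .writeTsv(averageMetrics(metrics),
                  file.path(outDir, "metrics", "metrics_averaged.tsv"))
    }
    if (length(runtimes))
        .writeTsv(data.frame(selector = names(runtimes),
                             seconds = unlist(runtimes)),
                  file.path(outDir, "logs", "runtimes.tsv"))

    ## ---- selector comparisons ----
    if (length(rankings) >= 2L) {
        logLine("stage: ranking concordance and overlaps")
        common <- Reduce(intersect, lapply(rankings, rankedGenes))
        if (length(common) >= 2L) {
            w <- kendallsW(lapply(rankings, .restrictRanking, common))
            .writeTsv(data.frame(statistic = "kendalls_w",
                                 value = w,
                                 n_rankings = length(rankings),
                                 n_common_genes = length(common)),
                      file.path(outDir, "metrics", "kendalls_w.tsv"))
        } else logLine("skipped Kendall's W: < 2 common genes")
        tops <- lapply(rankings, function(r)
            selectTopK(r, min(topN, nrow(rankingTable(r)))))
        .writeTsv(featureOverlap(tops),
                  file.path(outDir, "metrics", "feature_overlap.tsv"))
    }

    ## ---- enrichment ----
    enrichGmt <- configParam(cfg, "evaluation", "enrichment_gmt")
    if (!is.null(enrichGmt) && length(rankings)) {
        logLine("stage: enrichment")
        lib <- fgsea::gmtPathways(enrichGmt)
        background <- geneIds(ds)
        enrichSets <- list()
        for (nm in names(rankings)) {
            k <- min(topN, nrow(rankingTable(rankings[[nm]])))
            res <- tryCatch(
                enrich(selectTopK(rankings[[nm]], k), lib, background),
                error = function(e) {
                    logLine("enrichment for ", nm, " failed: ",
                            conditionMessage(e))
                    NULL
                })
            if (is.null(res)) next
            .writeTsv(res, file.path(outDir, "enrichment",
                                     paste0(nm, ".tsv")))
            enrichSets[[nm]] <- utils::head(res$term, topN)
        }
        if (length(enrichSets) >= 2L)
            .writeTsv(annotationOverlap(enrichSets),
                      file.path(outDir, "metrics",
                                "annotation_overlap.tsv"))
    }
    logLine("benchmark complete; selector failures: ",
            length(failures))
    invisible(list(outDir = outDir, rankings = rankings,
                   pathwaySets = pathwaySets, metrics = metrics,
                   runtimes = runtimes, failures = failures))
}
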