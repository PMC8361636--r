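test_that("generation is fully deterministic from the seed", {
    spec <- simulationSpec(nSamples = 30, nGenes = 50,
                           nInformative = 5, missingRate = 0.05,
                           seed = 42)
    g1 <- generateExpression(spec)
    g2 <- generateExpression(spec)
    expect_identical(exprValues(g1$dataset), exprValues(g2$dataset))
    expect_identical(g1$truth, g2$truth)
    expect_identical(kbRecords(generateAssociationKB(g1$truth, spec)),
                     kbRecords(generateAssociationKB(g2$truth, spec)))
    # workspace files byte-identical across runs
    d1 <- tempfile(); d2 <- tempfile()
    suppressMessages(writeFixtureWorkspace(spec, d1))
    suppressMessages(writeFixtureWorkspace(spec, d2))
    for (f in list.files(d1)) {
        expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                         readBin(file.path(d2, f), "raw", 1e6),
                         label = f)
    }
})

test_that("expression generator plants signal and missingness as told", {
    spec0 <- simulationSpec(nSamples = 40, nGenes = 30,
                            nInformative = 5, missingRate = 0,
                            seed = 1)
    g <- generateExpression(spec0)
    expect_false(anyNA(exprValues(g$dataset)))
    expect_length(g$truth$informative, 5)
    expect_equal(sort(unique(unname(sampleLabels(g$dataset)))),
                 c("class1", "class2"))

    specM <- simulationSpec(nSamples = 40, nGenes = 30,
                            missingRate = 0.2, seed = 1)
    gm <- generateExpression(specM)
    frac <- mean(is.na(exprValues(gm$dataset)))
    expect_gt(frac, 0.12); expect_lt(frac, 0.28)

    # effect 0: ANOVA p-values behave like a null (about 5% below .05)
    hits <- 0; total <- 0
    for (seed in 1:5) {
        s <- simulationSpec(nSamples = 60, nGenes = 200,
                            nInformative = 10, effectSize = 0,
                            seed = seed)
        gg <- generateExpression(s)
        f <- PKBench:::.rowAnovaF(exprValues(gg$dataset),
                                  sampleLabels(gg$dataset))
        p <- pf(f, 1, 58, lower.tail = FALSE)
        hits <- hits + sum(p < 0.05); total <- total + length(p)
    }
    expect_gt(hits / total, 0.02)
    expect_lt(hits / total, 0.09)
})

test_that("association generator separates signal from noise scores", {
    spec <- simulationSpec(nSamples = 20, nGenes = 100,
                           nInformative = 10, kbSignalScore = 0.9,
                           kbNoiseScore = 0.1, kbCoverage = 0.5,
                           seed = 3)
    truth <- generateExpression(spec)$truth
    kb <- generateAssociationKB(truth, spec)
    rec <- kbRecords(kb)
    inf <- rec$score[rec$gene %in% truth$informative]
    noise <- rec$score[!rec$gene %in% truth$informative]
    expect_gt(mean(inf), mean(noise))
    expect_equal(length(noise), 45)  # 50% of 90 null genes
    # full coverage gives every gene a record
    specF <- simulationSpec(nSamples = 20, nGenes = 100,
                            nInformative = 10, kbCoverage = 1,
                            seed = 3)
    kbF <- generateAssociationKB(truth, specF)
    expect_setequal(kbRecords(kbF)$gene, truth$genes)
    # score bounds respected across many seeds
    for (seed in 1:100) {
        s <- simulationSpec(nSamples = 10, nGenes = 30,
                            nInformative = 5, kbSignalScore = 0.98,
                            kbNoiseScore = 0.02, seed = seed)
        t <- generateExpression(s)$truth
        sc <- kbRecords(generateAssociationKB(t, s))$score
        expect_true(all(sc >= 0 & sc <= 1))
    }
})

test_that("network generator plants hubs and round-trips its files", {
    spec <- simulationSpec(nSamples = 40, nGenes = 80,
                           nInformative = 8, nPathways = 4,
                           pathwaySize = 15, hubFraction = 0.2,
                           seed = 9)
    truth <- generateExpression(spec)$truth
    netg <- generateNetworkKB(truth, spec)
    # designated hubs take the top within-pathway percentile ranks
    for (p in pathwayNames(netg$net)) {
        g <- pathwayGraph(netg$net, p)
        deg <- igraph::degree(g)
        pr <- rank(deg, ties.method = "average") / length(deg)
        hubs <- netg$hubs[[p]]
        expect_true(all(pr[hubs] >= max(pr[setdiff(names(pr), hubs)])),
                    label = p)
    }
    # files written by the workspace round-trip losslessly
    ws <- tempfile()
    paths <- suppressMessages(writeFixtureWorkspace(spec, ws,
                                                    secondDataset = FALSE))
    reloaded <- suppressMessages(loadNetworkKB(paths$gmt, paths$edges))
    expect_setequal(pathwayNames(reloaded), pathwayNames(netg$net))
    for (p in pathwayNames(netg$net)) {
        expect_setequal(pathwayMembers(reloaded, p),
                        pathwayMembers(netg$net, p))
        expect_equal(igraph::ecount(pathwayGraph(reloaded, p)),
                     igraph::ecount(pathwayGraph(netg$net, p)))
    }
    # the signal pathway's members are the most class-associated
    ds <- generateExpression(spec)$dataset
    f <- PKBench:::.rowAnovaF(exprValues(ds), sampleLabels(ds))
    meanF <- vapply(pathwayNames(netg$net), function(p)
        mean(f[pathwayMembers(netg$net, p)]), numeric(1))
    expect_equal(names(which.max(meanF)), netg$signalPathway)
})

test_that("paired datasets share structure but not noise", {
    spec <- simulationSpec(nSamples = 50, nGenes = 60,
                           nInformative = 6, effectSize = 2, seed = 4)
    g <- generateExpression(spec)
    dsB <- generatePairedDataset(g$truth, spec)
    expect_identical(geneIds(dsB), geneIds(g$dataset))
    expect_false(identical(exprValues(dsB), exprValues(g$dataset)))
    # same planted genes score high in both
    fB <- PKBench:::.rowAnovaF(exprValues(dsB), sampleLabels(dsB))
    topB <- names(sort(fB, decreasing = TRUE))[1:6]
    expect_gte(length(intersect(topB, g$truth$informative)), 5)
    # a global shift moves every entry by the same constant
    dsShift <- generatePairedDataset(g$truth, spec, shift = 3)
    expect_equal(exprValues(dsShift), exprValues(dsB) + 3)
})

test_that("simulation specs validate their invariants", {
    expect_error(simulationSpec(nGenes = 5, nInformative = 10))
    expect_error(simulationSpec(missingRate = 1.5))
    expect_error(simulationSpec(nClasses = 1))
    expect_s3_class(simulationSpec(), "SimulationSpec")
})
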