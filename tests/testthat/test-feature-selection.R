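test_that("variance ranking matches closed forms and a two-pass oracle", {
    m <- rbind(g_const = rep(1, 4),
               g_small = c(0, 1, 0, 1),
               g_big = c(0, 2, 0, 2))
    colnames(m) <- paste0("s", 1:4)
    r <- rankByVariance(ExpressionDataset(m))
    tab <- rankingTable(r)
    expect_equal(tab$gene[1], "g_big")
    expect_equal(tab$score[tab$gene == "g_big"], var(c(0, 2, 0, 2)))
    expect_equal(tab$gene[3], "g_const")
    expect_equal(tab$score[3], 0)

    # two-value closed forms: {0,2} -> 2, {0,1} -> 0.5
    m2 <- rbind(a = c(0, 2), b = c(0, 1))
    colnames(m2) <- c("s1", "s2")
    t2 <- rankingTable(rankByVariance(ExpressionDataset(m2)))
    expect_equal(t2$score, c(2, 0.5))

    # independent two-pass oracle on a random 20 x 10 matrix
    ds <- makeLabeledDataset(nGenes = 20, nSamples = 10, seed = 5)
    ours <- rankingTable(rankByVariance(ds))
    oracle <- apply(exprValues(ds), 1, function(x) {
        mu <- sum(x) / length(x)
        sum((x - mu)^2) / (length(x) - 1)
    })
    expect_equal(ours$score, unname(sort(oracle, decreasing = TRUE)),
                 tolerance = 1e-12)
    expect_equal(ours$gene,
                 names(sort(oracle, decreasing = TRUE)))
    expect_error(rankByVariance(ds[, 1]), ">= 2 samples")
})

test_that("ANOVA F ranking matches the textbook closed form", {
    m <- rbind(gene = c(1, 2, 3, 7, 8, 9))
    colnames(m) <- paste0("s", 1:6)
    ds <- ExpressionDataset(m, labels = rep(c("a", "b"), each = 3))
    f <- rankingTable(rankByAnovaF(ds))$score
    # between MS = 54, within MS = 1
    expect_equal(f, 54)
    # agrees with stats::anova as a second route
    fit <- anova(lm(m[1, ] ~ rep(c("a", "b"), each = 3)))
    expect_equal(f, fit$`F value`[1])
})

test_that("ANOVA F separates planted genes and flags degenerate input", {
    # equal class means -> F near 0, ranked at the bottom
    ds <- makeLabeledDataset(nGenes = 100, nSamples = 40, effect = 0,
                             seed = 2)
    m <- exprValues(ds)
    m["g100", ] <- rep(c(-1, -1, 1, 1), 10)  # same mean in both classes
    # strong planted gene ranks first against a 100-gene null background
    m["g001", ] <- withr::with_seed(7, rnorm(40, sd = 0.1)) +
        10 * (match(sampleLabels(ds), c("c1", "c2")) - 1)
    ds <- ExpressionDataset(m, labels = sampleLabels(ds))
    r <- rankingTable(rankByAnovaF(ds))
    expect_equal(r$gene[1], "g001")

    expect_error(rankByAnovaF(ExpressionDataset(m)), "labeled")
    tiny <- ExpressionDataset(m[, 1:3],
                              labels = c("a", "a", "b"))
    expect_error(rankByAnovaF(tiny), "< 2 samples")
})

test_that("prefilter and postfilter agree for subset-independent scores", {
    ds <- makeLabeledDataset(nGenes = 50, nSamples = 20, seed = 3)
    kb <- makeKb(terms = "t", genes = sprintf("g%03d", seq(2, 50, 2)),
                 scores = seq(0.5, 0.99, length.out = 25))
    pre <- prefilterSelect(ds, kb, "t", 0, baseRanker = rankByVariance)
    post <- postfilterSelect(rankByVariance(ds), kb, "t", 0)
    expect_equal(rankingTable(pre)$gene, rankingTable(post)$gene)
    expect_equal(rankingTable(pre)$score, rankingTable(post)$score)
    expect_equal(nrow(rankingTable(pre)), 25)

    # vacuous filter reproduces the base ranking
    allkb <- makeKb(terms = "t", genes = geneIds(ds),
                    scores = rep(0.9, 50))
    expect_equal(rankingTable(prefilterSelect(ds, allkb, "t", 0,
                                              rankByVariance)),
                 rankingTable(rankByVariance(ds)))
    # surviving genes keep their relative base order
    base <- rankedGenes(rankByVariance(ds))
    kept <- rankedGenes(post)
    expect_equal(kept, base[base %in% kept])

    expect_error(suppressMessages(
        prefilterSelect(ds, makeKb("t", "not_measured", .9), "t", 0)),
        "relevant")
    expect_error(suppressMessages(
        postfilterSelect(rankByVariance(ds),
                         makeKb("t", "not_measured", .9), "t", 0)),
        "relevant")
})

test_that("extension appends KB genes without duplication", {
    ds <- makeLabeledDataset(nGenes = 30, nSamples = 20, seed = 4)
    base <- rankByVariance(ds)
    kb <- makeKb(terms = rep("t", 10),
                 genes = sprintf("g%03d", 1:10),
                 scores = seq(1, 0.1, length.out = 10))
    ext <- extensionSelect(base, kb, "t", 0, kStat = 5, kKb = 5)
    genes <- rankedGenes(ext)
    expect_equal(genes[1:5], rankedGenes(base)[1:5])
    expect_false(anyDuplicated(genes) > 0)
    expect_lte(length(genes), 10)
    # kKb = 0 degenerates to top-kStat
    expect_equal(rankedGenes(extensionSelect(base, kb, "t", 0, 5, 0)),
                 rankedGenes(base)[1:5])
    # kStat = 0: KB genes by association score descending
    kbOnly <- rankedGenes(extensionSelect(base, kb, "t", 0, 0, 3))
    expect_equal(kbOnly, sprintf("g%03d", 1:3))
    # uniqueness under random fixtures
    for (seed in 1:5) {
        kbR <- withr::with_seed(seed, makeKb(
            terms = rep("t", 15),
            genes = sample(geneIds(ds), 15),
            scores = runif(15)))
        g <- rankedGenes(extensionSelect(base, kbR, "t", 0, 7, 7))
        expect_equal(anyDuplicated(g), 0L)
    }
})

test_that("weighted combination multiplies scores and re-ranks", {
    base <- FeatureRanking(c("a", "b"), c(2, 1), "stat")
    w <- weightedCombine(base, c(a = 0.5, b = 1),
                         missingPolicy = "zero")
    tab <- rankingTable(w)
    expect_equal(tab$score[tab$gene == "a"], 1.0)
    expect_equal(tab$gene[1], "a")  # 1.0 vs 1.0 tie -> gene id order

    # uniform KB scores preserve the base order exactly
    ds <- makeLabeledDataset(nGenes = 40, nSamples = 20, seed = 6)
    b <- rankByVariance(ds)
    uni <- weightedCombine(b, setNames(rep(1, 40), geneIds(ds)))
    expect_equal(rankedGenes(uni), rankedGenes(b))

    # zero policy pushes uncovered genes below any covered one
    z <- weightedCombine(b, setNames(rep(0.5, 39),
                                     geneIds(ds)[-1]),
                         missingPolicy = "zero")
    expect_equal(utils::tail(rankedGenes(z), 1), geneIds(ds)[1])
    expect_error(weightedCombine(b, c(g001 = .5), epsilon = -1),
                 "non-negative")
})

test_that("penalized Lasso honours per-feature penalty factors", {
    ds <- makeLabeledDataset(nGenes = 30, nSamples = 60, effect = 1,
                             nInformative = 5, seed = 8)
    # all penalty factors equal -> identical support to plain glmnet
    noKb <- setNames(rep(0, 30), geneIds(ds))  # w = 1 everywhere
    ours <- kbPenalizedLasso(ds, noKb, lambda = 0.05)
    y <- factor(sampleLabels(ds))
    plain <- glmnet::glmnet(t(exprValues(ds)), y, family = "binomial",
                            alpha = 1)
    beta <- as.numeric(glmnet::coef.glmnet(plain, s = 0.05))[-1]
    plainSupport <- geneIds(ds)[beta != 0]
    oursSupport <- with(rankingTable(ours), gene[score > 0])
    expect_setequal(oursSupport, plainSupport)

    # a strongly KB-backed gene survives a lambda that zeroes its
    # unweighted self
    path <- glmnet::glmnet(t(exprValues(ds)), y, family = "binomial")
    betaMat <- as.matrix(path$beta)
    # target = the planted gene that enters the path last
    planted <- sprintf("g%03d", 1:5)
    entry <- vapply(planted, function(g)
        suppressWarnings(max(path$lambda[betaMat[g, ] != 0])),
        numeric(1))
    target <- names(which.min(entry))
    zeroed <- path$lambda[betaMat[target, ] == 0 &
                          colSums(betaMat != 0) >= 2]
    expect_gt(length(zeroed), 0)
    lam <- min(zeroed)
    plainAtLam <- as.numeric(glmnet::coef.glmnet(path, s = lam,
                                                 exact = FALSE))[-1]
    expect_equal(plainAtLam[match(target, geneIds(ds))], 0)
    kbv <- setNames(rep(0, 30), geneIds(ds))
    kbv[target] <- 1    # penalty factor epsilon
    boosted <- kbPenalizedLasso(ds, kbv, lambda = lam)
    expect_gt(rankingTable(boosted)$score[
        rankingTable(boosted)$gene == target], 0)

    # extreme lambda: empty support, ranking falls back to penalty order
    kbv2 <- setNames(rep(0, 30), geneIds(ds))
    kbv2[target] <- 0.5
    allzero <- kbPenalizedLasso(ds, kbv2, lambda = 50)
    tab <- rankingTable(allzero)
    expect_true(all(tab$score <= 0))
    expect_equal(tab$gene[1], target)   # lowest penalty first
    expect_error(kbPenalizedLasso(ds, kbv, lambda = -1), "positive")
})

test_that("top-k selection is a nested prefix of the ranking", {
    r <- FeatureRanking(letters[1:5], 5:1, "m")
    expect_equal(selectTopK(r, 5), letters[1:5])
    expect_equal(selectTopK(r, 1), "a")
    for (k in 1:4)
        expect_true(all(selectTopK(r, k) %in% selectTopK(r, k + 1)))
    expect_error(selectTopK(r, 0), "k must")
    expect_error(selectTopK(r, 6), "k must")
})

test_that("rankings are deterministic with gene-id tie-breaks", {
    r <- FeatureRanking(c("b", "a", "c"), c(1, 1, 2), "m")
    expect_equal(rankedGenes(r), c("c", "a", "b"))
    expect_error(FeatureRanking(c("a", "a"), c(1, 2), "m"), "unique")
    expect_error(FeatureRanking("a", NaN, "m"), "finite")
})
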