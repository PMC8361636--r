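test_that("cross-validation is stratified, deterministic and leak-free", {
    ds <- makeLabeledDataset(nGenes = 10, nSamples = 40, effect = 10,
                             nInformative = 3, seed = 10)
    mt <- kfoldCV(ds, c("g001", "g002"), c("naive_bayes", "knn3"),
                  k = 5, seed = 3)
    # exact fold coverage: folds 0..k-1 once per (classifier, metric)
    cell <- mt[mt$classifier == "knn3" & mt$metric == "accuracy", ]
    expect_equal(sort(cell$fold), 0:4)
    expect_true(all(mt$value >= 0 & mt$value <= 1))
    # same seed twice: identical table
    expect_identical(mt, kfoldCV(ds, c("g001", "g002"),
                                 c("naive_bayes", "knn3"), k = 5,
                                 seed = 3))
    # stratification: per-fold class counts deviate < 1 sample's worth
    folds <- PKBench:::.stratifiedFolds(sampleLabels(ds), 5, seed = 3)
    for (f in 0:4) {
        tab <- table(sampleLabels(ds)[folds == f])
        expect_true(all(abs(tab - 4) < 1))  # 40 samples, 2x20, k=5
    }
    expect_error(kfoldCV(ds, "g001", "naive_bayes", k = 25, seed = 1),
                 "fewer than k")
    expect_error(kfoldCV(ds, "nope", "naive_bayes", k = 5, seed = 1),
                 "not in dataset")
    expect_error(kfoldCV(ds, "g001", "not_a_classifier", k = 5,
                         seed = 1), "unknown classifier")
})

test_that("preprocessing parameters come from training folds only", {
    ds <- makeLabeledDataset(nGenes = 5, nSamples = 20, effect = 5,
                             nInformative = 2, seed = 11)
    folds <- PKBench:::.stratifiedFolds(sampleLabels(ds), 4, seed = 1)
    victim <- names(folds)[folds == 0][1]
    # leakage canary: a gene constant in training folds but extreme in
    # one test sample must not move the training-fold fit
    m2 <- exprValues(ds)
    m2["g005", ] <- 1
    m2["g005", victim] <- 1e6
    ds2 <- ExpressionDataset(m2, sampleLabels(ds))
    train <- names(folds)[folds != 0]
    sc <- PKBench:::.fitScaler(t(exprValues(ds2))[train, ,
                                                  drop = FALSE])
    expect_equal(sc$mu[["g005"]], 1)
    expect_equal(sc$sd[["g005"]], 1)  # zero variance -> unit scale
    # fold-level check: metrics of folds not containing the perturbed
    # sample are unchanged when the test-only value changes
    m3 <- m2
    m3["g005", victim] <- -1e6
    ds3 <- ExpressionDataset(m3, sampleLabels(ds))
    mt2 <- kfoldCV(ds2, geneIds(ds2), "naive_bayes", k = 4, seed = 1)
    mt3 <- kfoldCV(ds3, geneIds(ds3), "naive_bayes", k = 4, seed = 1)
    expect_identical(mt2[mt2$fold != 0, ], mt3[mt3$fold != 0, ])
})

test_that("feature-size sweeps reuse one fold assignment", {
    ds <- makeLabeledDataset(nGenes = 15, nSamples = 30, effect = 3,
                             nInformative = 5, seed = 12)
    r <- rankByAnovaF(ds)
    mt <- sweepFeatureSizes(r, ds, "naive_bayes", k = 5, sizes = 1:4,
                            seed = 2)
    # counting contract: |sizes| x |classifiers| x k rows per metric
    expect_equal(nrow(mt), 4 * 1 * 5 * 2)
    expect_equal(sort(unique(mt$feature_set_size)), 1:4)
    # full-size sweep equals kfoldCV on all ranked genes
    full <- sweepFeatureSizes(r, ds, "naive_bayes", k = 5, sizes = 15,
                              seed = 2)
    direct <- kfoldCV(ds, selectTopK(r, 15), "naive_bayes", k = 5,
                      seed = 2, selector = methodName(r))
    expect_equal(full$value, direct$value)
    expect_error(sweepFeatureSizes(r, ds, "naive_bayes", 5,
                                   sizes = 1:99, seed = 1), "exceed")
})

test_that("accuracy is non-decreasing on a noiseless nested fixture", {
    # each added gene is individually informative and noiseless
    labels <- rep(c("a", "b"), 15)
    m <- rbind(g1 = ifelse(labels == "a", 0, 1),
               g2 = ifelse(labels == "a", 0, 1),
               g3 = ifelse(labels == "a", 0, 1))
    colnames(m) <- sprintf("s%02d", 1:30)
    ds <- ExpressionDataset(m, labels)
    r <- FeatureRanking(rownames(m), 3:1, "fixture")
    mt <- sweepFeatureSizes(r, ds, "knn3", k = 3, sizes = 1:3,
                            seed = 1)
    avg <- averageMetrics(mt)
    acc <- avg$value[avg$metric == "accuracy"]
    expect_true(all(diff(acc) >= 0))
    expect_equal(acc[1], 1)
})

test_that("cross-dataset validation reduces to in-dataset CV on A == B", {
    ds <- makeLabeledDataset(nGenes = 10, nSamples = 24, effect = 2,
                             nInformative = 3, seed = 13)
    feats <- c("g001", "g002", "g003")
    a <- kfoldCV(ds, feats, "naive_bayes", k = 4, seed = 5)
    b <- crossDatasetValidation(feats, ds, "naive_bayes", k = 4,
                                seed = 5)
    expect_equal(a$value, b$value)
    # permuting the sample order leaves averaged metrics unchanged
    perm <- withr::with_seed(1, sample(sampleIds(ds)))
    dsPerm <- ExpressionDataset(exprValues(ds)[, perm],
                                sampleLabels(ds)[perm])
    bPerm <- crossDatasetValidation(feats, dsPerm, "naive_bayes",
                                    k = 4, seed = 5)
    # fold assignment is (label, id, seed)-driven, so a permuted
    # sample order yields identical metrics
    expect_equal(b$value, bPerm$value)
    # features missing from B are dropped, the run proceeds
    okay <- suppressMessages(crossDatasetValidation(
        c(feats, "absent_gene"), ds, "naive_bayes", k = 4, seed = 5))
    expect_equal(okay$value, a$value)
    expect_error(crossDatasetValidation("absent", ds, "naive_bayes",
                                        4, 1), "no selected feature")
})

test_that("Kendall's W spans identical to reversed rankings", {
    r1 <- FeatureRanking(letters[1:5], 5:1, "m1")
    expect_equal(kendallsW(list(r1, r1, r1)), 1.0)
    # two mutually reversed rankings -> 0
    expect_equal(kendallsW(list(c("a", "b", "c"), c("c", "b", "a"))),
                 0.0)
    # invariant under item relabeling
    r2 <- FeatureRanking(letters[1:5], c(4, 5, 1, 2, 3), "m2")
    w12 <- kendallsW(list(r1, r2))
    relabel <- function(r) {
        tab <- rankingTable(r)
        FeatureRanking(chartr("abcde", "vwxyz", tab$gene), tab$score,
                       methodName(r))
    }
    expect_equal(kendallsW(list(relabel(r1), relabel(r2))), w12)
    expect_error(kendallsW(list(r1, FeatureRanking("q", 1, "x"))),
                 "identical item sets")
})

test_that("Kendall's W matches naive and vegan implementations", {
    skip_if_not_installed("vegan")
    for (seed in 1:25) {
        panel <- withr::with_seed(seed, {
            m <- sample(2:5, 1); n <- sample(3:8, 1)
            items <- paste0("i", seq_len(n))
            lapply(seq_len(m), function(j)
                FeatureRanking(items,
                               round(runif(n), 1),  # provoke ties
                               paste0("m", j)))
        })
        R <- vapply(panel, function(r) {
            tab <- rankingTable(r)
            setNames(rank(-tab$score), tab$gene)[sort(tab$gene)]
        }, numeric(nrow(rankingTable(panel[[1]]))))
        expect_equal(kendallsW(panel), naiveKendallsW(R),
                     tolerance = 1e-12)
        vw <- vegan::kendall.global(R)$Concordance_analysis["W", 1]
        expect_equal(kendallsW(panel), unname(vw), tolerance = 1e-10)
    }
})

test_that("exclusive overlap counts partition the union", {
    ov <- featureOverlap(list(A = c("x", "y", "z"),
                              B = c("p", "q", "r")))
    expect_equal(ov$count[ov$subset == "A"], 3)
    expect_equal(ov$count[ov$subset == "B"], 3)
    expect_equal(ov$count[ov$subset == "A&B"], 0)
    same <- featureOverlap(list(A = c("x", "y"), B = c("x", "y")))
    expect_equal(same$count[same$subset == "A&B"], 2)
    expect_equal(sum(same$count), 2)
    for (seed in 1:10) {
        sets <- withr::with_seed(seed, lapply(1:3, function(i)
            sample(letters, sample(3:10, 1))))
        names(sets) <- c("s1", "s2", "s3")
        ov <- featureOverlap(sets)
        expect_equal(sum(ov$count),
                     length(unique(unlist(sets))))
        # element-wise membership oracle for one subset
        excl12 <- sum(vapply(unique(unlist(sets)), function(el)
            el %in% sets$s1 && el %in% sets$s2 && !el %in% sets$s3,
            logical(1)))
        expect_equal(ov$count[ov$subset == "s1&s2"], excl12)
    }
})

test_that("enrichment recovers an exactly matching term", {
    background <- sprintf("g%04d", 1:1000)
    lib <- list(hit = background[1:25],
                other = background[100:160],
                far = background[500:540])
    res <- enrich(background[1:25], lib, background)
    expect_equal(res$term[1], "hit")
    expect_lt(res$adjusted_p[1], 0.05)
    expect_equal(res$overlap_count[1], 25)
    expect_true(all(res$adjusted_p >= res$p_value - 1e-15))
    # genes in no term -> empty result
    none <- enrich(background[900:910], lib, background)
    expect_equal(nrow(none), 0)
    expect_error(enrich(character(0), lib, background), "empty query")
    expect_error(enrich("not_in_bg", lib, background), "background")
})

test_that("enrichment p-values equal the hypergeometric tail sum", {
    # fixed 2x2 from the spec of the statistic
    background <- sprintf("g%04d", 1:1000)
    lib <- list(t = background[1:10])
    q <- c(background[1:5], background[500:504])
    res <- enrich(q, lib, background, maxAdjustedP = 1)
    expect_equal(res$p_value, tailSumHyper(5, 10, 1000, 10),
                 tolerance = 1e-12)
    # random tables
    for (seed in 1:50) {
        par <- withr::with_seed(seed, {
            N <- sample(100:300, 1)
            K <- sample(5:30, 1)
            n <- sample(5:40, 1)
            k <- sample(0:min(K, n), 1)
            c(N = N, K = K, n = n, k = k)
        })
        N <- par[["N"]]; K <- par[["K"]]
        n <- par[["n"]]; k <- par[["k"]]
        bg <- paste0("b", seq_len(N))
        lb <- list(term = bg[seq_len(K)])
        extra <- if (n > k) bg[(K + 1):(K + n - k)] else character(0)
        r <- enrich(c(bg[seq_len(k)], extra), lb, bg,
                    maxAdjustedP = 1)
        expect_equal(r$p_value, tailSumHyper(k, K, N, n),
                     tolerance = 1e-9)
    }
    # monotone decreasing in overlap for fixed margins
    ps <- vapply(0:10, function(k) {
        bg <- paste0("b", 1:200)
        extra <- if (k < 10) bg[100:(109 - k)] else character(0)
        enrich(c(bg[seq_len(k)], extra), list(t = bg[1:10]), bg,
               maxAdjustedP = 1)$p_value
    }, numeric(1))
    expect_true(all(diff(ps) < 0))
})

test_that("annotation overlaps tolerate empty enrichment results", {
    ov <- annotationOverlap(list(a = c("t1", "t2"),
                                 b = character(0),
                                 c = c("t2", "t3")))
    expect_equal(ov$count[ov$subset == "b"], 0)
    expect_equal(ov$count[ov$subset == "a&c"], 1)  # t2
    expect_equal(sum(ov$count), 3)
    df <- data.frame(term = c("t1", "t2"), overlap_count = 1,
                     p_value = .01, adjusted_p = .02,
                     combined_score = 1)
    ov2 <- annotationOverlap(list(a = df, b = df))
    expect_equal(ov2$count[ov2$subset == "a&b"], 2)
})

test_that("runtime profiling returns results and elapsed seconds", {
    out <- runtimeProfile(function() {
        x <- sum(seq_len(1e5)); x
    })
    expect_gte(out$seconds, 0)
    expect_equal(out$value, sum(seq_len(1e5)))
})
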