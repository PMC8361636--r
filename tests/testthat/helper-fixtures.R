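# shared builders for small in-code fixtures

# deterministic labeled dataset: nGenes x nSamples Gaussian noise, the
# first nInformative genes shifted by `effect` in class2
makeLabeledDataset <- function(nGenes = 20, nSamples = 20, effect = 0,
                               nInformative = 0, seed = 1,
                               nClasses = 2) {
    withr::with_seed(seed, {
        classes <- paste0("c", seq_len(nClasses))
        labels <- rep(classes, length.out = nSamples)
        m <- matrix(rnorm(nGenes * nSamples), nGenes, nSamples,
                    dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                                    sprintf("s%03d", seq_len(nSamples))))
        if (nInformative > 0)
            for (j in seq_len(nInformative))
                m[j, ] <- m[j, ] + effect * (match(labels, classes) - 1)
        ExpressionDataset(m, labels = labels)
    })
}

# tiny association KB over explicit records
makeKb <- function(terms, genes, scores, name = "testkb") {
    AssociationKB(data.frame(term = terms, gene = genes,
                             score = scores), name = name)
}

# write a genes x samples matrix as the TSV dialect the loader reads
writeExpressionTsv <- function(m, path, transpose = FALSE) {
    if (transpose) {
        df <- data.frame(sample_id = colnames(m), t(m),
                         check.names = FALSE)
    } else {
        df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

# independent brute-force connectedness oracle working from raw member
# lists and edge tables (no igraph, no base::rank)
bruteConnectedness <- function(members, edges) {
    total <- numeric(0); count <- integer(0)
    for (p in names(members)) {
        mem <- members[[p]]
        e <- edges[edges$pathway == p, , drop = FALSE]
        deg <- vapply(mem, function(v)
            sum((e$gene_a == v | e$gene_b == v) &
                e$gene_a %in% mem & e$gene_b %in% mem &
                e$gene_a != e$gene_b), numeric(1))
        sorted <- sort(deg)
        pr <- vapply(deg, function(d) mean(which(sorted == d)),
                     numeric(1)) / length(mem)
        for (i in seq_along(mem)) {
            g <- mem[i]
            if (!g %in% names(total)) { total[g] <- 0; count[g] <- 0L }
            total[g] <- total[g] + pr[i]
            count[g] <- count[g] + 1L
        }
    }
    s <- total / count
    s[order(names(s))]
}

# random pathway collection (valid: unique simple edges over members)
randomNetworkFixture <- function(nPathways, maxNodes, seed) {
    withr::with_seed(seed, {
        members <- list(); edgeRows <- list()
        for (i in seq_len(nPathways)) {
            p <- sprintf("p%02d", i)
            n <- sample(2:maxNodes, 1)
            mem <- sprintf("P%d_n%02d", i, seq_len(n))
            nEdge <- sample(0:(n * (n - 1) / 2), 1)
            pairs <- t(combn(mem, 2))
            take <- sample(nrow(pairs), min(nEdge, nrow(pairs)))
            members[[p]] <- mem
            if (length(take))
                edgeRows[[p]] <- data.frame(pathway = p,
                    gene_a = pairs[take, 1], gene_b = pairs[take, 2],
                    stringsAsFactors = FALSE)
        }
        edges <- if (length(edgeRows)) do.call(rbind, edgeRows) else
            data.frame(pathway = character(), gene_a = character(),
                       gene_b = character())
        list(members = members, edges = edges)
    })
}

# textbook Kendall's W from an items x m matrix of ranks, with the
# standard tie correction
naiveKendallsW <- function(R) {
    m <- ncol(R); n <- nrow(R)
    Rsum <- rowSums(R)
    S <- sum((Rsum - mean(Rsum))^2)
    Tj <- apply(R, 2, function(r) { t <- table(r); sum(t^3 - t) })
    denom <- m^2 * (n^3 - n) - m * sum(Tj)
    if (denom <= 0) return(1)
    12 * S / denom
}

# hypergeometric upper-tail oracle by explicit summation
tailSumHyper <- function(k, K, N, n) {
    ks <- k:min(K, n)
    sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
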