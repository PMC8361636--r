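# internal helpers shared across modules

# package-level message with a common prefix; suppressible via
# suppressMessages() and redirected into run logs by the pipeline
.log <- function(...) message("[PKBench] ", ...)

# clip numeric values into [lo, hi]
.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# derive a child seed from a base seed; stays inside 32-bit range
.childSeed <- function(seed, offset) {
    (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) %% 1000L
}

# per-gene sample variance of a genes x samples matrix, NAs ignored
.rowVarsNA <- function(m) {
    obs <- !is.na(m)
    n <- rowSums(obs)
    m0 <- ifelse(obs, m, 0)
    mu <- rowSums(m0) / n
    ss <- rowSums(m0^2) - n * mu^2
    v <- ss / (n - 1)
    v[n < 2] <- NA_real_
    # numeric floor: sums of squares can go microscopically negative
    pmax(v, 0)
}

# vectorized one-way ANOVA F across the rows of a genes x samples
# matrix. Missing entries are ignored per gene. Genes where a class has
# no observation get NA; zero within-class variance with signal present
# is capped at a large finite F so downstream rankings stay finite.
.rowAnovaF <- function(m, labels) {
    labels <- as.factor(labels)
    k <- nlevels(labels)
    stopifnot(k >= 2L)
    G <- stats::model.matrix(~ labels - 1)        # samples x classes
    obs <- !is.na(m)
    m0 <- ifelse(obs, m, 0)
    ngc <- obs %*% G                              # genes x classes counts
    sgc <- m0 %*% G
    mgc <- sgc / ngc                              # NaN where ngc == 0
    n <- rowSums(ngc)
    grand <- rowSums(sgc) / n
    ssb <- rowSums(ngc * (mgc - grand)^2)
    sstot <- rowSums(m0^2) - n * grand^2
    ssw <- pmax(sstot - ssb, 0)
    f <- (ssb / (k - 1)) / (ssw / (n - k))
    f[rowSums(ngc == 0) > 0] <- NA_real_
    f[!is.na(f) & is.infinite(f)] <- 1e12
    f[is.nan(f)] <- 0                             # 0/0: constant gene
    f
}

# evaluate expr with a deterministic RNG state, restoring the caller's
.withSeed <- function(seed, expr) {
    withr::with_seed(as.integer(seed), expr)
}

# write a data.frame as TSV without row names (the package's standard
# output dialect)
.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Time a function invocation
#'
#' Runs a zero-argument function and records its wall-clock runtime.
#' Used by the benchmark driver to profile each feature selector.
#'
#' @param fn a function of no arguments.
#' @return A list with elements \code{value} (the function's result) and
#'   \code{seconds} (elapsed wall-clock time, a non-negative number).
#' @examples
#' runtimeProfile(function() sum(rnorm(10)))$seconds >= 0
#' @export
runtimeProfile <- function(fn) {
    stopifnot(is.function(fn))
    t0 <- proc.time()[["elapsed"]]
    value <- fn()
    list(value = value, seconds = max(proc.time()[["elapsed"]] - t0, 0))
}
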