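# Layered INI-style configuration: a complete main file plus an
# optional user file that overrides only the keys it names. The
# effective configuration is validated against a strict schema and
# snapshotted into every run directory.

# section -> known keys; unknown sections/keys are hard errors
.configSchema <- list(
    data = c("expression", "metadata", "sample_id_column",
             "label_attribute", "expression_b", "metadata_b",
             "mapping", "orientation"),
    preprocessing = c("max_missing_feature", "max_missing_sample"),
    knowledge = c("associations", "gmt", "edges", "terms", "min_score"),
    selection = c("selectors", "lambda", "k_stat", "k_kb",
                  "n_pathways", "n_permutations", "missing_policy",
                  "epsilon", "aggregation"),
    evaluation = c("classifiers", "cv_k", "sizes", "seed",
                   "enrichment_gmt", "cross_dataset", "top_n"),
    output = c("dir", "verbose"))

# minimal INI reader: [section] headers, key = value lines, comments
# with '#' or ';'
.readIni <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    out <- list()
    section <- NULL
    for (i in seq_along(lines)) {
        ln <- trimws(lines[i])
        if (!nzchar(ln) || startsWith(ln, "#") || startsWith(ln, ";"))
            next
        if (grepl("^\\[.+\\]$", ln)) {
            section <- sub("^\\[(.+)\\]$", "\\1", ln)
            if (is.null(out[[section]])) out[[section]] <- list()
            next
        }
        if (!grepl("=", ln, fixed = TRUE))
            stop(path, " line ", i, ": expected 'key = value'")
        if (is.null(section))
            stop(path, " line ", i, ": key outside any [section]")
        key <- trimws(sub("=.*$", "", ln))
        value <- trimws(sub("^[^=]*=", "", ln))
        out[[section]][[key]] <- value
    }
    out
}

.validateConfigKeys <- function(params, path) {
    for (sec in names(params)) {
        if (!sec %in% names(.configSchema))
            stop("unknown config section [", sec, "] in ", path)
        bad <- setdiff(names(params[[sec]]), .configSchema[[sec]])
        if (length(bad))
            stop("unknown config key(s) in [", sec, "]: ",
                 paste(bad, collapse = ", "), " (", path, ")")
    }
    invisible(params)
}

#' Load a layered benchmark configuration
#'
#' Reads the main configuration file (which carries every parameter the
#' benchmark needs) and overlays an optional user file that names only
#' the parameters to overwrite, key by key. Both files are validated
#' against a strict schema: unknown sections or keys are errors that
#' name the offending key. Required inputs (expression, metadata, label
#' attribute, selectors) and the resolvability of every referenced path
#' are checked on the effective configuration.
#'
#' @param defaultPath path to the main INI file.
#' @param userPath optional path to the user's override INI.
#' @return A \code{BenchmarkConfig} object (classed list of sections).
#' @seealso [configParam()], [runBenchmark()]
#' @export
loadConfig <- function(defaultPath, userPath = NULL) {
    params <- .validateConfigKeys(.readIni(defaultPath), defaultPath)
    if (!is.null(userPath)) {
        user <- .validateConfigKeys(.readIni(userPath), userPath)
        for (sec in names(user))
            for (key in names(user[[sec]]))
                params[[sec]][[key]] <- user[[sec]][[key]]
    }
    cfg <- structure(list(params = params), class = "BenchmarkConfig")
    .validateConfig(cfg)
    cfg
}

#' Read one effective configuration value
#'
#' @param cfg a \code{BenchmarkConfig}.
#' @param section,key the parameter address.
#' @param default value returned when the key is unset or empty.
#' @return The parameter as a string, or \code{default}.
#' @export
configParam <- function(cfg, section, key, default = NULL) {
    v <- cfg$params[[section]][[key]]
    if (is.null(v) || !nzchar(v)) default else v
}

# list-valued parameter (comma separated)
.configList <- function(cfg, section, key, default = character()) {
    v <- configParam(cfg, section, key)
    if (is.null(v)) return(default)
    trimws(strsplit(v, ",", fixed = TRUE)[[1L]])
}

# integer range parameter: "1:20" or a comma list
.configSizes <- function(cfg, default = 1:20) {
    v <- configParam(cfg, "evaluation", "sizes")
    if (is.null(v)) return(default)
    if (grepl(":", v, fixed = TRUE)) {
        ab <- as.integer(strsplit(v, ":", fixed = TRUE)[[1L]])
        return(seq(ab[1L], ab[2L]))
    }
    as.integer(trimws(strsplit(v, ",", fixed = TRUE)[[1L]]))
}

.configNum <- function(cfg, section, key, default) {
    v <- configParam(cfg, section, key)
    if (is.null(v)) default else as.numeric(v)
}

.validateConfig <- function(cfg) {
    req <- list(c("data", "expression"), c("data", "metadata"),
                c("data", "sample_id_column"),
                c("data", "label_attribute"),
                c("selection", "selectors"))
    for (r in req)
        if (is.null(configParam(cfg, r[1L], r[2L])))
            stop("required config parameter missing: [", r[1L], "] ",
                 r[2L])
    pathKeys <- list(c("data", "expression"), c("data", "metadata"),
                     c("data", "expression_b"), c("data", "metadata_b"),
                     c("data", "mapping"), c("knowledge", "associations"),
                     c("knowledge", "gmt"), c("knowledge", "edges"),
                     c("evaluation", "enrichment_gmt"))
    for (pk in pathKeys) {
        p <- configParam(cfg, pk[1L], pk[2L])
        if (!is.null(p) && !file.exists(p))
            stop("configured path does not exist: [", pk[1L], "] ",
                 pk[2L], " = ", p)
    }
    selectors <- .configList(cfg, "selection", "selectors")
    bad <- setdiff(selectors, listSelectors())
    if (length(bad))
        stop("unregistered selector(s) in config: ",
             paste(bad, collapse = ", "))
    clfs <- .configList(cfg, "evaluation", "classifiers",
                        listClassifiers())
    badc <- setdiff(clfs, listClassifiers())
    if (length(badc))
        stop("unregistered classifier(s) in config: ",
             paste(badc, collapse = ", "))
    invisible(cfg)
}

# write the effective configuration back out as INI
.writeConfigSnapshot <- function(cfg, path) {
    lines <- character()
    for (sec in names(cfg$params)) {
        lines <- c(lines, paste0("[", sec, "]"))
        for (key in names(cfg$params[[sec]]))
            lines <- c(lines,
                       paste0(key, " = ", cfg$params[[sec]][[key]]))
        lines <- c(lines, "")
    }
    writeLines(lines, path)
    invisible(path)
}
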