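.onLoad <- function(libname, pkgname) {
    # populate the registries with the built-in components; guard
    # against double-registration when the namespace is reloaded
    .registries$classifiers <- list()
    .registries$selectors <- list()
    for (nm in names(.builtinClassifiers()))
        registerClassifier(nm, .builtinClassifiers()[[nm]])
    for (nm in names(.builtinSelectors())) {
        s <- .builtinSelectors()[[nm]]
        registerSelector(nm, s$factory, s$type)
    }
    invisible()
}
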