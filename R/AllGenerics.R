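#' @rdname MetaboSet-accessors
#' @export
setGeneric("concentrations", function(x, ...) standardGeneric("concentrations"))

#' @rdname MetaboSet-accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname MetaboSet-accessors
#' @export
setGeneric("outcome", function(x) standardGeneric("outcome"))

#' @rdname MetaboSet-accessors
#' @export
setGeneric("outcome<-", function(x, value) standardGeneric("outcome<-"))

#' @rdname MetaboSet-accessors
#' @export
setGeneric("scaleState", function(x) standardGeneric("scaleState"))

#' @rdname MetaboSet-accessors
#' @export
setGeneric("metaboliteNames", function(x) standardGeneric("metaboliteNames"))

#' @rdname MetaboSet-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname MetaboSet-accessors
#' @export
setGeneric("trueValues", function(x) standardGeneric("trueValues"))

#' @rdname PosteriorSummary-accessors
#' @export
setGeneric("posteriorSummary", function(x) standardGeneric("posteriorSummary"))

#' @rdname PosteriorSummary-accessors
#' @export
setGeneric("betaDraws", function(x) standardGeneric("betaDraws"))

#' @rdname PosteriorSummary-accessors
#' @export
setGeneric("hyperParams", function(x) standardGeneric("hyperParams"))

#' @rdname PosteriorSummary-accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname ImputationPosterior-accessors
#' @export
setGeneric("imputedMeans", function(x) standardGeneric("imputedMeans"))

#' @rdname ImputationPosterior-accessors
#' @export
setGeneric("imputedSds", function(x) standardGeneric("imputedSds"))

#' @rdname ImputationPosterior-accessors
#' @export
setGeneric("censorLimits", function(x) standardGeneric("censorLimits"))
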