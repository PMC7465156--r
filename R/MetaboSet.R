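#' Construct a MetaboSet
#'
#' @param values numeric matrix of concentrations, samples in rows and
#'   metabolites in columns (the conventional table orientation). `NA`
#'   marks a missing (censored) cell.
#' @param outcome integer/numeric vector of 0/1 outcome labels, one per
#'   sample (1 = event, e.g. non-survivor).
#' @param sampleIds,metaboliteNames optional character vectors; default to
#'   the dimnames of `values` or generated labels.
#' @param scaleState one of `"raw"`, `"log"`, `"log_zscaled"`.
#' @param trueValues optional complete samples-by-metabolites matrix of the
#'   values before censoring (simulation bookkeeping).
#'
#' @return a [MetaboSet-class] object.
#' @examples
#' x <- matrix(rlnorm(20), 5, 4)
#' ms <- MetaboSet(x, outcome = c(0, 0, 1, 1, 0))
#' dim(concentrations(ms))
#' @export
MetaboSet <- function(values, outcome,
                      sampleIds = rownames(values),
                      metaboliteNames = colnames(values),
                      scaleState = c("raw", "log", "log_zscaled"),
                      trueValues = NULL) {
  scaleState <- match.arg(scaleState)
  values <- as.matrix(values)
  if (length(outcome) != nrow(values))
    stop("need one outcome label per sample (row of 'values')")
  if (is.null(sampleIds)) sampleIds <- paste0("sample", seq_len(nrow(values)))
  if (is.null(metaboliteNames))
    metaboliteNames <- paste0("met", seq_len(ncol(values)))
  if (anyDuplicated(metaboliteNames))
    stop("duplicate metabolite names: ",
         paste(unique(metaboliteNames[duplicated(metaboliteNames)]),
               collapse = ", "))
  a <- t(values)
  dimnames(a) <- list(metaboliteNames, sampleIds)
  assays <- list(concentrations = a)
  if (!is.null(trueValues)) {
    tv <- t(as.matrix(trueValues))
    dimnames(tv) <- dimnames(a)
    assays$trueValues <- tv
  }
  se <- SummarizedExperiment(
    assays = assays,
    colData = DataFrame(outcome = as.integer(outcome), row.names = sampleIds))
  metadata(se)$scaleState <- scaleState
  new("MetaboSet", se)
}

#' Accessors for MetaboSet objects
#'
#' `concentrations()` returns the samples-by-metabolites concentration
#' matrix (with `NA` at missing cells); `missingMask()` the logical missing
#' indicator of the same shape; `outcome()` the 0/1 labels; `scaleState()`
#' the preprocessing stage; `trueValues()` the pre-censoring matrix for
#' simulated data (or `NULL`).
#'
#' @param x a [MetaboSet-class].
#' @param ... unused.
#' @param value replacement outcome labels.
#' @name MetaboSet-accessors
NULL

#' @rdname MetaboSet-accessors
#' @export
setMethod("concentrations", "MetaboSet", function(x, ...)
  t(assay(x, "concentrations")))

#' @rdname MetaboSet-accessors
#' @export
setMethod("missingMask", "MetaboSet", function(x)
  is.na(t(assay(x, "concentrations"))))

#' @rdname MetaboSet-accessors
#' @export
setMethod("outcome", "MetaboSet", function(x) {
  y <- colData(x)$outcome
  names(y) <- colnames(x)
  y
})

#' @rdname MetaboSet-accessors
#' @export
setReplaceMethod("outcome", "MetaboSet", function(x, value) {
  colData(x)$outcome <- as.integer(value)
  validObject(x)
  x
})

#' @rdname MetaboSet-accessors
#' @export
setMethod("scaleState", "MetaboSet", function(x) metadata(x)$scaleState)

#' @rdname MetaboSet-accessors
#' @export
setMethod("metaboliteNames", "MetaboSet", function(x) rownames(x))

#' @rdname MetaboSet-accessors
#' @export
setMethod("sampleIds", "MetaboSet", function(x) colnames(x))

#' @rdname MetaboSet-accessors
#' @export
setMethod("trueValues", "MetaboSet", function(x) {
  if ("trueValues" %in% assayNames(x)) t(assay(x, "trueValues")) else NULL
})

setMethod("show", "MetaboSet", function(object) {
  v <- assay(object, "concentrations")
  cat("MetaboSet:", nrow(object), "metabolites x", ncol(object), "samples\n")
  cat("  scale:", scaleState(object),
      "| missing:", sprintf("%.1f%%", 100 * mean(is.na(v))),
      "| outcome events:", sum(colData(object)$outcome), "/",
      ncol(object), "\n")
  if ("trueValues" %in% assayNames(object))
    cat("  carries hidden true values (simulated, censored)\n")
})

#' Per-metabolite missing rates
#'
#' Column means of the missing indicator, one rate per metabolite.
#'
#' @param x a [MetaboSet-class].
#' @return named numeric vector of fractions in \eqn{[0, 1]}.
#' @export
missingRates <- function(x) {
  stopifnot(is(x, "MetaboSet"))
  colMeans(missingMask(x))
}
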