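#' Read a concentration table from CSV/TSV
#'
#' Expects a header row, a sample-identifier column (by default the first
#' column), a named binary outcome column, and numeric metabolite columns.
#' Blank cells, `NA`, `NaN` and zeros are treated as missing: a
#' concentration of exactly 0 is below any detection limit and has no
#' finite log-transform, so it is interpreted as a censored cell.
#'
#' @param path file path.
#' @param outcomeColumn name of the 0/1 outcome column.
#' @param dialect `"csv"` or `"tsv"`; guessed from the file extension by
#'   default.
#' @param idColumn name of the sample-ID column; defaults to the first
#'   column of the file.
#' @return a [MetaboSet-class] with `scaleState = "raw"`.
#' @export
readConcentrationTable <- function(path, outcomeColumn,
                                   dialect = c("guess", "csv", "tsv"),
                                   idColumn = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "guess")
    dialect <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE))
      "tsv" else "csv"
  sep <- if (dialect == "tsv") "\t" else ","
  header <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  if (anyDuplicated(header))
    stop("duplicate metabolite names in header: ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA", "NaN"))
  if (is.null(idColumn)) idColumn <- names(df)[1]
  if (!outcomeColumn %in% names(df))
    stop("outcome column '", outcomeColumn, "' not found")
  y <- df[[outcomeColumn]]
  if (!all(stats::na.omit(y) %in% c(0, 1)) || anyNA(y))
    stop("outcome column must contain only 0/1 values")
  ids <- as.character(df[[idColumn]])
  metCols <- setdiff(names(df), c(idColumn, outcomeColumn))
  if (anyDuplicated(metCols))
    stop("duplicate metabolite names in header")
  vals <- as.matrix(df[metCols])
  if (!is.numeric(vals)) stop("metabolite columns must be numeric")
  vals[!is.na(vals) & vals == 0] <- NA  # 0 = below detection, censored
  allMiss <- colSums(!is.na(vals)) == 0
  if (any(allMiss))
    warning("metabolite(s) with all values missing retained: ",
            paste(metCols[allMiss], collapse = ", "))
  MetaboSet(vals, outcome = y, sampleIds = ids, metaboliteNames = metCols,
            scaleState = "raw")
}

#' Write a MetaboSet back to CSV/TSV
#'
#' Inverse of [readConcentrationTable()]: sample IDs in the first column,
#' the outcome in a named column, missing cells written as empty fields.
#'
#' @param x a [MetaboSet-class].
#' @param path output file path.
#' @param outcomeColumn header for the outcome column.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeConcentrationTable <- function(x, path, outcomeColumn = "outcome",
                                    dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(is(x, "MetaboSet"))
  df <- data.frame(sample_id = sampleIds(x), check.names = FALSE)
  df[[outcomeColumn]] <- unname(outcome(x))
  df <- cbind(df, as.data.frame(concentrations(x), check.names = FALSE))
  utils::write.table(df, path, sep = if (dialect == "tsv") "\t" else ",",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Filter, log-transform and autoscale a raw concentration table
#'
#' Applies the standard preprocessing pipeline: metabolites whose missing
#' rate is at or above `missingThreshold` are dropped (kept only if rate
#' is strictly below the threshold); observed concentrations are
#' natural-log transformed; each metabolite is then centred and scaled to
#' unit standard deviation over its observed entries. Missing cells stay
#' missing. The per-metabolite log-scale mean and sd are stored in
#' `rowData` (`logMean`, `logSd`) so that later steps (e.g. naive min/2
#' imputation) can map concentrations through the same transform.
#'
#' @param x a raw-scale [MetaboSet-class] with all observed values > 0.
#' @param missingThreshold keep metabolites with missing rate strictly
#'   below this fraction (default 0.3).
#' @return a [MetaboSet-class] with `scaleState = "log_zscaled"`.
#' @export
preprocess <- function(x, missingThreshold = 0.3) {
  stopifnot(is(x, "MetaboSet"))
  if (scaleState(x) != "raw")
    stop("preprocess() expects raw-scale data; got scale_state '",
         scaleState(x), "'")
  stopifnot(missingThreshold >= 0, missingThreshold <= 1)
  v <- concentrations(x)
  bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "non-positive observed concentration at sample '%s', metabolite '%s'",
      rownames(v)[bad[1, 1]] %||% bad[1, 1],
      colnames(v)[bad[1, 2]] %||% bad[1, 2]))
  keep <- missingRates(x) < missingThreshold
  if (!any(keep)) stop("all metabolites exceed the missing-rate threshold")
  v <- v[, keep, drop = FALSE]
  lg <- log(v)
  mu <- colMeans(lg, na.rm = TRUE)
  sd <- apply(lg, 2, stats::sd, na.rm = TRUE)
  if (any(!is.na(sd) & sd == 0))
    stop("constant-valued metabolite (zero sd): ",
         paste(colnames(v)[!is.na(sd) & sd == 0], collapse = ", "))
  z <- sweep(sweep(lg, 2, mu), 2, sd, `/`)
  out <- MetaboSet(z, outcome = unname(outcome(x)),
                   sampleIds = sampleIds(x),
                   metaboliteNames = colnames(v),
                   scaleState = "log_zscaled")
  rowData(out)$logMean <- unname(mu)
  rowData(out)$logSd <- unname(sd)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
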