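.bayesScenarios <- list(
  bayes_learned = quote(learnedPrior()),
  bayes_nu1 = quote(fixedNuPrior(1)),
  bayes_weak = quote(weaklyInformativePrior(100, 5)),
  bayes_bounded = quote(sigmaBoundedPrior(0.1)))

.allModels <- c("bayes_learned", "bayes_nu1", "bayes_weak", "bayes_bounded",
                "freq_raw", "freq_bonferroni", "freq_bh")

#' Run one simulation replicate through all decision procedures
#'
#' Draws a single synthetic dataset under the scenario, assigns truth,
#' injects left-censored missingness when the average missing rate is
#' positive, fits every requested model on the same dataset — the Bayesian
#' models through the two-stage soft-imputation path when missing data are
#' present, the frequentist baselines on naive min/2-imputed data — and
#' scores each against the truth (power, FDR, AER).
#'
#' @param cfg a [SimulationConfig-class].
#' @param params a [ClassParams-class].
#' @param models subset of `bayes_learned`, `bayes_nu1`, `bayes_weak`,
#'   `bayes_bounded`, `freq_raw`, `freq_bonferroni`, `freq_bh`.
#' @param control a [McmcControl-class] for the Bayesian fits.
#' @param marginalBeta precomputed [marginalTrueBeta()] vector; computed
#'   on the fly (slow) when `NULL`.
#' @param referenceRates reference missing-rate distribution for the beta
#'   model (default the packaged synthetic panel rates).
#' @param cImpute number of predictor metabolites in stage 1.
#' @param seed optional integer; when given, `set.seed(seed)` makes the
#'   replicate fully reproducible.
#' @param alpha frequentist decision threshold.
#' @return a data frame with one row per model: confusion counts, power,
#'   FDR, AER, and a convergence flag.
#' @export
runReplicate <- function(cfg, params,
                         models = c("bayes_learned", "freq_raw",
                                    "freq_bonferroni", "freq_bh"),
                         control = mcmcControl(), marginalBeta = NULL,
                         referenceRates = syntheticMissingRates(
                           length(params@muD)),
                         cImpute = 8, seed = NULL, alpha = 0.05) {
  stopifnot(is(cfg, "SimulationConfig"), is(params, "ClassParams"))
  models <- match.arg(models, .allModels, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  m <- length(params@muD)
  truth <- assignTruth(params, cfg@fractionSignificant, cfg@nPerGroup)
  truth <- oracleTrueBeta(truth, params, marginalBeta = marginalBeta)
  ds <- generateDataset(truth, params, cfg@nPerGroup)
  r <- cfg@averageMissingRate
  dsm <- if (r > 0) {
    mm <- buildMissingness(referenceRates, r, cfg@maxMissingRate, m)
    injectMissingness(ds, mm)
  } else ds
  tdiff <- truth@trulyDifferent
  rows <- list()
  score <- function(model, predicted, estimates, converged) {
    ev <- evaluateClassification(predicted, tdiff)
    ev$aer <- aer(estimates, truth@trueBeta, predicted, tdiff)
    cbind(data.frame(model = model), ev,
          data.frame(converged = converged))
  }
  freqModels <- intersect(models, c("freq_raw", "freq_bonferroni", "freq_bh"))
  if (length(freqModels) > 0) {
    fr <- fitUnivariateLogistic(naiveImpute(dsm), alpha = alpha)
    flagOf <- list(freq_raw = fr$sigRaw, freq_bonferroni = fr$sigBonferroni,
                   freq_bh = fr$sigBH)
    for (mod in freqModels)
      rows[[mod]] <- score(mod, flagOf[[mod]], fr$beta, TRUE)
  }
  bayesModels <- intersect(models, names(.bayesScenarios))
  if (length(bayesModels) > 0) {
    ip <- if (r > 0 && anyNA(concentrations(dsm)))
      fitCensoredImputation(dsm, c = cImpute, control = control) else NULL
    for (mod in bayesModels) {
      scen <- eval(.bayesScenarios[[mod]])
      ps <- if (is.null(ip)) fitMultilevelLogistic(ds, scen, control)
            else fitLogisticWithUncertainty(dsm, ip, scen, control)
      rows[[mod]] <- score(mod, classifySignificant(ps),
                           posteriorSummary(ps)$betaMean, isConverged(ps))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$nPerGroup <- cfg@nPerGroup
  out$fractionSignificant <- cfg@fractionSignificant
  out$averageMissingRate <- r
  out
}

#' Run a scenario grid of replicated simulations
#'
#' Runs `nSimulations` replicates (or `replicates`, if supplied) for every
#' scenario in `configs`, with replicate seeds derived deterministically
#' from `seed`, and aggregates power/FDR/AER per scenario and model
#' (means over replicates; AER averaged over replicates where it is
#' defined). Failed replicates are recorded with an error message and the
#' grid continues.
#'
#' @param configs list of [SimulationConfig-class] scenarios.
#' @param params a [ClassParams-class] (default the packaged synthetic
#'   panel).
#' @param models model set, as in [runReplicate()].
#' @param replicates optional override of each config's `nSimulations`.
#' @param seed global seed for the grid.
#' @param control a [McmcControl-class].
#' @param oracleN Monte-Carlo size for the true-effect oracle (computed
#'   once for the grid).
#' @param outDir optional directory; per-replicate and aggregate CSVs are
#'   written there.
#' @param ... passed on to [runReplicate()].
#' @return list with `replicates` (long data frame, one row per scenario
#'   x model x replicate) and `aggregate` (scenario x model means).
#' @export
runGrid <- function(configs, params = syntheticClassParams(),
                    models = c("bayes_learned", "freq_raw",
                               "freq_bonferroni", "freq_bh"),
                    replicates = NULL, seed = 1, control = mcmcControl(),
                    oracleN = 1e6, outDir = NULL, ...) {
  if (is(configs, "SimulationConfig")) configs <- list(configs)
  set.seed(seed)
  marginalBeta <- marginalTrueBeta(params, oracleN)
  nrep <- vapply(configs, function(cf)
    if (is.null(replicates)) cf@nSimulations else as.integer(replicates),
    integer(1))
  seedTab <- matrix(sample.int(2^31 - 2, sum(nrep)), nrow = max(nrep))
  allRows <- list()
  for (s in seq_along(configs)) {
    cfg <- configs[[s]]
    for (rep in seq_len(nrep[s])) {
      repSeed <- seedTab[rep, s]
      row <- tryCatch(
        runReplicate(cfg, params, models = models, control = control,
                     marginalBeta = marginalBeta, seed = repSeed, ...),
        error = function(e) data.frame(
          model = models, TP = NA, FP = NA, FN = NA, TN = NA,
          power = NA, fdr = NA, aer = NA, converged = FALSE,
          nPerGroup = cfg@nPerGroup,
          fractionSignificant = cfg@fractionSignificant,
          averageMissingRate = cfg@averageMissingRate,
          error = conditionMessage(e)))
      if (is.null(row$error)) row$error <- NA_character_
      row$scenario <- s
      row$replicate <- rep
      row$seed <- repSeed
      allRows[[length(allRows) + 1]] <- row
    }
  }
  rep_df <- do.call(rbind, allRows)
  agg <- stats::aggregate(
    cbind(power, fdr) ~ scenario + model + nPerGroup +
      fractionSignificant + averageMissingRate,
    data = rep_df, FUN = mean, na.action = stats::na.pass,
    na.rm = TRUE)
  aerAgg <- stats::aggregate(
    aer ~ scenario + model, data = rep_df,
    FUN = function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE),
    na.action = stats::na.pass)
  agg <- merge(agg, aerAgg, by = c("scenario", "model"), sort = FALSE)
  agg <- agg[order(agg$scenario, agg$model), ]
  rownames(agg) <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(rep_df, file.path(outDir, "replicates.csv"),
                     row.names = FALSE)
    utils::write.csv(agg, file.path(outDir, "aggregate.csv"),
                     row.names = FALSE)
  }
  list(replicates = rep_df, aggregate = agg)
}

#' Plot metric curves across scenarios
#'
#' Line plots of power, FDR and AER against a scenario axis (sample size
#' or missing rate), one line per model. Requires ggplot2.
#'
#' @param aggregate the `aggregate` table from [runGrid()].
#' @param xvar scenario axis: `"nPerGroup"` or `"averageMissingRate"`.
#' @return a ggplot object.
#' @export
plotMetricCurves <- function(aggregate,
                             xvar = c("nPerGroup", "averageMissingRate")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  xvar <- match.arg(xvar)
  long <- do.call(rbind, lapply(c("power", "fdr", "aer"), function(met)
    data.frame(x = aggregate[[xvar]], model = aggregate$model,
               metric = met, value = aggregate[[met]])))
  ggplot2::ggplot(long, ggplot2::aes(x = x, y = value, colour = model)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = xvar, y = NULL)
}
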