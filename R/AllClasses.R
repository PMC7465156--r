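#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames assay<- rowData rowData<- colData colData<-
NULL

#' MetaboSet: a two-group metabolomics concentration experiment
#'
#' `MetaboSet` extends [SummarizedExperiment::SummarizedExperiment] and holds
#' a metabolites-by-samples concentration matrix (assay `"concentrations"`,
#' with `NA` marking missing cells), a binary outcome label per sample
#' (column data `outcome`, 1 = event such as death), and a `scaleState`
#' metadata flag recording the preprocessing stage: `"raw"` (positive
#' concentrations), `"log"` or `"log_zscaled"` (natural-log transformed and
#' per-metabolite autoscaled over observed entries).
#'
#' Simulated data sets may carry a second assay, `"trueValues"`, holding the
#' complete matrix before left-censoring so that imputation quality can be
#' scored against the hidden truth.
#'
#' User-facing accessors ([concentrations()], [missingMask()],
#' [trueValues()]) return matrices in the conventional table orientation,
#' samples in rows and metabolites in columns; internal storage follows the
#' SummarizedExperiment convention (features in rows).
#'
#' @name MetaboSet-class
#' @aliases MetaboSet-class
#' @exportClass MetaboSet
setClass("MetaboSet", contains = "SummarizedExperiment")

setValidity("MetaboSet", function(object) {
  msg <- NULL
  if (!"concentrations" %in% assayNames(object))
    msg <- c(msg, "assay 'concentrations' is required")
  y <- colData(object)$outcome
  if (is.null(y)) {
    msg <- c(msg, "colData must contain an 'outcome' column")
  } else if (!all(y %in% c(0L, 1L))) {
    msg <- c(msg, "outcome labels must all be 0 or 1")
  }
  st <- metadata(object)$scaleState
  if (is.null(st) || !st %in% c("raw", "log", "log_zscaled"))
    msg <- c(msg, "metadata scaleState must be 'raw', 'log' or 'log_zscaled'")
  v <- assay(object, "concentrations")
  if (any(!is.finite(v) & !is.na(v)))
    msg <- c(msg, "concentrations must be finite wherever observed")
  if (is.null(msg)) TRUE else msg
})

#' Class-conditional Gaussian parameters learned from a reference data set
#'
#' Per-class mean vector and covariance matrix of the log-z-scaled
#' concentrations, with the group sizes used for learning. Class "D"
#' is the event group (e.g., non-survivors), class "S" the non-event group.
#'
#' @slot muD,muS numeric mean vectors (length m, z-scale units).
#' @slot SigmaD,SigmaS m-by-m covariance matrices (symmetric PSD).
#' @slot nD,nS integer group sizes.
#' @exportClass ClassParams
setClass("ClassParams",
  representation(muD = "numeric", SigmaD = "matrix",
                 muS = "numeric", SigmaS = "matrix",
                 nD = "integer", nS = "integer"))

setValidity("ClassParams", function(object) {
  m <- length(object@muD)
  msg <- NULL
  if (length(object@muS) != m) msg <- c(msg, "muD and muS lengths differ")
  for (nm in c("SigmaD", "SigmaS")) {
    S <- slot(object, nm)
    if (!all(dim(S) == c(m, m)))
      msg <- c(msg, sprintf("%s must be %d x %d", nm, m, m))
    else if (max(abs(S - t(S))) > 1e-8)
      msg <- c(msg, sprintf("%s must be symmetric", nm))
    else if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <
             -1e-8 * max(1, max(abs(S))))
      msg <- c(msg, sprintf("%s must be positive semi-definite", nm))
  }
  if (object@nD < 2L || object@nS < 2L)
    msg <- c(msg, "each class needs at least 2 samples")
  if (is.null(msg)) TRUE else msg
})

#' Ground-truth assignment for one simulated scenario
#'
#' Flags the metabolites simulated to be truly different between outcome
#' classes, carries the truth-modified class means (zeroed where a
#' metabolite was not selected), the selection probabilities derived from
#' the absolute Welch t-statistic, and the oracle true log-odds effect size
#' per metabolite (0 for non-selected metabolites, NA until computed by
#' [oracleTrueBeta()]).
#'
#' @exportClass TruthAssignment
setClass("TruthAssignment",
  representation(trulyDifferent = "logical",
                 muDHat = "numeric", muSHat = "numeric",
                 trueBeta = "numeric", selectionProbs = "numeric"))

setValidity("TruthAssignment", function(object) {
  m <- length(object@trulyDifferent)
  msg <- NULL
  if (length(object@muDHat) != m || length(object@muSHat) != m ||
      length(object@trueBeta) != m || length(object@selectionProbs) != m)
    msg <- c(msg, "all slots must have equal length")
  ns <- !object@trulyDifferent
  if (any(object@muDHat[ns] != 0) || any(object@muSHat[ns] != 0))
    msg <- c(msg, "non-selected metabolites must have zero modified means")
  tb <- object@trueBeta[ns]
  if (any(!is.na(tb) & tb != 0))
    msg <- c(msg, "non-selected metabolites must have trueBeta 0")
  if (abs(sum(object@selectionProbs) - 1) > 1e-8)
    msg <- c(msg, "selectionProbs must sum to 1")
  if (is.null(msg)) TRUE else msg
})

#' Beta-distributed per-metabolite missing-rate model
#'
#' Holds the reference beta moments fitted to the missing-rate distribution
#' of a real data set, the moments rescaled to a target average missing
#' rate, the implied beta shape parameters, and the realized per-metabolite
#' rates (truncated at `maxRate`).
#'
#' @exportClass MissingnessModel
setClass("MissingnessModel",
  representation(targetRate = "numeric", maxRate = "numeric",
                 refMean = "numeric", refVar = "numeric",
                 shape1 = "numeric", shape2 = "numeric",
                 rates = "numeric"))

setValidity("MissingnessModel", function(object) {
  msg <- NULL
  if (any(object@rates < 0) || any(object@rates > object@maxRate + 1e-12))
    msg <- c(msg, "rates must lie in [0, maxRate]")
  if (is.null(msg)) TRUE else msg
})

#' One simulated-study scenario
#'
#' Bundles the five simulation parameters: number of replicate data sets,
#' samples per outcome group, fraction of metabolites truly different,
#' average missing rate (mean of the rescaled beta distribution), and the
#' maximum (truncation) missing rate.
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(nSimulations = "integer", nPerGroup = "integer",
                 fractionSignificant = "numeric",
                 averageMissingRate = "numeric", maxMissingRate = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- NULL
  fr <- c(object@fractionSignificant, object@averageMissingRate,
          object@maxMissingRate)
  if (any(fr < 0) || any(fr > 1)) msg <- c(msg, "fractions must lie in [0,1]")
  if (object@nPerGroup < 2L) msg <- c(msg, "nPerGroup must be >= 2")
  if (object@nSimulations < 1L) msg <- c(msg, "nSimulations must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Prior scenario for the hierarchical effect-size prior
#'
#' The shared prior over metabolite log-odds coefficients is a
#' t-distribution centred at zero with degrees of freedom `nu` and scale
#' `sigma`. Four scenarios are supported: `"learned"` (both hyperparameters
#' inferred), `"nu_fixed"` (`nu` held fixed, `sigma` learned),
#' `"weakly_informative"` (both fixed; with large `nu` and `sigma` the model
#' collapses to independent near-flat-prior regressions), and
#' `"sigma_lower_bound"` (both learned, but `sigma` bounded below to limit
#' over-shrinkage).
#'
#' @exportClass PriorScenario
setClass("PriorScenario",
  representation(mode = "character", nu = "numeric", sigma = "numeric",
                 sigmaLowerBound = "numeric"))

setValidity("PriorScenario", function(object) {
  msg <- NULL
  if (!object@mode %in% c("learned", "nu_fixed", "weakly_informative",
                          "sigma_lower_bound"))
    msg <- c(msg, "unknown prior scenario mode")
  if (!is.na(object@nu) && object@nu < 1) msg <- c(msg, "nu must be >= 1")
  if (!is.na(object@sigma) && object@sigma <= 0)
    msg <- c(msg, "sigma must be > 0")
  if (object@sigmaLowerBound < 0) msg <- c(msg, "sigmaLowerBound must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' MCMC sampler settings
#'
#' @slot chains number of chains (>= 2 so convergence can be diagnosed).
#' @slot adapt,burnin adaptation and additional burn-in iterations.
#' @slot iter retained sampling iterations per chain.
#' @slot maxRhat convergence threshold on the potential scale reduction
#'   factor; fits exceeding it are flagged non-converged.
#' @slot minEss minimum pooled effective sample size before flagging.
#' @exportClass McmcControl
setClass("McmcControl",
  representation(chains = "integer", adapt = "integer", burnin = "integer",
                 iter = "integer", maxRhat = "numeric", minEss = "numeric"))

setValidity("McmcControl", function(object) {
  msg <- NULL
  if (object@chains < 2L) msg <- c(msg, "at least 2 chains required")
  if (object@iter < 100L) msg <- c(msg, "iter must be >= 100")
  if (is.null(msg)) TRUE else msg
})

#' Posterior summary of the hierarchical logistic regression
#'
#' Per-metabolite posterior summaries of the log-odds coefficients
#' (mean, sd, tail probabilities, central 95% credible interval,
#' significance flag) plus intercept means, posterior means of the prior
#' hyperparameters, retained coefficient draws, and convergence
#' diagnostics.
#'
#' @exportClass PosteriorSummary
setClass("PosteriorSummary",
  representation(summary = "data.frame", hyper = "numeric",
                 betaDraws = "matrix", hyperDraws = "matrix",
                 scenario = "PriorScenario",
                 diagnostics = "data.frame", converged = "logical"))

#' Posterior of the left-censored imputation model
#'
#' For every missing cell, the posterior mean `E` and standard deviation
#' `S` of the latent (below-threshold) concentration, the per-metabolite
#' censoring thresholds, and the predictor sets used (indices of the `c`
#' most-correlated metabolites). `E` and `S` are samples-by-metabolites
#' matrices, defined (non-NA) exactly where the input was missing.
#'
#' @exportClass ImputationPosterior
setClass("ImputationPosterior",
  representation(E = "matrix", S = "matrix", thresholds = "numeric",
                 predictorSets = "matrix", c = "integer",
                 latentDraws = "matrix",
                 diagnostics = "data.frame", converged = "logical"))

setValidity("ImputationPosterior", function(object) {
  msg <- NULL
  if (!identical(dim(object@E), dim(object@S)))
    msg <- c(msg, "E and S must have equal dimensions")
  s <- object@S[!is.na(object@S)]
  if (any(s <= 0)) msg <- c(msg, "posterior sds must be positive")
  def <- !is.na(object@E)
  if (any(is.na(object@S[def])))
    msg <- c(msg, "E and S must be defined on the same cells")
  if (length(def) > 0 && any(def)) {
    tmat <- matrix(object@thresholds, nrow(object@E), ncol(object@E),
                   byrow = TRUE)
    if (any(object@E[def] > tmat[def] + 1e-8))
      msg <- c(msg, "posterior means must not exceed censoring thresholds")
  }
  if (is.null(msg)) TRUE else msg
})

#' Bayesian shrinkage-slope comparison
#'
#' Posterior of the slope from a flat-prior Bayesian simple linear
#' regression of hierarchical-model effect sizes on frequentist MLEs.
#' A slope below 1 evidences shrinkage of the Bayesian estimates.
#'
#' @exportClass SlopeComparison
setClass("SlopeComparison",
  representation(slopeMean = "numeric", slopeCi = "numeric",
                 probLessThanOne = "numeric", interceptMean = "numeric",
                 draws = "matrix"))
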