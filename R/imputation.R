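#' Per-metabolite left-censoring thresholds
#'
#' The detection-limit proxy for each metabolite is the minimum observed
#' value on the current (transformed) scale; under quantile left-censoring
#' every hidden value lies below it.
#'
#' @param x a [MetaboSet-class].
#' @return numeric vector of thresholds, one per metabolite.
#' @export
censoringThresholds <- function(x) {
  stopifnot(is(x, "MetaboSet"))
  v <- concentrations(x)
  nobs <- colSums(!is.na(v))
  if (any(nobs == 0))
    stop("metabolite(s) fully missing: ",
         paste(colnames(v)[nobs == 0], collapse = ", "))
  apply(v, 2, min, na.rm = TRUE)
}

#' Naive minimum/2 imputation
#'
#' Replaces every missing cell of a metabolite by half its minimum
#' observed concentration. On raw-scale data this is literal; on
#' log-z-scaled data the same substitution is applied on the concentration
#' scale and mapped through the stored transform, i.e. the fill-in value is
#' `z_min - log(2)/logSd` (with `logSd` taken from the preprocessing
#' statistics, or 1 for data generated directly on the z scale).
#'
#' @param x a [MetaboSet-class].
#' @return a complete [MetaboSet-class] (missing mask cleared; any
#'   `trueValues` assay carried along).
#' @export
naiveImpute <- function(x) {
  stopifnot(is(x, "MetaboSet"))
  v <- concentrations(x)
  if (!anyNA(v)) return(x)
  nobs <- colSums(!is.na(v))
  if (any(nobs == 0))
    stop("cannot naive-impute fully missing metabolite(s): ",
         paste(colnames(v)[nobs == 0], collapse = ", "))
  mins <- apply(v, 2, min, na.rm = TRUE)
  if (scaleState(x) == "raw") {
    fill <- mins / 2
  } else {
    logSd <- rowData(x)$logSd
    if (is.null(logSd)) logSd <- rep(1, ncol(v))
    fill <- mins - log(2) / logSd
  }
  for (j in seq_len(ncol(v))) v[is.na(v[, j]), j] <- fill[j]
  MetaboSet(v, outcome = unname(outcome(x)), sampleIds = sampleIds(x),
            metaboliteNames = metaboliteNames(x),
            scaleState = scaleState(x), trueValues = trueValues(x))
}

#' Select the most-correlated predictor metabolites
#'
#' For each target metabolite, returns the indices of the `c` metabolites
#' with the largest absolute Pearson correlation to it, computed on a
#' naive-completed working matrix (the target is never its own
#' predictor). Predictor sets are fixed once, before sampling.
#'
#' @param x a [MetaboSet-class] (missing cells are naive-imputed
#'   internally for the correlation computation).
#' @param c number of predictors per metabolite (must be < number of
#'   metabolites).
#' @param j optional single target index; default returns the full set.
#' @return with `j`: integer vector of `c` indices in decreasing
#'   correlation order; otherwise an m-by-c integer matrix (row per
#'   target).
#' @export
selectPredictors <- function(x, c = 8, j = NULL) {
  stopifnot(is(x, "MetaboSet"))
  w <- concentrations(naiveImpute(x))
  m <- ncol(w)
  if (c >= m) stop("c must be smaller than the number of metabolites")
  r <- abs(stats::cor(w))
  diag(r) <- -Inf
  pick <- function(jj) order(r[jj, ], decreasing = TRUE)[seq_len(c)]
  if (!is.null(j)) return(pick(j))
  t(vapply(seq_len(m), pick, integer(c)))
}

#' Likelihood contribution of a left-censored cell
#'
#' Under the censored regression model a missing cell contributes the
#' probability mass below the censoring threshold,
#' \eqn{\int_{-\infty}^{t} N(a \mid \mu, \sigma)\,da = \Phi((t-\mu)/\sigma)},
#' rather than a density at an imputed point. Exposed for verification;
#' tends to 1 as \eqn{t \to \infty} and to 0 as \eqn{t \to -\infty}.
#'
#' @param mu,sigma mean and sd of the cell's regression prediction.
#' @param t censoring threshold.
#' @return the censored-likelihood term \eqn{\Phi((t-\mu)/\sigma)}.
#' @export
censoredCellLikelihood <- function(mu, sigma, t) {
  stopifnot(all(sigma > 0))
  stats::pnorm((t - mu) / sigma)
}

.imputationModelString <- "
model {
  for (j in 1:m) {
    alphaI[j] ~ dnorm(0, 1.0E-6)
    for (k in 1:c) { B[j, k] ~ dnorm(0, pow(sig_b, -2)) }
    sig[j] ~ dunif(0, 100)
    for (i in 1:n) {
      mu[i, j] <- alphaI[j] + inprod(B[j, ], W[i, pred[j, ]])
      isObs[i, j] ~ dinterval(X[i, j], thr[j])
      X[i, j] ~ dnorm(mu[i, j], pow(sig[j], -2))
    }
  }
  sig_b ~ dnorm(0, 1) T(0,)
}"

#' Stage 1: Bayesian left-censored multivariate imputation
#'
#' Fits, jointly, one Bayesian linear regression per metabolite on its `c`
#' most-correlated metabolites (predictor values from a fixed
#' naive-completed working matrix). Observed cells contribute a normal
#' density; missing cells are latent values supported on
#' \eqn{(-\infty, t_j]}, so their marginal likelihood contribution is the
#' normal CDF up to the censoring threshold. Coefficients share a single
#' half-normal(0, 1) prior scale across metabolites (ridge-like pooled
#' shrinkage); intercepts and residual scales get effectively flat priors.
#' The posterior mean `E_ij` and sd `S_ij` of every latent missing value
#' summarize the soft imputation.
#'
#' @param x a preprocessed [MetaboSet-class] with missing cells.
#' @param c number of predictor metabolites (default 8).
#' @param control a [McmcControl-class].
#' @param thresholds optional censoring thresholds; default
#'   [censoringThresholds()] (minimum observed value per metabolite).
#' @param keepDraws retain the raw posterior draws of the latent missing
#'   values (`latentDraws` slot, draws by missing cells) for inspection.
#' @return an [ImputationPosterior-class]. Uses the session RNG.
#' @export
fitCensoredImputation <- function(x, c = 8, control = mcmcControl(),
                                  thresholds = censoringThresholds(x),
                                  keepDraws = FALSE) {
  stopifnot(is(x, "MetaboSet"), is(control, "McmcControl"))
  X <- concentrations(x)
  n <- nrow(X); m <- ncol(X)
  stopifnot(length(thresholds) == m)
  Z <- is.na(X)
  pred <- selectPredictors(x, c = c)
  W <- concentrations(naiveImpute(x))
  isObs <- 1L - Z * 1L  # dinterval: 1 = at/above threshold (observed)
  # latent inits must start below the threshold
  Xinit <- matrix(NA_real_, n, m)
  Xinit[Z] <- (matrix(thresholds, n, m, byrow = TRUE) - 0.5)[Z]
  dat <- list(X = X, isObs = isObs, thr = thresholds, W = W, pred = pred,
              n = n, m = m, c = c)
  fit <- .runJags(.imputationModelString, dat, c("X", "sig_b", "sig"),
                  control, inits = list(X = Xinit))
  E <- S <- matrix(NA_real_, n, m, dimnames = dimnames(X))
  latent <- matrix(numeric(0), 0, 0)
  if (any(Z)) {
    cells <- which(Z, arr.ind = TRUE)
    cols <- sprintf("X[%d,%d]", cells[, 1], cells[, 2])
    d <- fit$draws[, cols, drop = FALSE]
    E[cells] <- colMeans(d)
    S[cells] <- apply(d, 2, stats::sd)
    if (keepDraws) latent <- d
  }
  sigCols <- c("sig_b", if (m == 1) "sig" else sprintf("sig[%d]", seq_len(m)))
  dg <- .diagnoseJags(fit$mcmc, sigCols, control)
  if (!dg$converged)
    warning("imputation MCMC flagged non-converged")
  new("ImputationPosterior", E = E, S = S, thresholds = thresholds,
      predictorSets = pred, c = as.integer(c), latentDraws = latent,
      diagnostics = dg$table, converged = dg$converged)
}

#' Stage 2: multilevel logistic regression with imputation uncertainty
#'
#' The hierarchical logistic model of [fitMultilevelLogistic()], extended
#' so that every missing concentration enters as a latent quantity
#' distributed as normal(`E_ij`, `S_ij`) right-truncated at the censoring
#' threshold `t_j` (support \eqn{(-\infty, t_j]}). The latent values are
#' re-sampled within the MCMC, so the imputation uncertainty of stage 1
#' propagates into the posterior of the effect sizes. With no missing
#' cells this reduces exactly to the complete-data model.
#'
#' @param x the censored [MetaboSet-class] (same one passed to stage 1).
#' @param ip the stage-1 [ImputationPosterior-class].
#' @param scenario a [PriorScenario-class].
#' @param control a [McmcControl-class].
#' @param tailThreshold significance tail cut-off (default 0.975).
#' @return a [PosteriorSummary-class]. Uses the session RNG.
#' @export
fitLogisticWithUncertainty <- function(x, ip, scenario = learnedPrior(),
                                       control = mcmcControl(),
                                       tailThreshold = 0.975) {
  stopifnot(is(x, "MetaboSet"), is(ip, "ImputationPosterior"),
            is(scenario, "PriorScenario"))
  X <- concentrations(x)
  Z <- is.na(X)
  if (!any(Z))
    return(fitMultilevelLogistic(x, scenario, control, tailThreshold))
  cells <- which(Z, arr.ind = TRUE)
  if (anyNA(ip@E[cells]))
    stop("imputation posterior does not cover every missing cell")
  y <- unname(outcome(x))
  n <- nrow(X); m <- ncol(X)
  modelString <- paste0("
model {
  for (j in 1:m) {
    alpha[j] ~ dnorm(0, 0.04)
    beta[j] ~ dt(0, pow(sigma_b, -2), nu)
    for (i in 1:n) {
      Y[i, j] ~ dbern(ilogit(alpha[j] + beta[j] * X[i, j]))
    }
  }
  for (k in 1:K) {
    X[mrow[k], mcol[k]] ~ dnorm(E[k], precS[k]) T(, tcut[k])
  }", .hyperBlock(scenario), "
}")
  Ev <- ip@E[cells]; Sv <- ip@S[cells]
  tcut <- ip@thresholds[cells[, 2]]
  Xinit <- matrix(NA_real_, n, m)
  Xinit[cells] <- pmin(Ev, tcut - 1e-3)
  dat <- c(list(Y = matrix(y, n, m), X = X, n = n, m = m,
                K = nrow(cells), mrow = cells[, 1], mcol = cells[, 2],
                E = Ev, precS = 1 / Sv^2, tcut = tcut),
           .hyperData(scenario))
  fit <- .runJags(modelString, dat,
                  c("beta", "alpha", .hyperMonitors(scenario)), control,
                  inits = list(X = Xinit))
  .summarizeLogisticFit(fit, m, colnames(X), scenario, control,
                        tailThreshold)
}

#' Accessors for ImputationPosterior objects
#'
#' `imputedMeans()` and `imputedSds()` return samples-by-metabolites
#' matrices defined (non-NA) exactly at the cells that were missing;
#' `censorLimits()` the per-metabolite censoring thresholds.
#'
#' @param x an [ImputationPosterior-class].
#' @name ImputationPosterior-accessors
NULL

#' @rdname ImputationPosterior-accessors
#' @export
setMethod("imputedMeans", "ImputationPosterior", function(x) x@E)

#' @rdname ImputationPosterior-accessors
#' @export
setMethod("imputedSds", "ImputationPosterior", function(x) x@S)

#' @rdname ImputationPosterior-accessors
#' @export
setMethod("censorLimits", "ImputationPosterior", function(x) x@thresholds)

setMethod("show", "ImputationPosterior", function(object) {
  k <- sum(!is.na(object@E))
  cat("ImputationPosterior:", k, "imputed cells |", object@c,
      "predictors per metabolite | converged:", object@converged, "\n")
})
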