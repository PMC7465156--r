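.multilevelModelString <- function(scenario) {
  paste0("
model {
  for (j in 1:m) {
    alpha[j] ~ dnorm(0, 0.04)
    beta[j] ~ dt(0, pow(sigma_b, -2), nu)
    for (i in 1:n) {
      Y[i, j] ~ dbern(ilogit(alpha[j] + beta[j] * X[i, j]))
    }
  }", .hyperBlock(scenario), "
}")
}

#' Fit the multilevel Bayesian logistic regression (complete data)
#'
#' Each metabolite is modelled by its own univariate logistic regression of
#' the outcome, `logit(p_ij) = alpha_j + beta_j x_ij`, with the log-odds
#' coefficients partially pooled through a shared t-distribution prior
#' centred at zero: `beta_j ~ t(nu, 0, sigma)`. The hyperparameters follow
#' the active [PriorScenario-class] (by default both are learned:
#' half-Cauchy(0,1) on `sigma`, gamma(2, 0.1) constrained to at least 1 on
#' `nu`); intercepts get independent normal(0, 5) priors with no pooling.
#' Sampling is Markov chain Monte Carlo via JAGS; summaries are computed
#' from the pooled post-warmup draws.
#'
#' @param x a complete, preprocessed (log-z-scaled) [MetaboSet-class].
#'   Missing cells are an error: use [fitCensoredImputation()] and
#'   [fitLogisticWithUncertainty()] for censored data.
#' @param scenario a [PriorScenario-class] (default [learnedPrior()]).
#' @param control a [McmcControl-class].
#' @param tailThreshold posterior tail-probability cut-off for the
#'   significance flag (strictly greater than; default 0.975).
#' @return a [PosteriorSummary-class]. Uses the session RNG for chain
#'   seeds; call `set.seed()` for reproducibility.
#' @export
fitMultilevelLogistic <- function(x, scenario = learnedPrior(),
                                  control = mcmcControl(),
                                  tailThreshold = 0.975) {
  stopifnot(is(x, "MetaboSet"), is(scenario, "PriorScenario"),
            is(control, "McmcControl"))
  X <- concentrations(x)
  if (anyNA(X))
    stop("missing entries present; use fitCensoredImputation() + ",
         "fitLogisticWithUncertainty() for the censored-data path")
  if (scaleState(x) != "log_zscaled")
    stop("expects preprocessed (log_zscaled) data")
  y <- unname(outcome(x))
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  n <- nrow(X); m <- ncol(X)
  dat <- c(list(Y = matrix(y, n, m), X = X, n = n, m = m),
           .hyperData(scenario))
  fit <- .runJags(.multilevelModelString(scenario), dat,
                  c("beta", "alpha", .hyperMonitors(scenario)), control)
  .summarizeLogisticFit(fit, m, colnames(X), scenario, control,
                        tailThreshold)
}

# Shared between the complete-data and uncertainty-propagating fits.
.summarizeLogisticFit <- function(fit, m, metNames, scenario, control,
                                  tailThreshold) {
  betaCols <- if (m == 1) "beta" else sprintf("beta[%d]", seq_len(m))
  alphaCols <- if (m == 1) "alpha" else sprintf("alpha[%d]", seq_len(m))
  d <- fit$draws
  beta <- d[, betaCols, drop = FALSE]
  probNeg <- colMeans(beta < 0)
  probPos <- colMeans(beta > 0)
  ci <- apply(beta, 2, stats::quantile, probs = c(0.025, 0.975))
  summ <- data.frame(
    metabolite = metNames %||% paste0("met", seq_len(m)),
    betaMean = colMeans(beta), betaSd = apply(beta, 2, stats::sd),
    probNegative = probNeg, probPositive = probPos,
    ciLower = ci[1, ], ciUpper = ci[2, ],
    alphaMean = colMeans(d[, alphaCols, drop = FALSE]),
    row.names = NULL)
  summ$significant <- pmax(summ$probNegative, summ$probPositive) >
    tailThreshold
  hyper <- c(
    sigma = if ("sigma_b" %in% colnames(d)) mean(d[, "sigma_b"])
            else scenario@sigma,
    nu = if ("nu" %in% colnames(d)) mean(d[, "nu"]) else scenario@nu)
  diagCols <- c(betaCols, .hyperMonitors(scenario))
  dg <- .diagnoseJags(fit$mcmc, diagCols, control)
  if (!dg$converged)
    warning("MCMC convergence diagnostics exceeded thresholds; ",
            "result flagged non-converged")
  colnames(beta) <- summ$metabolite
  hypCols <- intersect(c("sigma_b", "nu"), colnames(d))
  new("PosteriorSummary", summary = summ, hyper = hyper, betaDraws = beta,
      hyperDraws = d[, hypCols, drop = FALSE],
      scenario = scenario, diagnostics = dg$table,
      converged = dg$converged)
}

#' Flag significant metabolites from posterior tail probabilities
#'
#' A metabolite is declared significant when the posterior probability
#' that its log-odds coefficient is negative, or that it is positive,
#' strictly exceeds `tailThreshold` (default 0.975, i.e. a 95% credible
#' interval excluding zero). Tail probabilities are fractions of pooled
#' post-warmup draws on each side of zero.
#'
#' @param ps a [PosteriorSummary-class].
#' @param tailThreshold tail-probability cut-off (strict inequality).
#' @return named logical vector, one flag per metabolite.
#' @export
classifySignificant <- function(ps, tailThreshold = 0.975) {
  stopifnot(is(ps, "PosteriorSummary"))
  beta <- ps@betaDraws
  flags <- pmax(colMeans(beta < 0), colMeans(beta > 0)) > tailThreshold
  names(flags) <- ps@summary$metabolite
  flags
}

#' Accessors for PosteriorSummary objects
#'
#' `posteriorSummary()` returns the per-metabolite summary data frame;
#' `betaDraws()` the pooled post-warmup coefficient draws (draws by
#' metabolites); `hyperParams()` the posterior means (or fixed values) of
#' the prior hyperparameters; `isConverged()` the convergence flag.
#'
#' @param x a [PosteriorSummary-class].
#' @name PosteriorSummary-accessors
NULL

#' @rdname PosteriorSummary-accessors
#' @export
setMethod("posteriorSummary", "PosteriorSummary", function(x) x@summary)

#' @rdname PosteriorSummary-accessors
#' @export
setMethod("betaDraws", "PosteriorSummary", function(x) x@betaDraws)

#' @rdname PosteriorSummary-accessors
#' @export
setMethod("hyperParams", "PosteriorSummary", function(x) x@hyper)

#' @rdname PosteriorSummary-accessors
#' @export
setMethod("isConverged", "PosteriorSummary", function(x) x@converged)

setMethod("show", "PosteriorSummary", function(object) {
  s <- object@summary
  cat("PosteriorSummary:", nrow(s), "metabolites |",
      sum(s$significant), "significant |",
      "scenario", object@scenario@mode, "\n")
  cat(sprintf("  hyper: sigma = %.3f, nu = %.2f | converged: %s\n",
              object@hyper["sigma"], object@hyper["nu"],
              object@converged))
})
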