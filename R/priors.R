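#' MCMC control constructor
#'
#' Defaults (4 chains, 500 adaptation + 500 burn-in, 1000 retained
#' iterations per chain) are sized for the funnel-prone hierarchical scale
#' parameters; smaller settings are adequate for quick exploration.
#'
#' @param chains,adapt,burnin,iter sampler sizes (see
#'   [McmcControl-class]).
#' @param maxRhat,minEss convergence-flag thresholds.
#' @return a [McmcControl-class].
#' @export
mcmcControl <- function(chains = 4, adapt = 500, burnin = 500, iter = 1000,
                        maxRhat = 1.1, minEss = 100) {
  new("McmcControl", chains = as.integer(chains), adapt = as.integer(adapt),
      burnin = as.integer(burnin), iter = as.integer(iter),
      maxRhat = maxRhat, minEss = minEss)
}

#' Prior scenarios for the shared effect-size prior
#'
#' `learnedPrior()` infers both the degrees of freedom `nu` (gamma(2, 0.1)
#' prior, shape/rate, constrained to be at least 1) and the scale `sigma`
#' (half-Cauchy(0, 1) prior) of the t-distribution shared across
#' metabolite log-odds coefficients. `fixedNuPrior(nu = 1)` fixes the
#' degrees of freedom (thicker tails, stronger shrinkage of small effects)
#' and learns only `sigma`. `weaklyInformativePrior(nu = 100, sigma = 5)`
#' fixes both, which removes the partial pooling entirely: each metabolite
#' gets an independent, approximately normal(0, 5) prior and the fit is
#' close to frequentist maximum likelihood. `sigmaBoundedPrior(bound =
#' 0.1)` learns both but bounds `sigma` below, guarding against
#' over-shrinkage when few metabolites carry true effects.
#'
#' @param nu degrees of freedom (>= 1).
#' @param sigma fixed prior scale (> 0).
#' @param bound lower bound on the learned scale.
#' @return a [PriorScenario-class].
#' @export
learnedPrior <- function()
  new("PriorScenario", mode = "learned", nu = NA_real_, sigma = NA_real_,
      sigmaLowerBound = 0)

#' @rdname learnedPrior
#' @export
fixedNuPrior <- function(nu = 1)
  new("PriorScenario", mode = "nu_fixed", nu = nu, sigma = NA_real_,
      sigmaLowerBound = 0)

#' @rdname learnedPrior
#' @export
weaklyInformativePrior <- function(nu = 100, sigma = 5)
  new("PriorScenario", mode = "weakly_informative", nu = nu, sigma = sigma,
      sigmaLowerBound = 0)

#' @rdname learnedPrior
#' @export
sigmaBoundedPrior <- function(bound = 0.1)
  new("PriorScenario", mode = "sigma_lower_bound", nu = NA_real_,
      sigma = NA_real_, sigmaLowerBound = bound)

setMethod("show", "PriorScenario", function(object) {
  cat("PriorScenario:", object@mode)
  if (!is.na(object@nu)) cat(" | nu =", object@nu)
  if (!is.na(object@sigma)) cat(" | sigma =", object@sigma)
  if (object@sigmaLowerBound > 0)
    cat(" | sigma lower bound =", object@sigmaLowerBound)
  cat("\n")
})
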