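#' Monte-Carlo oracle for per-metabolite true log-odds effect sizes
#'
#' The generative model is Gaussian within each class, so the "true"
#' univariate logistic log-odds coefficient of a metabolite is defined
#' operationally: draw `oracleN` samples per class from the metabolite's
#' truth-modified marginal distributions and fit a maximum-likelihood
#' univariate logistic regression; the slope at large `oracleN` is the
#' population effect size. (When the class variances are equal this
#' converges to the discriminant-analysis closed form
#' \eqn{(\mu_D - \mu_S)/\sigma^2}.)
#'
#' `marginalTrueBeta()` computes the oracle slope for every metabolite as
#' if it were selected (using the learned class means); since truth
#' assignment only zeroes out non-selected metabolites, this table can be
#' computed once per [ClassParams-class] and reused across replicates.
#' `oracleTrueBeta()` combines it with a [TruthAssignment-class].
#'
#' @param params a [ClassParams-class].
#' @param oracleN Monte-Carlo samples per group (default 1e6).
#' @return `marginalTrueBeta()`: numeric vector of slopes, one per
#'   metabolite. Uses the session RNG.
#' @export
marginalTrueBeta <- function(params, oracleN = 1e6) {
  stopifnot(is(params, "ClassParams"), oracleN >= 1000)
  m <- length(params@muD)
  vapply(seq_len(m), function(j) {
    .oracleSlope(params@muD[j], sqrt(params@SigmaD[j, j]),
                 params@muS[j], sqrt(params@SigmaS[j, j]), oracleN)
  }, numeric(1))
}

.oracleSlope <- function(muD, sdD, muS, sdS, n) {
  fit1 <- function(n) {
    x <- c(stats::rnorm(n, muD, sdD), stats::rnorm(n, muS, sdS))
    y <- rep(c(1, 0), each = n)
    f <- stats::glm.fit(cbind(1, x), y, family = stats::binomial())
    list(beta = f$coefficients[2], conv = f$converged)
  }
  f <- fit1(n)
  if (!f$conv) {
    f <- fit1(2 * n)  # one retry at doubled n
    if (!f$conv) stop("oracle logistic fit failed to converge")
  }
  unname(f$beta)
}

#' @rdname marginalTrueBeta
#' @param truth a [TruthAssignment-class].
#' @param marginalBeta optionally, a precomputed [marginalTrueBeta()]
#'   vector (avoids redoing the Monte-Carlo work per replicate).
#' @return `oracleTrueBeta()`: the [TruthAssignment-class] with its
#'   `trueBeta` slot filled in (0 for non-selected metabolites).
#' @export
oracleTrueBeta <- function(truth, params, oracleN = 1e6,
                           marginalBeta = NULL) {
  stopifnot(is(truth, "TruthAssignment"))
  if (is.null(marginalBeta)) marginalBeta <- marginalTrueBeta(params, oracleN)
  stopifnot(length(marginalBeta) == length(truth@trulyDifferent))
  truth@trueBeta <- ifelse(truth@trulyDifferent, marginalBeta, 0)
  validObject(truth)
  truth
}
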