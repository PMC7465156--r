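#' Confusion counts, power and false discovery rate
#'
#' Compares declared significance flags against the simulation truth.
#' Power is `TP/(TP+FN)` (NA when no metabolite is truly different); the
#' per-replicate FDR is `FP/(TP+FP)`, taken as 0 when nothing was declared
#' significant (no discoveries means no false discoveries).
#'
#' @param predicted,truth logical vectors of equal length.
#' @return one-row data frame with `TP`, `FP`, `FN`, `TN`, `power`, `fdr`.
#' @export
evaluateClassification <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  predicted <- as.logical(predicted); truth <- as.logical(truth)
  tp <- sum(predicted & truth); fp <- sum(predicted & !truth)
  fn <- sum(!predicted & truth); tn <- sum(!predicted & !truth)
  data.frame(TP = tp, FP = fp, FN = fn, TN = tn,
             power = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
             fdr = if (tp + fp > 0) fp / (tp + fp) else 0)
}

#' Average exaggeration ratio (Type M error proxy)
#'
#' Over the set ST of metabolites both declared significant and truly
#' non-null, the mean of `|estimate / true effect|`. An AER of 1 means
#' magnitudes are estimated without systematic exaggeration; values above
#' 1 indicate inflated significant estimates. Returns `NA` when ST is
#' empty (such replicates are excluded from scenario averages).
#'
#' @param estimates per-metabolite effect-size estimates.
#' @param trueBeta oracle true effect sizes (non-zero wherever `truth` is
#'   `TRUE`).
#' @param predicted,truth logical significance and truth flags.
#' @return a single ratio, or `NA` if no metabolite is in ST.
#' @export
aer <- function(estimates, trueBeta, predicted, truth) {
  stopifnot(length(estimates) == length(trueBeta),
            length(predicted) == length(truth),
            length(estimates) == length(predicted))
  truth <- as.logical(truth)
  if (any(truth & (is.na(trueBeta) | trueBeta == 0)))
    stop("trueBeta must be non-zero for every truly different metabolite")
  st <- as.logical(predicted) & truth
  if (!any(st)) return(NA_real_)
  mean(abs(estimates[st] / trueBeta[st]))
}

#' Certainty weights from imputation posterior sds
#'
#' `w = 1 - s / max(s)`: the most uncertain imputed cell gets weight 0 and
#' weights approach 1 as the posterior sd shrinks. (If all sds are equal
#' every weight is 0 — a degenerate case of the formula.)
#'
#' @param S positive posterior sds (vector, or matrix with `NA` at
#'   non-imputed cells).
#' @return weights of the same shape, in \eqn{[0, 1]}.
#' @export
imputationWeights <- function(S) {
  s <- S[!is.na(S)]
  stopifnot(length(s) > 0, all(s > 0))
  out <- 1 - S / max(s)
  out
}

#' Weighted Pearson correlation
#'
#' Correlation computed from weighted first and second moments, with
#' weights normalized to sum to one. Equal weights recover the ordinary
#' Pearson correlation.
#'
#' @param x,y numeric vectors of equal length.
#' @param w non-negative weights, not all zero.
#' @return the weighted correlation coefficient.
#' @export
weightedCorrelation <- function(x, y, w) {
  stopifnot(length(x) == length(y), length(x) == length(w),
            all(w >= 0), sum(w) > 0)
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) stop("zero weighted variance")
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Bayesian shrinkage-slope comparison
#'
#' Regresses the hierarchical model's effect sizes on the frequentist
#' MLEs with a flat-prior Bayesian simple linear regression and reports
#' the posterior of the slope. With identical inputs the slope
#' concentrates at 1; partial pooling shows up as a slope below 1. Under
#' flat priors the posterior is available in closed form (normal
#' inverse-chi-square), so draws are exact rather than MCMC.
#'
#' @param bayesBeta,freqBeta effect-size vectors (length >= 3).
#' @param nDraws posterior draws used for the summaries.
#' @return a [SlopeComparison-class]. Uses the session RNG.
#' @export
shrinkageSlope <- function(bayesBeta, freqBeta, nDraws = 4000) {
  stopifnot(length(bayesBeta) == length(freqBeta), length(bayesBeta) >= 3)
  if (stats::sd(freqBeta) == 0) stop("constant frequentist effect sizes")
  X <- cbind(1, freqBeta)
  n <- length(bayesBeta)
  XtXinv <- solve(crossprod(X))
  betaHat <- XtXinv %*% crossprod(X, bayesBeta)
  rss <- sum((bayesBeta - X %*% betaHat)^2)
  sigma2 <- rss / stats::rchisq(nDraws, df = n - 2)
  ch <- chol(XtXinv)
  zs <- matrix(stats::rnorm(2 * nDraws), nDraws, 2)
  draws <- sweep(zs %*% ch * sqrt(sigma2), 2, as.numeric(betaHat), `+`)
  colnames(draws) <- c("intercept", "slope")
  ci <- stats::quantile(draws[, "slope"], c(0.025, 0.975), names = FALSE)
  new("SlopeComparison",
      slopeMean = mean(draws[, "slope"]), slopeCi = ci,
      probLessThanOne = mean(draws[, "slope"] < 1),
      interceptMean = mean(draws[, "intercept"]), draws = draws)
}

setMethod("show", "SlopeComparison", function(object) {
  cat(sprintf(
    "SlopeComparison: slope %.3f (95%% CI %.3f-%.3f), P(slope < 1) = %.4f\n",
    object@slopeMean, object@slopeCi[1], object@slopeCi[2],
    object@probLessThanOne))
})
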