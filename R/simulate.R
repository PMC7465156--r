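#' Simulation scenario constructor
#'
#' @param nPerGroup samples per outcome group.
#' @param fractionSignificant target fraction of metabolites truly
#'   different between the groups.
#' @param averageMissingRate target mean of the per-metabolite missing
#'   rates (0 disables missingness).
#' @param maxMissingRate truncation limit on any single metabolite's
#'   missing rate (the study design caps it at 0.4).
#' @param nSimulations replicate data sets per scenario.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(nPerGroup, fractionSignificant,
                             averageMissingRate = 0, maxMissingRate = 0.4,
                             nSimulations = 200L) {
  new("SimulationConfig", nSimulations = as.integer(nSimulations),
      nPerGroup = as.integer(nPerGroup),
      fractionSignificant = fractionSignificant,
      averageMissingRate = averageMissingRate,
      maxMissingRate = maxMissingRate)
}

#' Learn class-conditional Gaussian parameters
#'
#' Computes the per-class sample mean vector and (unbiased, `n-1`
#' denominator) sample covariance matrix of the log-z-scaled
#' concentrations. With missing cells present, set `use = "pairwise"` to
#' estimate covariances from pairwise-complete observations; a resulting
#' indefinite matrix is projected to the nearest positive semi-definite
#' matrix with a warning.
#'
#' @param x a complete (or `use = "pairwise"`) log-z-scaled
#'   [MetaboSet-class].
#' @param use `"complete"` (default, errors on missing cells) or
#'   `"pairwise"`.
#' @return a [ClassParams-class].
#' @export
learnClassParams <- function(x, use = c("complete", "pairwise")) {
  use <- match.arg(use)
  stopifnot(is(x, "MetaboSet"))
  if (scaleState(x) != "log_zscaled")
    stop("learnClassParams() expects preprocessed (log_zscaled) data")
  v <- concentrations(x)
  if (use == "complete" && anyNA(v))
    stop("missing entries present; preprocess/impute first or use = 'pairwise'")
  y <- outcome(x)
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    stop("each outcome class needs at least 2 samples")
  est <- function(w) {
    mu <- colMeans(w, na.rm = TRUE)
    S <- stats::cov(w, use = if (use == "pairwise")
      "pairwise.complete.obs" else "everything")
    S[is.na(S)] <- 0
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(abs(ev))) {
      warning("pairwise covariance not PSD; projecting to nearest PSD matrix")
      S <- nearestPSD(S)
    }
    list(mu = mu, S = S)
  }
  d <- est(v[y == 1, , drop = FALSE])
  s <- est(v[y == 0, , drop = FALSE])
  new("ClassParams", muD = d$mu, SigmaD = d$S, muS = s$mu, SigmaS = s$S,
      nD = sum(y == 1), nS = sum(y == 0))
}

#' Project a symmetric matrix to the nearest positive semi-definite matrix
#'
#' Eigenvalue clipping: negative eigenvalues are set to a small positive
#' floor and the matrix reassembled.
#'
#' @param S symmetric matrix.
#' @param eps eigenvalue floor relative to the largest eigenvalue.
#' @return a symmetric PSD matrix.
#' @export
nearestPSD <- function(S, eps = 1e-10) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, eps * max(abs(e$values)))
  out <- e$vectors %*% (lam * t(e$vectors))
  (out + t(out)) / 2
}

#' Assign which metabolites are truly different between classes
#'
#' Selection probability is proportional to the absolute Welch t-statistic
#' between the two classes,
#' \deqn{TS_j = |\mu_{Dj} - \mu_{Sj}| / \sqrt{\sigma^2_{Dj}/n_D +
#'   \sigma^2_{Sj}/n_S},} normalized so \eqn{\sum_j p_j = 1}. Metabolites
#' are sampled without replacement with these weights (successive
#' renormalization) until at least `ceiling(fractionSignificant * m)` are
#' selected; all non-selected metabolites have both class means zeroed so
#' they carry no true group difference.
#'
#' Uses the session RNG; call `set.seed()` for reproducibility.
#'
#' @param params a [ClassParams-class].
#' @param fractionSignificant fraction in \eqn{[0, 1]}.
#' @param nPerGroup per-group sample size of the scenario (enters the
#'   t-statistic denominator for both groups).
#' @return a [TruthAssignment-class] (with `trueBeta` set to `NA` for
#'   selected metabolites until [oracleTrueBeta()] fills it in).
#' @export
assignTruth <- function(params, fractionSignificant, nPerGroup) {
  stopifnot(is(params, "ClassParams"),
            fractionSignificant >= 0, fractionSignificant <= 1)
  m <- length(params@muD)
  ts <- abs(params@muD - params@muS) /
    sqrt(diag(params@SigmaD) / nPerGroup + diag(params@SigmaS) / nPerGroup)
  if (all(ts == 0)) {
    if (fractionSignificant > 0)
      warning("all t-statistics are zero; falling back to uniform selection")
    ts <- rep(1, m)
  }
  p <- ts / sum(ts)
  k <- min(ceiling(fractionSignificant * m), m)
  sel <- logical(m)
  if (k > 0) {
    npos <- sum(p > 0)
    if (k <= npos) {
      sel[sample.int(m, size = k, replace = FALSE, prob = p)] <- TRUE
    } else {
      # all positive-weight metabolites are exhausted; the remainder is a
      # uniform draw among the zero-weight ones
      sel[p > 0] <- TRUE
      zero <- which(p == 0)
      sel[zero[sample.int(length(zero), k - npos)]] <- TRUE
    }
  }
  muDHat <- ifelse(sel, params@muD, 0)
  muSHat <- ifelse(sel, params@muS, 0)
  names(muDHat) <- names(muSHat) <- names(params@muD)
  new("TruthAssignment", trulyDifferent = sel, muDHat = muDHat,
      muSHat = muSHat, trueBeta = ifelse(sel, NA_real_, 0),
      selectionProbs = p)
}

#' Generate one synthetic two-group dataset
#'
#' Draws `nPerGroup` samples per class from multivariate normal
#' distributions with the truth-modified class means and the original
#' class covariance matrices, on the log-z-scaled concentration scale.
#' Uses the session RNG.
#'
#' @param truth a [TruthAssignment-class].
#' @param params the [ClassParams-class] the truth was derived from.
#' @param nPerGroup samples per class.
#' @return a complete [MetaboSet-class] (`scaleState = "log_zscaled"`,
#'   outcome 1 for the event class).
#' @export
generateDataset <- function(truth, params, nPerGroup) {
  stopifnot(is(truth, "TruthAssignment"), is(params, "ClassParams"))
  m <- length(params@muD)
  xd <- MASS::mvrnorm(nPerGroup, truth@muDHat, params@SigmaD)
  xs <- MASS::mvrnorm(nPerGroup, truth@muSHat, params@SigmaS)
  if (nPerGroup == 1) { xd <- matrix(xd, 1); xs <- matrix(xs, 1) }
  vals <- rbind(xd, xs)
  nm <- names(params@muD) %||% paste0("met", seq_len(m))
  MetaboSet(vals, outcome = rep(c(1L, 0L), each = nPerGroup),
            sampleIds = sprintf("sim%03d", seq_len(2 * nPerGroup)),
            metaboliteNames = nm, scaleState = "log_zscaled")
}

#' Fit and rescale the beta missing-rate model
#'
#' Fits beta-distribution moments to the reference per-metabolite missing
#' rates by the method of moments (zero rates are excluded, since a point
#' mass at zero is outside the beta family), rescales the moments to the
#' target average rate `r` — the mean becomes `r` and the variance is
#' scaled proportionally, \eqn{\hat\sigma^2_\beta = (r/\mu_\beta)\,
#' \sigma^2_\beta} — converts to beta shape parameters, draws one rate per
#' metabolite, and truncates the draws at `maxRate`. If the rescaled
#' moments are not valid beta moments the variance is shrunk to
#' \eqn{0.95\,\hat\mu(1-\hat\mu)} with a warning. With `r = 0` all rates
#' are zero. Uses the session RNG.
#'
#' @param referenceRates per-metabolite missing fractions of a reference
#'   dataset, each in \eqn{[0, 1)}.
#' @param r target average missing rate in \eqn{[0, 1)}.
#' @param maxRate truncation limit in \eqn{(0, 1]}.
#' @param m number of metabolites to draw rates for.
#' @return a [MissingnessModel-class].
#' @export
buildMissingness <- function(referenceRates, r, maxRate, m) {
  stopifnot(all(referenceRates >= 0), all(referenceRates < 1),
            r >= 0, r < 1, maxRate > 0, maxRate <= 1, m >= 1)
  pos <- referenceRates[referenceRates > 0]
  if (length(pos) < 2)
    stop("need at least 2 positive reference rates to fit beta moments")
  muB <- mean(pos)
  s2B <- stats::var(pos)
  if (r == 0) {
    return(new("MissingnessModel", targetRate = 0, maxRate = maxRate,
               refMean = muB, refVar = s2B, shape1 = NA_real_,
               shape2 = NA_real_, rates = rep(0, m)))
  }
  muHat <- r
  s2Hat <- (r / muB) * s2B
  lim <- muHat * (1 - muHat)
  if (s2Hat >= lim) {
    warning("rescaled variance exceeds beta bound; shrinking to 0.95*mu*(1-mu)")
    s2Hat <- 0.95 * lim
  }
  common <- lim / s2Hat - 1
  a <- muHat * common
  b <- (1 - muHat) * common
  rates <- pmin(stats::rbeta(m, a, b), maxRate)
  new("MissingnessModel", targetRate = r, maxRate = maxRate,
      refMean = muB, refVar = s2B, shape1 = a, shape2 = b, rates = rates)
}

#' Left-censor a complete dataset according to a missingness model
#'
#' For metabolite `j`, every value strictly below the empirical
#' `rates[j]`-quantile (linear-interpolation quantile, pooled over both
#' classes) is marked missing. The complete matrix is retained in the
#' `"trueValues"` assay so imputation quality can later be scored against
#' the hidden truth.
#'
#' @param x a complete [MetaboSet-class].
#' @param cfg a [MissingnessModel-class] whose `rates` match the number of
#'   metabolites.
#' @return a [MetaboSet-class] with `NA` at censored cells and the
#'   pre-censoring matrix stored as `trueValues`.
#' @export
injectMissingness <- function(x, cfg) {
  stopifnot(is(x, "MetaboSet"), is(cfg, "MissingnessModel"))
  v <- concentrations(x)
  if (anyNA(v)) stop("injectMissingness() expects a complete matrix")
  if (length(cfg@rates) != ncol(v))
    stop("rates length does not match the number of metabolites")
  cens <- v
  for (j in seq_len(ncol(v))) {
    mj <- cfg@rates[j]
    if (mj <= 0) next
    q <- stats::quantile(v[, j], probs = mj, type = 7, names = FALSE)
    cens[v[, j] < q, j] <- NA
  }
  MetaboSet(cens, outcome = unname(outcome(x)), sampleIds = sampleIds(x),
            metaboliteNames = metaboliteNames(x),
            scaleState = scaleState(x), trueValues = v)
}
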