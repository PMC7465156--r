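#' Synthetic class-conditional parameters for a 27-metabolite NMR-like panel
#'
#' A deterministic, fully synthetic stand-in for class parameters learned
#' from a real septic-shock serum NMR panel, so the simulation study runs
#' with no external data. It emulates the broad features of such a panel
#' on the log-z-scaled concentration scale: 27 metabolites in four
#' correlated blocks (pathway-like correlation ~0.45 within blocks, ~0.05
#' between), group sizes 122 events / 106 non-events, per-class standard
#' deviations spread over roughly 0.8-1.25, and class mean differences
#' ranging from near zero to about 0.9 z-units with alternating signs
#' (pooled means centred at zero, as autoscaling enforces). It is not
#' derived from any measured data set.
#'
#' @param m number of metabolites (default 27).
#' @return a [ClassParams-class].
#' @export
syntheticClassParams <- function(m = 27) {
  # class mean differences: smooth ramp of magnitudes, alternating sign
  delta <- seq(0.02, 0.9, length.out = m) * rep_len(c(1, -1), m)
  nD <- 122L; nS <- 106L
  muD <- delta * nS / (nD + nS)
  muS <- muD - delta                     # pooled weighted mean is zero
  # block-structured correlation shared by both classes
  sizes <- rep_len(ceiling(m / 4), 4)
  sizes[4] <- m - sum(sizes[1:3])
  block <- rep(seq_along(sizes), sizes)[seq_len(m)]
  R <- outer(block, block, function(a, b) ifelse(a == b, 0.45, 0.05))
  diag(R) <- 1
  sdD <- 0.8 + 0.45 * (seq_len(m) %% 5) / 4
  sdS <- 1.25 - 0.45 * (seq_len(m) %% 4) / 3
  nm <- sprintf("met%02d", seq_len(m))
  SigD <- outer(sdD, sdD) * R
  SigS <- outer(sdS, sdS) * R
  dimnames(SigD) <- dimnames(SigS) <- list(nm, nm)
  names(muD) <- names(muS) <- nm
  new("ClassParams", muD = muD, SigmaD = SigD, muS = muS, SigmaS = SigS,
      nD = nD, nS = nS)
}

#' Synthetic reference missing-rate distribution
#'
#' Deterministic per-metabolite missing fractions shaped like the
#' right-skewed missing-rate distribution of a quantified NMR panel before
#' filtering (most metabolites below 20% missing, a few up to ~45%); used
#' as the reference for the beta missing-rate model. Synthetic, not
#' measured.
#'
#' @param m number of metabolites (default 27).
#' @return numeric vector of fractions in \eqn{(0, 1)}.
#' @export
syntheticMissingRates <- function(m = 27) {
  stats::qbeta(stats::ppoints(m), shape1 = 1.1, shape2 = 6)
}

setMethod("show", "ClassParams", function(object) {
  m <- length(object@muD)
  cat("ClassParams:", m, "metabolites | group sizes", object@nD, "(D) /",
      object@nS, "(S)\n")
  cat(sprintf("  max |muD - muS| = %.3f\n", max(abs(object@muD - object@muS))))
})

setMethod("show", "TruthAssignment", function(object) {
  cat("TruthAssignment:", sum(object@trulyDifferent), "of",
      length(object@trulyDifferent), "metabolites truly different\n")
  if (!anyNA(object@trueBeta))
    cat(sprintf("  |trueBeta| range over selected: %.3f-%.3f\n",
                min(abs(object@trueBeta[object@trulyDifferent])),
                max(abs(object@trueBeta[object@trulyDifferent]))))
})

setMethod("show", "MissingnessModel", function(object) {
  cat(sprintf(
    "MissingnessModel: target rate %.2f (max %.2f) | realized mean %.3f\n",
    object@targetRate, object@maxRate, mean(object@rates)))
})
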