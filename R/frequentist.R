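#' Univariate logistic regression baselines
#'
#' Fits, per metabolite, a maximum-likelihood logistic regression of the
#' outcome on that metabolite plus an intercept, and reports the Wald
#' p-value for the slope together with Bonferroni and Benjamini-Hochberg
#' adjusted p-values and significance flags at `alpha`. Perfect separation
#' is flagged (the estimate diverges) with a warning rather than an error.
#'
#' @param x a complete [MetaboSet-class] (apply [naiveImpute()] first when
#'   censored cells are present).
#' @param alpha decision threshold on the (adjusted) p-values.
#' @return a data frame with one row per metabolite: `beta`, `se`,
#'   `pValue`, `pBonferroni`, `pBH`, significance flags, and a
#'   `separation` indicator.
#' @export
fitUnivariateLogistic <- function(x, alpha = 0.05) {
  stopifnot(is(x, "MetaboSet"))
  X <- concentrations(x)
  if (anyNA(X)) stop("missing entries present; impute first")
  y <- unname(outcome(x))
  m <- ncol(X)
  beta <- se <- p <- numeric(m)
  sep <- logical(m)
  for (j in seq_len(m)) {
    fit <- withCallingHandlers(
      stats::glm(y ~ X[, j], family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) {
          sep[j] <<- TRUE
          invokeRestart("muffleWarning")
        } else if (grepl("algorithm did not converge",
                         conditionMessage(w))) {
          sep[j] <<- TRUE  # divergence accompanies separation
          invokeRestart("muffleWarning")
        }
      })
    cf <- summary(fit)$coefficients
    beta[j] <- cf[2, 1]; se[j] <- cf[2, 2]; p[j] <- cf[2, 4]
  }
  if (any(sep))
    warning("perfect separation for metabolite(s): ",
            paste(colnames(X)[sep], collapse = ", "))
  out <- data.frame(metabolite = colnames(X), beta = beta, se = se,
                    pValue = p,
                    pBonferroni = adjustPvalues(p, "bonferroni"),
                    pBH = adjustPvalues(p, "bh"),
                    separation = sep, row.names = NULL)
  out$sigRaw <- out$pValue < alpha
  out$sigBonferroni <- out$pBonferroni < alpha
  out$sigBH <- out$pBH < alpha
  out
}

#' Multiple-testing adjustment of p-values
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up adjusted
#' p-values, via [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in \eqn{[0, 1]}.
#' @param method `"bonferroni"` or `"bh"`.
#' @return adjusted p-values of the same length.
#' @export
adjustPvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  stopifnot(all(p >= 0), all(p <= 1))
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}
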