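test_that("censoring thresholds are the per-metabolite observed minima", {
  vals <- cbind(a = c(-1.2, 0.3, 2.0), b = c(0.5, 1.5, 2.5))
  ms <- MetaboSet(vals, outcome = c(0, 1, 0), scaleState = "log_zscaled")
  expect_equal(censoringThresholds(ms), c(a = -1.2, b = 0.5))

  vals[2, "a"] <- NA
  msm <- MetaboSet(vals, outcome = c(0, 1, 0), scaleState = "log_zscaled")
  expect_equal(censoringThresholds(msm), c(a = -1.2, b = 0.5))

  vals[, "a"] <- NA
  suppressWarnings(bad <- MetaboSet(vals, outcome = c(0, 1, 0),
                                    scaleState = "log_zscaled"))
  expect_error(censoringThresholds(bad), "fully missing")
})

test_that("simulated censoring keeps hidden values below the threshold", {
  params <- tinyParams(5)
  set.seed(40)
  tr <- assignTruth(params, 0.4, 60)
  ds <- generateDataset(tr, params, 60)
  mm <- buildMissingness(syntheticMissingRates(), 0.3, 0.4, 5)
  cd <- injectMissingness(ds, mm)
  t <- censoringThresholds(cd)
  Z <- missingMask(cd); tv <- trueValues(cd)
  for (j in which(colSums(Z) > 0))
    expect_true(all(tv[Z[, j], j] < t[j]))
})

test_that("predictor selection ranks by absolute Pearson correlation", {
  set.seed(41)
  x <- matrix(rnorm(300), 50, 6)
  x[, 2] <- x[, 1] + rnorm(50, sd = 0.05)   # near-duplicate of column 1
  x[, 3] <- -x[, 1] + rnorm(50, sd = 0.3)   # strong negative correlation
  ms <- MetaboSet(x, outcome = rep(c(0, 1), 25), scaleState = "log_zscaled")
  expect_equal(selectPredictors(ms, c = 1, j = 1), 2L)
  got <- selectPredictors(ms, c = 3)
  # brute-force oracle over all pairs
  r <- abs(cor(x)); diag(r) <- -Inf
  for (j in 1:6)
    expect_equal(got[j, ], order(r[j, ], decreasing = TRUE)[1:3])

  # m = 3, c = 2: the predictor set is forced to the other two metabolites
  ms3 <- MetaboSet(x[, 1:3], outcome = rep(c(0, 1), 25),
                   scaleState = "log_zscaled")
  expect_setequal(selectPredictors(ms3, c = 2, j = 1), c(2L, 3L))
  expect_error(selectPredictors(ms3, c = 3), "smaller")
})

test_that("censored-cell likelihood equals the normal probability mass", {
  # independent oracle: numeric integration of the normal density
  for (case in list(c(0, 1, -0.5), c(1.3, 0.4, 1.0), c(-2, 2.5, 0))) {
    mu <- case[1]; sig <- case[2]; t <- case[3]
    direct <- integrate(dnorm, -Inf, t, mean = mu, sd = sig,
                        rel.tol = 1e-10)$value
    expect_equal(censoredCellLikelihood(mu, sig, t), direct,
                 tolerance = 1e-8)
  }
  expect_equal(censoredCellLikelihood(0, 1, 1e6), 1)
  expect_equal(censoredCellLikelihood(0, 1, -1e6), 0)
})

test_that("stage 1 posterior respects censoring and beats naive imputation", {
  params <- tinyParams(6)
  set.seed(42)
  tr <- assignTruth(params, 0.4, 60)
  ds <- generateDataset(tr, params, 60)
  mm <- buildMissingness(syntheticMissingRates(), 0.3, 0.4, 6)
  cd <- injectMissingness(ds, mm)
  ip <- fitCensoredImputation(cd, c = 3, control = fastControl(),
                              keepDraws = TRUE)
  Z <- missingMask(cd)
  expect_equal(!is.na(imputedMeans(ip)), Z, ignore_attr = TRUE)
  tmat <- matrix(censorLimits(ip), nrow(Z), ncol(Z), byrow = TRUE)
  expect_true(all(imputedMeans(ip)[Z] <= tmat[Z]))
  expect_true(all(imputedSds(ip)[Z] > 0))
  # every latent draw honours the truncation at its threshold
  cells <- which(Z, arr.ind = TRUE)
  expect_true(all(t(ip@latentDraws) <= tmat[cells] + 1e-12))

  tv <- trueValues(cd)
  corBayes <- cor(imputedMeans(ip)[Z], tv[Z])
  corNaive <- cor(concentrations(naiveImpute(cd))[Z], tv[Z])
  expect_gt(corBayes, corNaive)
})

test_that("stage 1 with complete data yields an empty imputation posterior", {
  ds <- makeZSet(30, 4, seed = 43)
  ip <- fitCensoredImputation(ds, c = 2, control = fastControl())
  expect_true(all(is.na(imputedMeans(ip))))
  expect_true(all(is.na(imputedSds(ip))))
  expect_equal(nrow(ip@latentDraws), 0L)
})

test_that("an unbinding censoring threshold leaves the regression fit", {
  # one censored cell whose predictors imply a mean far below the
  # threshold: the truncation is inactive, so E ~= regression mean and
  # S ~= residual sd
  set.seed(44)
  n <- 120
  x2 <- c(rnorm(n - 1), -4); x3 <- c(rnorm(n - 1), 4)
  x1 <- 0.9 * x2 - 0.6 * x3 + rnorm(n, sd = 0.25)
  miss <- n  # prediction 0.9*(-4) - 0.6*4 = -6, deep in the left tail
  predMean <- 0.9 * x2[miss] - 0.6 * x3[miss]
  vals <- cbind(a = x1, b = x2, c = x3)
  vals[miss, "a"] <- NA
  ms <- MetaboSet(vals, outcome = rep(c(0, 1), n / 2),
                  scaleState = "log_zscaled")
  expect_lt(predMean, censoringThresholds(ms)["a"] - 1)
  ip <- fitCensoredImputation(ms, c = 2, control = fastControl())
  expect_equal(unname(imputedMeans(ip)[miss, "a"]), predMean,
               tolerance = 0.25)
  expect_equal(unname(imputedSds(ip)[miss, "a"]), 0.25, tolerance = 0.15)
})

test_that("stage 2 reduces to hard imputation as the posterior sd shrinks", {
  params <- tinyParams(4)
  set.seed(45)
  tr <- assignTruth(params, 0.5, 80)
  ds <- generateDataset(tr, params, 80)
  mm <- new("MissingnessModel", targetRate = 0.2, maxRate = 0.4,
            refMean = 0.1, refVar = 0.01, shape1 = 1, shape2 = 1,
            rates = rep(0.2, 4))
  cd <- injectMissingness(ds, mm)
  Z <- missingMask(cd)
  E <- matrix(NA_real_, nrow(Z), ncol(Z))
  E[Z] <- (matrix(censoringThresholds(cd), nrow(Z), ncol(Z),
                  byrow = TRUE) - 0.4)[Z]
  S <- matrix(NA_real_, nrow(Z), ncol(Z)); S[Z] <- 1e-4
  ip <- new("ImputationPosterior", E = E, S = S,
            thresholds = censoringThresholds(cd),
            predictorSets = matrix(0L, 0, 0), c = 0L,
            latentDraws = matrix(numeric(0), 0, 0),
            diagnostics = data.frame(), converged = TRUE)
  ctrl <- fastControl(iter = 800)
  set.seed(46)
  soft <- fitLogisticWithUncertainty(cd, ip, learnedPrior(), ctrl)
  hard <- concentrations(cd); hard[Z] <- E[Z]
  hardSet <- MetaboSet(hard, outcome = unname(outcome(cd)),
                       scaleState = "log_zscaled")
  set.seed(47)
  psHard <- fitMultilevelLogistic(hardSet, learnedPrior(), ctrl)
  expect_equal(posteriorSummary(soft)$betaMean,
               posteriorSummary(psHard)$betaMean, tolerance = 0.12)
})

test_that("stage 2 with no missing data delegates to the complete model", {
  ds <- makeZSet(40, 4, seed = 48)
  ipEmpty <- new("ImputationPosterior",
                 E = matrix(NA_real_, 80, 4), S = matrix(NA_real_, 80, 4),
                 thresholds = censoringThresholds(ds),
                 predictorSets = matrix(0L, 0, 0), c = 0L,
                 latentDraws = matrix(numeric(0), 0, 0),
                 diagnostics = data.frame(), converged = TRUE)
  set.seed(49)
  a <- fitLogisticWithUncertainty(ds, ipEmpty, learnedPrior(), fastControl())
  set.seed(49)
  b <- fitMultilevelLogistic(ds, learnedPrior(), fastControl())
  expect_equal(betaDraws(a), betaDraws(b))
})

test_that("uncertainty propagation limits AER under 30% missingness", {
  # matched replicates: two-stage Bayesian path vs frequentist regression
  # on naive-imputed data, scored against the same oracle truth
  params <- syntheticClassParams()
  cfg <- simulationConfig(100, 0.4, averageMissingRate = 0.3,
                          nSimulations = 5)
  out <- runGrid(cfg, params, models = c("bayes_learned", "freq_raw"),
                 seed = 7,
                 control = mcmcControl(chains = 2, adapt = 300,
                                       burnin = 200, iter = 500,
                                       minEss = 20),
                 oracleN = 5e4)
  r <- out$replicates
  a <- r$aer[r$model == "bayes_learned"]
  b <- r$aer[r$model == "freq_raw"]
  ok <- !is.na(a) & !is.na(b)
  expect_gte(sum(ok), 3)
  expect_lt(mean(a[ok]), mean(b[ok]))
})
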