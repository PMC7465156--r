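test_that("learnClassParams returns per-class moments", {
  set.seed(10)
  # identical classes give identical parameters
  half <- matrix(rnorm(40), 10, 4)
  ms <- MetaboSet(rbind(half, half), outcome = rep(c(1, 0), each = 10),
                  scaleState = "log_zscaled")
  cp <- learnClassParams(ms)
  expect_equal(cp@muD, cp@muS, ignore_attr = TRUE)
  expect_equal(cp@SigmaD, cp@SigmaS, ignore_attr = TRUE)

  # hand computation: values {-1, 1} -> mean 0, unbiased variance 2
  one <- matrix(c(-1, 1, -1, 1), 4, 1)
  ms1 <- MetaboSet(rbind(one, one + 5), outcome = rep(c(1, 0), each = 4),
                   scaleState = "log_zscaled")
  cp1 <- learnClassParams(ms1)
  expect_equal(unname(cp1@muD), 0)
  expect_equal(unname(cp1@SigmaD[1, 1]), 4 / 3)  # var of (-1,1,-1,1), ddof 1
  two <- matrix(c(-1, 1), 2, 1)
  ms2 <- MetaboSet(rbind(two, two), outcome = c(1, 1, 0, 0),
                   scaleState = "log_zscaled")
  expect_equal(unname(learnClassParams(ms2)@SigmaD[1, 1]), 2)

  expect_error(learnClassParams(
    MetaboSet(matrix(rnorm(8), 4, 2), outcome = c(1, 0, 0, 0),
              scaleState = "log_zscaled")), "at least 2")
})

test_that("learned parameters recover the generating values", {
  set.seed(11)
  params <- tinyParams(4)
  truth <- assignTruth(params, 1, 2000)  # all selected: means unchanged
  ds <- generateDataset(truth, params, 2000)
  cp <- learnClassParams(ds)
  se <- sqrt(diag(params@SigmaD) / 2000)
  expect_true(all(abs(cp@muD - params@muD) < 3 * se))
  expect_true(all(abs(cp@muS - params@muS) < 3 * se))
  expect_lt(max(abs(cp@SigmaD - params@SigmaD)), 0.1)
})

test_that("assignTruth boundaries and weighted selection frequencies", {
  params <- tinyParams(6)
  set.seed(12)
  tAll <- assignTruth(params, 1, 50)
  expect_true(all(tAll@trulyDifferent))
  expect_equal(tAll@muDHat, params@muD)
  tNone <- assignTruth(params, 0, 50)
  expect_false(any(tNone@trulyDifferent))
  expect_true(all(tNone@muDHat == 0) && all(tNone@muSHat == 0))
  expect_equal(tNone@trueBeta, rep(0, 6))

  # m = 2 with TS ratio 3:1 -> selection probabilities (0.75, 0.25)
  p2 <- new("ClassParams", muD = c(a = 1.5, b = 0.5),
            SigmaD = diag(2), muS = c(a = -1.5, b = -0.5),
            SigmaS = diag(2), nD = 50L, nS = 50L)
  t2 <- assignTruth(p2, 0.5, 50)
  expect_equal(unname(t2@selectionProbs), c(0.75, 0.25))
  picks <- replicate(2e4, which(assignTruth(p2, 0.5, 50)@trulyDifferent))
  expect_equal(mean(picks == 1), 0.75, tolerance = 0.015)

  # all-zero t statistics fall back to uniform selection with a warning
  p0 <- new("ClassParams", muD = c(a = 0, b = 0), SigmaD = diag(2),
            muS = c(a = 0, b = 0), SigmaS = diag(2), nD = 50L, nS = 50L)
  expect_warning(t0 <- assignTruth(p0, 0.5, 50), "uniform")
  expect_equal(sum(t0@trulyDifferent), 1L)
})

test_that("selection count always reaches the ceiling of the target", {
  params <- syntheticClassParams()
  set.seed(13)
  for (f in c(0.1, 0.4, 0.7, 0.95)) {
    tr <- assignTruth(params, f, 100)
    expect_gte(sum(tr@trulyDifferent), ceiling(f * 27))
    expect_lte(sum(tr@trulyDifferent), 27)
  }
})

test_that("generateDataset is seed-reproducible and matches its moments", {
  params <- tinyParams(4)
  truth <- local({set.seed(14); assignTruth(params, 0.5, 100)})
  set.seed(99); d1 <- generateDataset(truth, params, 100)
  set.seed(99); d2 <- generateDataset(truth, params, 100)
  expect_identical(concentrations(d1), concentrations(d2))

  set.seed(15)
  big <- generateDataset(truth, params, 5000)
  v <- concentrations(big)
  xb <- colMeans(v[outcome(big) == 1, ])
  se <- sqrt(diag(params@SigmaD) / 5000)
  expect_true(all(abs(xb - truth@muDHat) < 4 * se))
})

test_that("null scenario is calibrated: ~5% t-test rejections", {
  params <- tinyParams(10)
  set.seed(16)
  pvals <- unlist(lapply(1:30, function(i) {
    tr <- assignTruth(params, 0, 50)
    ds <- generateDataset(tr, params, 50)
    v <- concentrations(ds); y <- outcome(ds)
    apply(v, 2, function(col) t.test(col[y == 1], col[y == 0])$p.value)
  }))
  rate <- mean(pvals < 0.05)
  se <- sqrt(0.05 * 0.95 / length(pvals))
  expect_lt(abs(rate - 0.05), 2.5 * se)
})

test_that("missingness model rescales beta moments as specified", {
  ref <- syntheticMissingRates(27)
  muB <- mean(ref); s2B <- var(ref)

  # r = 0: no missingness at all
  m0 <- buildMissingness(ref, 0, 0.4, 10)
  expect_true(all(m0@rates == 0))

  # r equal to the reference mean: rescaling is the identity on moments
  set.seed(17)
  mid <- buildMissingness(ref, muB, 1, 5)
  a <- mid@shape1; b <- mid@shape2
  expect_equal(a / (a + b), muB, tolerance = 1e-10)
  expect_equal(a * b / ((a + b)^2 * (a + b + 1)), s2B, tolerance = 1e-10)

  # Monte-Carlo moment check without truncation
  set.seed(18)
  mm <- buildMissingness(ref, 0.3, 1, 1e5)
  expect_equal(mean(mm@rates), 0.3, tolerance = 0.005)

  # infeasible rescaled variance triggers shrinkage, not failure
  wild <- c(0.01, 0.02, 0.9, 0.95)
  expect_warning(mw <- buildMissingness(wild, 0.5, 1, 10), "shrinking")
  expect_true(all(is.finite(c(mw@shape1, mw@shape2))))
})

test_that("left-censoring hides exactly the lower quantile tail", {
  params <- tinyParams(5)
  set.seed(19)
  tr <- assignTruth(params, 0.4, 100)
  ds <- generateDataset(tr, params, 50)  # n = 100 samples
  cfg <- new("MissingnessModel", targetRate = 0.3, maxRate = 0.4,
             refMean = 0.1, refVar = 0.01, shape1 = 1, shape2 = 1,
             rates = c(0, 0.3, 0.1, 0.25, 0.4))
  cd <- injectMissingness(ds, cfg)
  Z <- missingMask(cd)
  expect_equal(unname(colSums(Z)), c(0, 30, 10, 25, 40))
  v <- concentrations(cd); tv <- trueValues(cd)
  for (j in 2:5) {
    cens <- tv[Z[, j], j]; obs <- v[!Z[, j], j]
    expect_lt(max(cens), min(obs))  # strict left-censoring ordering
  }
  # realized overall missing fraction tracks the mean target rate
  expect_equal(mean(Z), mean(cfg@rates), tolerance = 0.02)
})

test_that("oracle effect sizes match the equal-variance closed form", {
  delta <- 0.5
  p <- new("ClassParams", muD = c(x = delta), SigmaD = diag(1),
           muS = c(x = -delta), SigmaS = diag(1), nD = 50L, nS = 50L)
  set.seed(20)
  b <- marginalTrueBeta(p, oracleN = 2e5)
  expect_equal(unname(b), 2 * delta, tolerance = 0.05)  # LDA closed form

  # sign follows the mean difference; non-selected metabolites are 0
  p2 <- tinyParams(4)
  set.seed(21)
  tr <- assignTruth(p2, 0.5, 50)
  tr <- oracleTrueBeta(tr, p2, oracleN = 2e4)
  expect_equal(tr@trueBeta[!tr@trulyDifferent],
               rep(0, sum(!tr@trulyDifferent)), ignore_attr = TRUE)
  sel <- tr@trulyDifferent & (tr@muDHat != tr@muSHat)
  expect_equal(sign(tr@trueBeta[sel]), sign(tr@muDHat - tr@muSHat)[sel],
               ignore_attr = TRUE)
})
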