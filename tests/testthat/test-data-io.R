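test_that("reading a table maps blanks and sentinel values to missing", {
  vals <- matrix(c(1.2, 2.3, 3.1, 4.5, NA, 6.7), 3, 2,
                 dimnames = list(NULL, c("ala", "gly")))
  path <- writeRawCsv(vals, c(0, 1, 0))
  ms <- readConcentrationTable(path, "died")
  expect_s4_class(ms, "MetaboSet")
  expect_equal(sum(missingMask(ms)), 1L)
  expect_equal(scaleState(ms), "raw")
  expect_equal(unname(outcome(ms)), c(0L, 1L, 0L))

  # zero concentrations are below any detection limit -> censored
  vals0 <- vals; vals0[2, 1] <- 0
  ms0 <- readConcentrationTable(writeRawCsv(vals0, c(0, 1, 0)), "died")
  expect_true(missingMask(ms0)[2, "ala"])
})

test_that("malformed tables are rejected with informative errors", {
  vals <- matrix(1:6 + 0.5, 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(
    readConcentrationTable(writeRawCsv(vals, c(0, 1, 2)), "died"),
    "0/1")
  path <- writeRawCsv(vals, c(0, 1, 0))
  txt <- readLines(path)
  txt[1] <- "sample_id,died,a,a"
  writeLines(txt, path)
  expect_error(readConcentrationTable(path, "died"), "duplicate")

  valsAllNA <- matrix(c(1, 2, 3, NA, NA, NA), 3, 2,
                      dimnames = list(NULL, c("ok", "gone")))
  expect_warning(
    readConcentrationTable(writeRawCsv(valsAllNA, c(0, 1, 0)), "died"),
    "all values missing")
})

test_that("write/read round-trip preserves values, mask and outcome", {
  set.seed(3)
  vals <- matrix(rlnorm(40), 8, 5,
                 dimnames = list(NULL, paste0("m", 1:5)))
  vals[cbind(c(2, 5), c(1, 4))] <- NA
  ms <- MetaboSet(vals, outcome = rep(c(0, 1), 4))
  path <- tempfile(fileext = ".csv")
  writeConcentrationTable(ms, path, outcomeColumn = "died")
  back <- readConcentrationTable(path, "died")
  expect_equal(unname(concentrations(back)), unname(concentrations(ms)),
               tolerance = 1e-12)
  expect_equal(missingMask(back), missingMask(ms), ignore_attr = TRUE)
  expect_equal(unname(outcome(back)), unname(outcome(ms)))
})

test_that("preprocess filters by missing rate, logs and autoscales", {
  set.seed(4)
  n <- 20
  vals <- cbind(clean = rlnorm(n), gappy = rlnorm(n))
  vals[1:7, "gappy"] <- NA  # 35% missing
  ms <- MetaboSet(vals, outcome = rep(c(0, 1), 10))
  pp <- preprocess(ms, missingThreshold = 0.30)
  expect_equal(metaboliteNames(pp), "clean")
  expect_equal(scaleState(pp), "log_zscaled")
  z <- concentrations(pp)[, "clean"]
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)

  # a metabolite exactly at the threshold is dropped (keep iff rate < thr)
  vals2 <- cbind(clean = rlnorm(n), edge = rlnorm(n))
  vals2[1:6, "edge"] <- NA  # exactly 30%
  pp2 <- preprocess(MetaboSet(vals2, outcome = rep(c(0, 1), 10)), 0.30)
  expect_equal(metaboliteNames(pp2), "clean")
})

test_that("preprocess keeps missing cells missing and scales over observed", {
  set.seed(5)
  vals <- cbind(a = rlnorm(20), b = rlnorm(20))
  vals[c(3, 9), "b"] <- NA
  pp <- preprocess(MetaboSet(vals, outcome = rep(c(0, 1), 10)), 0.30)
  z <- concentrations(pp)
  expect_true(all(is.na(z[c(3, 9), "b"])))
  obs <- z[-c(3, 9), "b"]
  expect_equal(mean(obs), 0, tolerance = 1e-9)
  expect_equal(sd(obs), 1, tolerance = 1e-9)
  # already-scaled input is rejected, so the pipeline cannot double-apply
  expect_error(preprocess(pp), "raw")
})

test_that("preprocess rejects non-positive and constant metabolites", {
  vals <- cbind(a = c(1, 2, -0.5, 3), b = c(1, 2, 3, 4))
  ms <- MetaboSet(vals, outcome = c(0, 1, 0, 1))
  expect_error(preprocess(ms), "non-positive")
  vals2 <- cbind(a = rep(2, 4), b = c(1, 2, 3, 4))
  expect_error(preprocess(MetaboSet(vals2, outcome = c(0, 1, 0, 1))),
               "constant")
  vals3 <- matrix(NA_real_, 4, 1, dimnames = list(NULL, "x"))
  suppressWarnings(ms3 <- MetaboSet(vals3, outcome = c(0, 1, 0, 1)))
  expect_error(preprocess(ms3), "all metabolites")
})
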