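# Thin wrapper around rjags: per-chain RNG seeds are drawn from the session
# RNG so results are reproducible under set.seed(); adaptation warnings from
# short exploratory runs are tolerated.
.runJags <- function(modelString, data, monitors, control, inits = NULL) {
  chainSeeds <- sample.int(.Machine$integer.max - 1L, control@chains)
  initList <- lapply(seq_len(control@chains), function(k) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = chainSeeds[k])
    if (!is.null(inits)) ini <- c(inits, ini)
    ini
  })
  jm <- suppressWarnings(rjags::jags.model(
    textConnection(modelString), data = data, inits = initList,
    n.chains = control@chains, n.adapt = control@adapt, quiet = TRUE))
  if (control@burnin > 0)
    stats::update(jm, n.iter = control@burnin, progress.bar = "none")
  samp <- rjags::coda.samples(jm, variable.names = monitors,
                              n.iter = control@iter, progress.bar = "none")
  list(mcmc = samp, draws = do.call(rbind, lapply(samp, as.matrix)))
}

# Split-free Gelman-Rubin Rhat and pooled ESS on the named columns.
.diagnoseJags <- function(samp, columns, control) {
  sub <- lapply(samp, function(ch) ch[, columns, drop = FALSE])
  rhat <- tryCatch({
    gd <- coda::gelman.diag(coda::as.mcmc.list(lapply(sub, coda::mcmc)),
                            multivariate = FALSE, autoburnin = FALSE)
    gd$psrf[, 1]
  }, error = function(e) rep(NA_real_, length(columns)))
  ess <- tryCatch(
    coda::effectiveSize(coda::as.mcmc.list(lapply(sub, coda::mcmc))),
    error = function(e) rep(NA_real_, length(columns)))
  diag <- data.frame(parameter = columns, rhat = unname(rhat[columns]),
                     ess = unname(ess[columns]), row.names = NULL)
  conv <- all(is.na(diag$rhat) | diag$rhat <= control@maxRhat) &&
    all(is.na(diag$ess) | diag$ess >= control@minEss)
  list(table = diag, converged = conv)
}

# Hyperprior block of the hierarchical logistic model for a given scenario.
# JAGS dt() takes precision; the half-Cauchy scale prior is dt(0,1,1)T(lb,).
.hyperBlock <- function(scenario) {
  switch(scenario@mode,
    learned = "
  sigma_b ~ dt(0, 1, 1) T(0,)
  nu ~ dgamma(2, 0.1) T(1,)",
    nu_fixed = "
  sigma_b ~ dt(0, 1, 1) T(0,)",
    weakly_informative = "",
    sigma_lower_bound = sprintf("
  sigma_b ~ dt(0, 1, 1) T(%g,)
  nu ~ dgamma(2, 0.1) T(1,)", scenario@sigmaLowerBound))
}

.hyperData <- function(scenario) {
  switch(scenario@mode,
    learned = list(),
    nu_fixed = list(nu = scenario@nu),
    weakly_informative = list(nu = scenario@nu, sigma_b = scenario@sigma),
    sigma_lower_bound = list())
}

.hyperMonitors <- function(scenario) {
  switch(scenario@mode,
    learned = c("sigma_b", "nu"),
    nu_fixed = "sigma_b",
    weakly_informative = character(0),
    sigma_lower_bound = c("sigma_b", "nu"))
}
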