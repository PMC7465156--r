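# metabshrink

Multilevel Bayesian effect-size estimation for two-group metabolomics
studies, with left-censored missing data handled by uncertainty-propagating
("soft") imputation.

## The problem

A standard metabolomics analysis ranks metabolites by running one logistic
regression per metabolite against a binary outcome (case/control,
survivor/non-survivor) and then corrects the p-values for multiple testing
(Bonferroni, Benjamini–Hochberg). Those corrections control Type I error
but do nothing about *Type M* (magnitude) error: conditional on being
declared significant, effect estimates are systematically exaggerated, so
replication studies designed around them are underpowered. Metabolomics
data add a second problem: concentrations below the detection limit are
left-censored, and the common min/2 plug-in imputation biases effect
estimates further.

`metabshrink` implements, simulates, and benchmarks an alternative:

**Hierarchical logistic regression.** Each metabolite *j* keeps its own
univariate model

    logit p_ij = α_j + β_j x_ij,        i = 1…n samples,

but the log-odds coefficients share a t-distribution prior centred at zero,

    β_j ~ t(ν, 0, σ),   σ ~ half-Cauchy(0, 1),   ν ~ gamma(2, 0.1), ν ≥ 1,
    α_j ~ N(0, 5)  (no pooling),

so the data decide how much the β_j are shrunk toward each other. A
metabolite is declared significant when P(β_j < 0) or P(β_j > 0) exceeds
0.975. Posterior means, not MLEs, are the reported effect sizes.

**Two-stage soft imputation.** Stage 1 regresses each metabolite on its
`c = 8` most-correlated metabolites inside a left-censored likelihood
(observed cells contribute a normal density, censored cells the normal CDF
up to the detection threshold `t_j`), producing a posterior mean `E_ij`
and sd `S_ij` per missing cell. Stage 2 re-fits the hierarchical logistic
model with each missing value as a latent draw from
`N(E_ij, S_ij)` truncated above at `t_j`, so imputation uncertainty flows
into the effect-size posteriors instead of being discarded.

**Evaluation suite.** A class-conditional Gaussian simulator (learned or
synthetic per-class means/covariances, a controlled fraction of truly
different metabolites, beta-distributed per-metabolite censoring rates)
plus power, FDR, and the **average exaggeration ratio**
`AER = mean over significant-and-true j of |β̂_j / β_j|`, the study's
Type M proxy. Frequentist baselines (raw/Bonferroni/BH on naive-imputed
data) are built in for matched comparisons.

MCMC runs on JAGS via `rjags`. Data live in a `MetaboSet`, a thin
`SummarizedExperiment` subclass (metabolites × samples, `NA` = censored,
outcome in `colData`).

## Worked example

Simulate a 27-metabolite, 100-per-group study in which 40% of metabolites
truly differ between outcome classes, then compare the hierarchical model
with Bonferroni-corrected logistic regression:

```r
library(metabshrink)
set.seed(11)
params <- syntheticClassParams()          # 27-metabolite synthetic panel
truth  <- assignTruth(params, fractionSignificant = 0.4, nPerGroup = 100)
truth  <- oracleTrueBeta(truth, params, oracleN = 1e6)
sim    <- generateDataset(truth, params, nPerGroup = 100)

fit  <- fitMultilevelLogistic(sim, learnedPrior(),
                              mcmcControl(chains = 2, iter = 1000))
fit
#> PosteriorSummary: 27 metabolites | 9 significant | scenario learned
#>   hyper: sigma = 0.426, nu = 17.39 | converged: TRUE

freq <- fitUnivariateLogistic(sim)
aer(posteriorSummary(fit)$betaMean, truth@trueBeta,
    classifySignificant(fit), truth@trulyDifferent)
#> [1] 0.9329503
aer(freq$beta, truth@trueBeta, freq$sigBonferroni, truth@trulyDifferent)
#> [1] 1.034388

shrinkageSlope(posteriorSummary(fit)$betaMean, freq$beta)
#> SlopeComparison: slope 0.898 (95% CI 0.889-0.906), P(slope < 1) = 1.0000
```

Both procedures find the same 9 truly-different metabolites here
(power 0.82, FDR 0), but the hierarchical posterior means carry an
exaggeration ratio of 0.93 versus 1.03 for the frequentist MLEs: the
significant Bayesian estimates are, on average, the right size rather than
inflated. The regression of Bayesian on frequentist effect sizes has slope
0.90 with P(slope < 1) ≈ 1 — the visible signature of partial pooling.

For censored data, the pipeline is

```r
cens <- injectMissingness(sim,
          buildMissingness(syntheticMissingRates(), r = 0.3,
                           maxRate = 0.4, m = 27))
imp  <- fitCensoredImputation(cens, c = 8)              # stage 1
post <- fitLogisticWithUncertainty(cens, imp)           # stage 2
```

A ready-made grid driver (`runGrid()`, or
`inst/scripts/simulate_grid.R` from a shell) repeats this over scenarios
and replicates and aggregates the metrics.

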