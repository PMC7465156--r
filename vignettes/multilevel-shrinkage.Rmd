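---
title: "Shrinkage estimation and soft imputation for two-group metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shrinkage estimation and soft imputation for two-group metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models implemented in
`metabshrink`, the assumptions behind the simulator, and the numerical and
design choices a maintainer should know about. It states no empirical
claims beyond what the package's test suite and `scripts/acceptance.R`
themselves compute.

## 1. Setting and data model

The package targets targeted metabolomics studies (NMR or MS, quantified
to a concentration table) with a binary outcome per sample: `n` samples,
`m` metabolites, typically `m` in the tens and `n` in the tens to
hundreds. Data enter as a `MetaboSet`. Preprocessing (`preprocess()`)
follows the field's standard pipeline:

1. drop metabolites whose missing rate is **not strictly below** the
   threshold (default 0.30) — the keep rule is `rate < threshold`, so a
   metabolite at exactly 30% is dropped;
2. natural-log transform the observed concentrations (the log base is
   immaterial once autoscaling follows: any base rescales each column by a
   constant that z-scaling removes);
3. z-scale each metabolite over its **observed** entries only — missing
   cells have no value to contribute, and they stay missing.

The per-metabolite log-scale mean and sd are kept in `rowData` so later
steps can map raw-scale conventions through the same transform. Observed
concentrations must be positive; an exact zero in an input table is read
as a censored cell, because a concentration of 0 is below any detection
limit and has no finite log.

## 2. The hierarchical logistic model

Each metabolite gets its own univariate logistic regression of the
outcome, and the slopes are tied together by a shared t-prior:

$$\mathrm{logit}(p_{ij}) = \alpha_j + \beta_j x_{ij}, \qquad
\beta_j \sim t(\nu, 0, \sigma), \qquad \alpha_j \sim N(0, 5).$$

Hyperpriors: $\sigma \sim$ half-Cauchy(0, 1); $\nu \sim$ gamma(2, 0.1)
constrained to $\nu \ge 1$. The gamma is shape/rate (mean 20), the
convention of the probabilistic-programming ecosystems this class of model
is usually written in. The intercepts are deliberately not pooled: the
$\beta_j$ are the parameters of scientific interest.

Why a t rather than a normal prior: with $\nu$ learned, the model can
interpolate between aggressive normal-like shrinkage (large $\nu$) and a
heavy-tailed regime (small $\nu$) that shrinks small coefficients hard
while letting genuinely large ones escape. Significance is declared when
`max(P(β<0), P(β>0)) > 0.975` — strictly greater, computed as the fraction
of pooled post-warmup draws on each side of zero — which corresponds to a
95% credible interval excluding zero. The reported effect size is the
posterior mean.

`PriorScenario` captures four regimes: `learned` (default),
`fixedNuPrior(1)` (thick tails, only $\sigma$ learned),
`weaklyInformativePrior(100, 5)` (both fixed; the hierarchy disappears and
each metabolite gets an independent, nearly flat normal prior — this is
the bridge case that should, and in the test suite does, track frequentist
maximum likelihood closely), and `sigmaBoundedPrior(0.1)` (a lower bound
on $\sigma$ that guards against over-shrinkage when few effects are
non-null, a failure mode the heavy pooling can hit when the true fraction
of affected metabolites is small).

**Sampling.** Inference is MCMC via JAGS (`rjags`). The model declaration
is authored in this package; JAGS supplies the samplers, in the same role
a Hamiltonian Monte Carlo engine would. Defaults (`mcmcControl()`): 4
chains, 500 adaptation + 500 burn-in, 1000 retained iterations per chain.
Convergence is diagnosed with split-free Gelman–Rubin $\hat R$ (flag at
1.1) and pooled effective sample size; a failing fit is returned but
flagged and warned about, never silently accepted. Chain seeds derive
from the session RNG, so `set.seed()` makes every fit reproducible.

## 3. The simulator

The simulator generates data on the post-preprocessing (log-z-scaled)
scale from class-conditional multivariate normals:

$$X_i \sim N(\mu_D, \Sigma_D) \text{ (event class)}, \qquad
  X_i \sim N(\mu_S, \Sigma_S) \text{ (non-event class)}.$$

Parameters can be learned from a reference dataset
(`learnClassParams()`: per-class sample means and unbiased covariances;
pairwise-complete estimation with nearest-PSD projection is available for
data with missing cells) or taken from `syntheticClassParams()`, a
deterministic 27-metabolite fixture shipped so the study runs without any
external download. The fixture is labelled synthetic throughout: it
emulates the broad structure of a quantified serum NMR panel (four
correlated blocks, within-block correlation 0.45; group sizes 122/106;
class mean differences ramping from ~0 to 0.9 z-units with alternating
signs; per-class sds 0.8–1.25) but is not derived from measured data.
Users chasing a specific study's numbers should learn `ClassParams` from
that study's table instead.

**Truth assignment.** A scenario marks a fraction of metabolites as truly
different. Selection probability is proportional to the absolute Welch
t-statistic
$TS_j = |\mu_{Dj}-\mu_{Sj}| / \sqrt{\sigma^2_{Dj}/n_D + \sigma^2_{Sj}/n_S}$,
normalized to $p_j = TS_j / \sum_k TS_k$; metabolites are drawn without
replacement with successive renormalization (the standard weighted
sampling scheme) until at least `ceiling(fraction * m)` are selected.
Non-selected metabolites have both class means set to zero, so they carry
no mean difference. If every $TS_j$ is zero the selection falls back to
uniform with a warning. When the target count exceeds the number of
positive-weight metabolites, the remainder is drawn uniformly from the
zero-weight ones.

**True effect sizes.** The Gaussian generative model does not come with a
"true log-odds coefficient" in closed form (except when class variances
are equal, where the discriminant-analysis identity
$\beta = (\mu_D-\mu_S)/\sigma^2$ holds — the test suite checks this
limit). The package therefore *defines* the oracle effect
operationally: `marginalTrueBeta()` draws `oracleN` (default $10^6$)
samples per class from each metabolite's marginal and fits a univariate
ML logistic regression; the slope is the true $\beta_j$. Because truth
assignment only zeroes out non-selected metabolites, this table depends
only on the `ClassParams` and is computed once per grid, not per
replicate. Non-selected metabolites have $\beta_j = 0$ exactly (their two
class marginals are symmetric about a common mean).

**Missingness.** Per-metabolite missing rates come from a beta
distribution fitted by method of moments to a reference missing-rate
distribution (zero rates excluded — a point mass at zero is outside the
beta family), then rescaled to the target average rate $r$:
$\hat\mu_\beta = r$ and $\hat\sigma^2_\beta = (r/\mu_\beta)\sigma^2_\beta$,
i.e. the variance scales proportionally with the mean. If the rescaled
pair is not a valid beta moment pair the variance is shrunk to
$0.95\,\hat\mu(1-\hat\mu)$ with a warning. Draws are truncated at the
maximum missing rate (study default 0.4). Censoring is by left quantile:
for metabolite $j$, all values strictly below the empirical $m_j$-quantile
(type-7, linear interpolation, pooled across both classes — the pooled
choice mirrors how a shared instrument detection limit acts on a whole
sample set) are hidden. The pre-censoring matrix is retained in a
`trueValues` assay for scoring, never shown to the models.

**What the simulator does not emulate:** batch effects, technical
replicates, non-Gaussian marginals (heavy tails, zero inflation beyond
censoring), missingness mechanisms other than left-censoring, and
outcome-dependent censoring. Passing tests therefore demonstrate correct
behaviour under the stated generative model, not robustness to all real
data pathologies.

## 4. Two-stage soft imputation

**Stage 1** (`fitCensoredImputation()`): for each metabolite $j$, a linear
regression on its `c` most-correlated metabolites (default `c = 8`),
with the likelihood split by the missing indicator: observed cells
contribute $N(x_{ij} \mid \beta_{-j}^T x_{i,-j} + a_j, \sigma_j)$;
missing cells contribute $\Phi((t_j - \mu_{ij})/\sigma_j)$, the
probability mass below the censoring threshold. In the sampler, missing
values are latent parameters supported on $(-\infty, t_j]$, so their
posterior mean $E_{ij}$ and sd $S_{ij}$ come out of the same fit. Choices
worth recording:

* **Thresholds** $t_j$ default to the minimum observed value per
  metabolite — the natural detection-limit proxy, consistent with the
  min/2 convention, and an upper bound on every hidden value under
  quantile censoring. They are an explicit argument, so a user with known
  limits of detection can supply them.
* **Predictor sets and values** are fixed once, from a naive-completed
  working matrix, before sampling (not updated within MCMC). This keeps
  the m regressions a linear model rather than a joint nonlinear system.
* **Naive completion on the z scale**: min/2 imputation is defined on the
  concentration scale; on log-z-scaled data the same substitution maps to
  $z_{\min} - \log(2)/\mathrm{logSd}$, with logSd = 1 for data generated
  directly on the z scale. The package applies this pull-back rather than
  halving z-scores, which would be meaningless for negative values.
* **One joint fit**: all m regressions share a single coefficient-prior
  scale $\sigma_{\beta_{-}} \sim$ half-normal(0, 1) (ridge-like pooled
  shrinkage), so they are fitted jointly in one model. Intercepts and
  residual scales use effectively flat priors (diffuse normal;
  uniform(0, 100) on a z scale where residual sds are below ~1.5).
* A metabolite with no missing cells is still included (it informs the
  shared scale and serves as a predictor) but contributes no $E/S$
  entries; with no missing cells anywhere the model degrades gracefully
  to a ridge-like multivariate regression with an empty imputation
  posterior.

**Stage 2** (`fitLogisticWithUncertainty()`): the hierarchical logistic
model with each missing $x_{ij}$ replaced by a latent variable

$$\hat x_{ij} \sim N(E_{ij}, S_{ij}) \text{ truncated to } (-\infty, t_j],$$

re-sampled within the MCMC (full Bayes, not plug-in multiple imputation).
With no missing cells stage 2 *is* the complete-data model (the code
delegates); as $S_{ij} \to 0$ it collapses to hard imputation at
$E_{ij}$ — both limits are exercised in the tests. The stage-1/stage-2
interface is just the triple $(E, S, t)$, so any external imputation
method that reports per-cell uncertainty can be slotted in.

## 5. Baselines and metrics

Frequentist baselines use `stats::glm` MLEs with Wald p-values (the
ecosystem default; the paper-style comparison does not specify the test,
and Wald is what the standard summary reports), corrected with
`stats::p.adjust` (Bonferroni, BH) at $\alpha = 0.05$, after min/2
imputation when data are censored. Perfect separation is flagged and
warned, not fatal.

Metrics per replicate: power $TP/(TP+FN)$ (undefined when nothing is truly
different), FDR $FP/(TP+FP)$ with the $0/0 \to 0$ convention (no
discoveries means no false discoveries), and the average exaggeration
ratio over the significant-and-true set,
$\mathrm{AER} = \frac{1}{|ST|}\sum_{j \in ST} |\hat\beta_j / \beta_j|$,
undefined (and excluded from scenario averages) when $ST$ is empty.
Imputation quality uses the certainty weights
$w_{ij} = 1 - S_{ij}/\max S_{ij}$ and a weighted Pearson correlation
(weighted first/second moments with weights normalized to sum one —
interpreted as the weighted correlation coefficient; if all sds are equal
the formula degenerates to zero weights everywhere, a recorded caveat).
The shrinkage comparison regresses Bayesian posterior means on
frequentist MLEs under a flat-prior Bayesian linear regression; that
posterior is normal-inverse-chi-square in closed form, so the package
draws from it exactly instead of running MCMC.

## 6. Problem sizes and reproducibility

The full study design is 200 replicates per scenario; `runGrid()` defaults
to each config's `nSimulations` and derives per-replicate seeds
deterministically from one global seed, so any replicate can be re-run in
isolation. The packaged test suite and the acceptance script use desk
scale sizes chosen to keep a complete run in minutes on one CPU while
leaving the Monte-Carlo orderings decisive: 20 replicates for the
complete-data ordering study, 10 for the prior-sensitivity comparison, 5
for the missing-data study, 50 (frequentist-only) for null calibration,
and 2 chains × (300 adapt + 200 burn-in + 500 retained) iterations for
MCMC fits, with the oracle at its default $10^6$ draws per group in the
acceptance script and $10^4$–$10^5$ in unit tests. Convergence flags are
checked at these sizes; scaling `--replicates 200` and the default
`mcmcControl()` reproduces the full-scale design.

## 7. Known limitations

* The model family is univariate-ranking by design; no joint
  multi-metabolite outcome model is provided.
* Heavy pooling can over-shrink when the true fraction of affected
  metabolites is small; `sigmaBoundedPrior()` is the provided mitigation,
  and the prior-sensitivity scenarios exist precisely to probe this.
* Stage 1 assumes the censoring threshold is the smallest observed value;
  a metabolite whose missingness is not left-censored (e.g. missing at
  random) violates the likelihood's support assumption.
* JAGS slice sampling handles these posteriors well at the package's
  scale (tens of metabolites, hundreds of samples); very large panels
  with high missingness will be slow, as any full-Bayes treatment of
  per-cell latent values is.
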