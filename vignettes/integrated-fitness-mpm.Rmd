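---
title: "Integrated fitness from transplant censuses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated fitness from transplant censuses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpmfit)
```

## The problem

Reciprocal transplant experiments test local adaptation by growing
genotypes from contrasting environments in each other's home sites. For
perennial plants a single fitness component (seed number, survival) is not
sufficient: fitness accrues over successive seasons, and investment in one
component trades off against others. `mpmfit` integrates individual-level
census records — who was alive at each seasonal census, who flowered each
year, how many mature seeds they set — together with a seedling
establishment trial, into a single demographic currency: the asymptotic
population growth rate $\lambda$ of a genotype in an environment.

The package covers the full chain: individual census table $\to$ vital
rates $\to$ seasonal age-structured projection matrix $\to$
eigenanalysis ($\lambda$, stable stage distribution, reproductive values,
sensitivities, elasticities) $\to$ fixed-design LTRE decomposition of
local-vs-foreign differences $\to$ population-stratified bootstrap with
bias-corrected confidence intervals. A seeded individual-based simulator
generates cohorts with the exact stochastic structure the estimators
assume, so the whole pipeline is testable without field data.

## The model

The life cycle is discretised into ordered seasonal stages alternating
summers and winters: $S_1, W_1, S_2, W_2, S_3$ by default (three growing
seasons, five censuses). Two kinds of vital rates parameterise the
projection matrix $A$:

* **Survival** $T_i$: the proportion of individuals alive at census $i$
  that are still alive at census $i+1$. These sit on the subdiagonal of
  $A$, moving survivors one seasonal age class forward per step.
* **Composite reproduction** $R_i = F_i \cdot N_i \cdot E$ for each
  reproductive year $i$ (summer): the product of the flowering probability
  $F_i$ (flowered, given alive at that summer census), the mean number of
  mature seeds per flowering plant $N_i$, and the establishment
  probability $E$ (a sown seed germinates and survives its first growing
  period). These sit in the first row of $A$ at the summer columns:
  offspring enter the first stage one projection step after reproduction.
  Because $E$ already carries the seed-to-seedling filter, the recruits'
  subsequent winter survival is carried by $T_1$ and is not double
  counted.

$\lambda$ is the dominant eigenvalue of $A$; the right eigenvector $w$
(normalised to sum to 1) is the stable stage distribution, the left
eigenvector $v$ (scaled so $\langle v, w\rangle = 1$) holds reproductive
values, the sensitivity matrix is $s_{ij} = v_i w_j$ and the elasticity
matrix $e_{ij} = (a_{ij}/\lambda)\, s_{ij}$, which for a primitive matrix
sums to one.

All estimators are pooled closed-form ratios. The field analyses that
motivated this package used binomial GLMMs with family and block random
intercepts for single vital rates; those single-rate inferential models
are out of scope here. For the integrated estimate, with a balanced design
and weak random effects the pooled proportion approximates the marginal
rate, and the closed form keeps every estimator exactly checkable against
hand-computed ratios and makes the 20,000-replicate bootstrap cheap. The
three source populations of a genotype are pooled *before* estimating the
genotype-level rates; the bootstrap below is stratified by population, so
the population structure still governs the resampling uncertainty.

### Undefined seed numbers

If nobody flowered in year $i$, $N_i$ has no empirical value. When
$\hat F_i = 0$ too, the model needs no seed number: $R_i = 0$. When
$\hat F_i > 0$ but seed counts are missing, the package raises an error
rather than imputing — that situation indicates a data defect, not a
demographic zero.

## LTRE: decomposing a growth-rate difference

The fixed-design life-table response experiment compares the foreign
genotype's matrix against the local genotype's matrix within one
environment:

$$\lambda^{foreign} - \lambda^{local} \approx \sum_{ij}
  \left(a_{ij}^{foreign} - a_{ij}^{local}\right) \,
  s_{ij}\!\left(A^*\right),$$

with sensitivities evaluated at the midpoint matrix
$A^* = (A^{local} + A^{foreign})/2$ by default. Entry contributions are
aggregated per vital rate ($T_1, T_2, \ldots, R_1, \ldots$), and the
first-order residual `approx_error` is reported. The midpoint choice is
deliberate: it makes the decomposition symmetric under swapping the roles
of the two matrices, and the midpoint rule cancels the quadratic error
term, so the residual is *third*-order in the matrix difference (halving
all perturbations shrinks it roughly eightfold, verified in the test
suite). Evaluating at the reference matrix instead
(`sensitivity = "reference"`) gives the classical first-order variant
whose residual shrinks fourfold under halving; both are available because
published analyses do not always state which variant was used.

### Elasticity shift and distance

To describe how the environment reshapes the relative importance of vital
rates, per-population elasticities are summarised by two descriptors: the
**shift** (a population's elasticity for a vital rate at its home
elevation minus the same quantity away) and the **distance** (its home
elasticity minus the mean home elasticity of the opposite genotype's
populations). Their Pearson correlation is reported descriptively, with
no significance test: elasticities are mutually dependent outputs of the
same fitted model, so a test would be meaningless.

## Bootstrap and bias-corrected intervals

Uncertainty in everything downstream of the census tables is quantified
by resampling individuals with replacement *within each source
population* (and establishment pots within population), preserving every
population's sample size exactly, then re-running the entire estimation
pipeline per replicate. The default is $B = 20{,}000$ replicates.

Intervals are bias-corrected (BC) percentile intervals:
$z_0 = \Phi^{-1}(\text{fraction of replicates strictly below the point
estimate})$, and the interval endpoints are the empirical replicate
quantiles at levels $\Phi(2z_0 \pm z_{1-\alpha/2})$. No acceleration
constant is used by default — BC, not BCa — because the method this
package operationalises specifies bias correction only; a jackknife-based
BCa variant is available in the generic bootstrap via `ci = "bca"`.

Two implementations exist and are tested against each other:

* `stratified_bootstrap()` resamples data frames and re-runs an arbitrary
  statistic — fully general, used for custom statistics.
* `bootstrap_growth_rate()` exploits the fact that every estimator in the
  pipeline is a pooled ratio: resampling $n$ individuals with replacement
  within a population is equivalent to drawing a multinomial weight
  vector, so all replicate vital rates are weighted column sums, and only
  the $5\times 5$ eigenvalue extraction loops over replicates. This makes
  the 20,000-replicate default run in seconds.

**Degenerate replicates.** A resample may leave some census with zero
survivors (a survival ratio becomes $0/0$) or nobody flowering in any
year (the matrix loses its reproductive loop, becomes nilpotent, and
$\lambda = 0$ is not a meaningful growth rate). Such replicates are
excluded from the interval and counted in `n_degenerate`; a warning is
emitted if they exceed 1% of $B$. Genotype comparisons difference the two
(independently resampled) replicate vectors index by index and attach a
BC interval to the difference; the percent advantage is
$100(\lambda_{local}/\lambda_{foreign} - 1)$.

## The synthetic-cohort generator

`generate_cohort()` draws one row per transplanted individual under the
design of a two-elevation reciprocal transplant: 4 sites (two per
elevation), ~500 individuals per site, 2 genotypes $\times$ 3 source
populations each, 20 maternal families per population, 8 blocks per site,
and the 5-census seasonal calendar. Survival is a chain of per-season
Bernoulli draws conditional on being alive; flowering is Bernoulli
conditional on being alive at that summer; seed counts are zero-inflated
Poisson conditional on flowering (structural-zero probability $\pi$,
Poisson mean $\mu$, so the mean seed number per flowering plant is
$(1-\pi)\mu$; a negative-binomial alternative is available).
`generate_establishment()` draws pot trials (~10 seeds per pot, 120 pots
per site by default) as binomial counts.

Default parameter values are a deliberate, fixed choice emulating a
short-lived alpine perennial with strong elevational adaptation: the
low-elevation genotype flowers early and heavily but pays with summer
mortality at home; the high-elevation genotype delays reproduction and
survives winters well at home; establishment is around 10% of sown seeds
at low elevation and 3%–5% at high elevation. Under these defaults the
true growth rates are roughly 1.26 (low genotype at home), 0.90 (high
genotype at low elevation), 0.77 (high genotype at home) and 0.58 (low
genotype at high elevation) — a local advantage of order 30%–40% at both
elevations, the magnitude reported for strongly adapted elevational
ecotypes. Within-family variance is not empirically constrained, so
family/block random intercepts (`family_sd`, `block_sd`, logit/log scale)
default to zero; that keeps the configured rates exactly equal to the
marginal rates, which is what makes the estimator-recovery oracles exact.
The generator produces post-exclusion cohorts: deaths from transplant
shock, which field protocols discard, are not modelled.

What the generator does *not* emulate — and what passing tests therefore
do not certify about real data: spatial autocorrelation among blocks,
climate covariates and year effects, non-independence of survival and
flowering within individuals beyond the alive-conditioning, gene flow, or
size structure. It validates the estimation machinery, not the biology.

## Numerical choices

* **Eigenanalysis** is a direct dense `eigen()` decomposition — matrices
  here are at most ~10 stages — with a power-iteration oracle in the test
  suite, never in the production path. When the spectral circle carries
  several eigenvalues (periodic chains), the real positive Perron root is
  preferred and `primitive = FALSE` is flagged; a complex-only dominant
  pair yields the spectral radius with eigenvector quantities `NA`.
* **Terminal stage:** truncation by default (no survival out of the last
  observed stage). Truncation adds no unobserved parameter, and both
  genotypes get identical topology, so $\lambda$ comparisons are
  internally consistent; a terminal self-loop reusing the last seasonal
  survival is available (`topology = "selfloop"`).
* $\lambda$ is a **per-projection-step** rate and steps alternate summer
  and winter of unequal calendar length; no calendar-time conversion is
  attempted, and all comparisons are between matrices with identical
  stage structure.
* **Seeding:** every stochastic function takes an explicit integer seed
  and restores the caller's RNG state; the pipeline derives fixed
  per-module sub-seeds from one run seed, so changing $B$ never changes
  the simulated cohort and identical runs are byte-identical.
* **Ties and degenerate inputs:** zero at-risk at a transition is an
  error naming the transition (never a silent `NaN`); all-zero matrices
  are an error; reproductive-loop-free matrices are flagged, not fatal,
  so bootstrap replicates never abort.

## Problem sizes used by the test suite

The packaged checks run at sizes chosen to balance statistical resolution
against a laptop-scale test run:

* estimator recovery: cohorts of $n = 10{,}000$ per genotype $\times$
  elevation stratum, every configured rate recovered within 4 binomial
  (or zero-inflated-Poisson) standard errors, and $\hat\lambda$ within
  0.02 of the truth. The establishment trial is sized larger
  (5,000 pots/site, i.e. 50,000 sown seeds per stratum) because $E$
  multiplies every $R_i$: at matched sample sizes, $E$'s sampling noise
  alone would dominate $\hat\lambda$'s error and the 0.02 band would be a
  test of the establishment trial rather than of the census estimators.
* bootstrap calibration: $B = 500$ replicates, 200 simulated cohorts of
  the study's per-stratum size (~500 individuals in 3 populations);
  the 95% BC interval covers the true $\lambda$ in 90%–99% of repeats,
  and under a genotype-symmetric generator the difference interval
  excludes zero in 2%–10% of repeats.
* eigen properties: 200 random primitive seasonal matrices with 3–6
  stages; elasticities sum to 1 within $10^{-10}$, the sensitivity
  formula matches central differences within $10^{-4}$, and $\lambda$
  matches power iteration within $10^{-8}$.

## Known limitations

* Pooled-ratio estimators ignore family/block random effects; with a
  strongly unbalanced design or large variance components the pooled
  proportion is not the marginal rate.
* No density dependence, no environment-varying (stochastic) $\lambda$,
  no periodic seasonal matrix products, no integral projection models.
* The matrices cover the observed early life cycle only; truncation means
  $\lambda$ is the growth rate of the observed three-year window, and
  longer-lived dynamics are outside the fitted model.
* The resampling unit is the individual (and the pot); block-level
  resampling and parametric bootstraps are not offered.
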