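# mpmfit

Integrated-fitness demographic analysis for multi-year reciprocal
transplant experiments on perennial plants.

When genotypes from contrasting environments (say, low- and high-elevation
ecotypes of an alpine perennial) are transplanted into each other's home
sites, no single fitness component tells the whole story: flowering,
seed set, establishment and season-by-season survival all contribute, and
they trade off against each other. `mpmfit` integrates individual-level
census records into a single currency — the population growth rate
$\lambda$ of a seasonal age-structured matrix population model (MPM) —
and asks the local-adaptation questions directly in that currency.

For each genotype × environment stratum the package estimates:

* seasonal survival vital rates $T_i$ (proportion of individuals
  transitioning between consecutive summer/winter censuses), and
* composite yearly reproductive rates
  $R_i = F_i \cdot N_i \cdot E$ — flowering probability × mean mature
  seed number per flowering plant × seedling establishment probability
  (from pot-sowing trials),

builds the Leslie-type seasonal projection matrix (survival on the
subdiagonal, reproduction in the first row at the summer columns),
and computes $\lambda$, stable stage distribution $w$, reproductive
values $v$, sensitivities $s_{ij} = v_i w_j$ and elasticities
$e_{ij} = (a_{ij}/\lambda) s_{ij}$. Local-vs-foreign contrasts come with:

* a **fixed-design LTRE** (life-table response experiment) decomposing
  $\lambda_{foreign} - \lambda_{local}$ into per-vital-rate contributions
  $(a_{ij}^{f} - a_{ij}^{l})\, s_{ij}(A^*)$ at the midpoint matrix
  $A^*$,
* a **population-stratified bootstrap** (individuals and pots resampled
  with replacement within source populations; default 20,000 replicates)
  with **bias-corrected (BC) percentile intervals**, paired-difference
  intervals, and percent-advantage summaries,
* **elasticity shift/distance** descriptors of how the environment
  reshapes the relative importance of each vital rate.

A seeded individual-based cohort simulator (`generate_cohort()`,
`generate_establishment()`) reproduces the stochastic structure the
estimators assume — Bernoulli seasonal survival chains, Bernoulli
flowering, zero-inflated Poisson seed counts, binomial establishment — so
the entire pipeline is testable end to end without any field data.

See the methods vignette (`vignettes/integrated-fitness-mpm.Rmd`) for the
model, the estimators, the interval construction and all design choices.

## Worked example

```r
library(mpmfit)
cfg <- simulation_config(n_individuals_per_site = 500)  # default design
report <- run_pipeline(config = cfg, B = 2000, seed = 42)
print(report)
```

```
Reciprocal-transplant demographic analysis
  individuals: 2000, pots: 480, B = 2000, seed = 42
  lambda[low.low] = 1.2137  BC CI [1.1195, 1.3057]
  lambda[high.low] = 0.9035  BC CI [0.8357, 0.9812]
  lambda[low.high] = 0.5746  BC CI [0.5157, 0.6368]
  lambda[high.high] = 0.7582  BC CI [0.7015, 0.8128]
  low elevation: local advantage 34.3% (difference CI excludes 0)
  high elevation: local advantage 32.0% (difference CI excludes 0)
  LTRE low: delta lambda = -0.3103, largest contribution R1
  LTRE high: delta lambda = -0.1836, largest contribution R3
  elasticity shift~distance correlation: 0.906
```

Reading this: each `lambda[genotype.elevation]` is the per-season growth
rate of that genotype in that environment with its 95% bias-corrected
bootstrap interval. At both elevations the local genotype's $\lambda$
exceeds the foreign one's (here by 34% and 32%), and the bootstrap
difference interval excludes zero — the local-vs-foreign criterion of
local adaptation in integrated-fitness terms. The LTRE lines name the
vital rate contributing most to the foreign genotype's deficit: first-year
reproduction (`R1`) at low elevation, third-year reproduction (`R3`) at
high elevation, matching the generator's built-in life-history contrast.

The intermediate objects are all inspectable:

```r
report$vital_rates[["low.low"]]
#> Vital rates: genotype=low, environment=low
#>   T: T1=0.5398 T2=0.8376 T3=0.5286 T4=0.8250
#>   F: F1=0.1574 F2=0.4978 F3=0.6364
#>   N: N1=24.28 N2=35.95 N3=35.71
#>   E: 0.1067
#>   R: R1=0.4075 R2=1.9087 R3=2.4242

report$ltre$low
#> LTRE (midpoint sensitivities): delta lambda = -0.31028
#> contributions:
#>       T1       T2       T3       T4       R1       R2       R3
#> -0.08912 -0.00814 -0.00807 -0.00121 -0.09943 -0.07051 -0.03367
#> approximation error: -1.24e-04
```

A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "mpmfit.R", package = "mpmfit"))')" \
  run --config config.yaml --out-dir out --reps 20000 --seed 1
```

with subcommands `simulate`, `validate`, `estimate`, `project`, `ltre`,
`bootstrap` and `run` (see `config_to_yaml()` for the config format).

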