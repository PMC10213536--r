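# strongties

Do strong social ties — kinship and friendship — push middle-aged and
older adults toward *formal* long-term care (home, community or
institutional services) instead of family care? `strongties` implements a
complete, simulation-backed version of that analysis for R: a synthetic
survey-microdata generator with a known data-generating process, composite
tie-strength indices, binary-choice model batteries, and a compartmental
diffusion model of the formal-care market. Because real ageing-survey
microdata of this kind are access-restricted, every quantitative claim is
made on the synthetic population, where the truth is known and the whole
pipeline can be validated as a parameter-recovery exercise.

It is aimed at quantitative social scientists and biostatisticians who
want a tested reference implementation of this analysis style: composite
index construction with PCA/KMO diagnostics, logit/probit ML with the
usual robustness/heterogeneity/mechanism batteries, and an analytically
solvable SIRS diffusion model.

## What is implemented

**Indices.** The kinship index is the log of total reciprocal economic
transfers over five relative categories,
`hosnet_R = ln(1 + Σ give + Σ receive)`; the friendship index `hosnet_F`
is the first principal component of three standardised social-interaction
indicators (ceremonial spending, guest meals, activity count), screened by
the Kaiser–Meyer–Olkin measure

    KMO = Σ r²ᵢⱼ / (Σ r²ᵢⱼ + Σ p²ᵢⱼ),   p = partial correlations,

retaining components with eigenvalue ≥ 1. Robustness variants: `clan`
(any transaction) and `friend` (0–6 contact frequency).

**Estimation.** `fit_binary()` is Newton–Raphson maximum likelihood for
binary logit and probit,

    logit(P) = ln P/(1−P) = α + Σ βᵢ Xᵢ,

with observed-information standard errors, odds ratios for logit fits,
McFadden (adjusted) pseudo-R², listwise deletion, and explicit errors for
rank deficiency and separation. Battery functions reproduce the standard
table layout: baseline, robustness (replacement regressors + probit),
heterogeneity (region and urban/rural splits) and mechanism (index →
medical insurance → care choice, including a healthy-only subsample).

**Diffusion model.** A SIRS system for the formal-care market — S never
considered formal care, I risk-aware but undecided, R formal-care users —
with bilinear incidence αSI, adoption βI, reversion δI and abandonment λR.
Closed-form steady states (`S* = (β+δ)/α`, endemic iff αN > β+δ), RK4
simulation with conservation checks, and comparative statics showing S*
strictly falling in tie strength α.

## Worked example

```r
library(strongties)

d <- add_indices(generate_population(generator_config(n = 20000, seed = 1)))$data
fit_binary(d, model_spec("care_all", c("hosnet_R", care_controls())))
```

```
Binary logit fit: care_all ~ hosnet_R + age + gender + edu + married + health + insurance + l_expen + family + urban + province
            odds_ratio      z        p sig
(Intercept)     0.0124 -19.84 1.27e-87 ***
hosnet_R        1.0881   9.42 4.43e-21 ***
age             1.0352  18.46 4.31e-76 ***
gender          1.0663   1.78 7.47e-02   *
edu             0.9349  -1.24 2.15e-01
married         0.8740  -2.74 6.18e-03 ***
health          1.0559   1.32 1.87e-01
insurance       1.3285   2.43 1.51e-02  **
l_expen         1.0328   1.84 6.56e-02   *
family          1.0100   0.93 3.51e-01
urban           0.9646  -0.91 3.63e-01
province        1.3946   8.81 1.21e-18 ***
n = 20000, log-lik = -9690.358, McFadden adj. R2 = 0.0251
```

The fitted kinship odds ratio 1.088 recovers the generating value 1.091
(its DGP truth) within sampling error: each extra log-yuan of reciprocal
transfers multiplies the odds of choosing formal care by about 1.09,
holding the ten controls fixed. The diffusion side is one call:

```r
sirs_steady_state(sirs_params(alpha = 1, beta = 0.2, lam = 0.3, delta = 0.1))
#> SIRS equilibrium: S* = 0.3, I* = 0.42, R* = 0.28 (endemic)
```

so with these rates 30% of the population never considers formal care at
equilibrium — and that share is exactly `(β+δ)/α`, falling as social
contact intensifies.

## The analysis workflow

The `analysis/` scripts run the full study in order, writing tables under
`results/analysis/`:

```sh
Rscript analysis/01_simulate.R   # synthetic population + descriptives
Rscript analysis/02_indices.R    # indices + KMO/PCA diagnostics
Rscript analysis/03_fit.R        # baseline/robustness/heterogeneity/mechanism
Rscript analysis/04_sirs.R       # equilibria + comparative statics
```

`run_pipeline(run_config(...))` does the same end-to-end with a manifest
of MD5 checksums; identical configs reproduce identical checksums.

## Package layout

- `R/generator.R` — `generator_config()`, `generate_population()`
- `R/indices.R` — `kinship_index()`, `friendship_index()`, `kmo()`,
  `clan_indicator()`, `friend_frequency()`, `add_indices()`
- `R/fit.R`, `R/batteries.R` — `fit_binary()` and the four batteries
- `R/sirs.R` — `sirs_params()`, `sirs_derivatives()`,
  `sirs_steady_state()`, `sirs_simulate()`, `sirs_comparative_statics()`
- `R/pipeline.R`, `R/io.R` — orchestration, config validation, CSV layer
- `vignettes/strong-ties-care-choice.Rmd` — the methods vignette
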