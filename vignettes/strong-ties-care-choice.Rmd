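---
title: "Strong social ties and formal long-term-care choice: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strong social ties and formal long-term-care choice: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strongties)
```

## The question and the modelling strategy

Whether middle-aged and older adults choose *formal* long-term care (home,
community or institutional services) rather than rely on family care is, in
societies with strong kinship norms, shaped by their social networks. Two
kinds of strong ties are distinguished: **kinship** (blood and in-law
relations, observable through reciprocal economic transfers) and
**friendship** (business- and interest-based relations, observable through
social spending and interaction frequency). The package implements a
complete, simulation-backed version of that analysis:

1. a synthetic survey-microdata generator with a fully known
   data-generating process (DGP), emulating the structure of a CHARLS-style
   ageing survey;
2. composite tie-strength indices: a log-sum kinship index and a
   first-principal-component friendship index with Kaiser–Meyer–Olkin (KMO)
   screening;
3. binary logit/probit maximum likelihood with the full battery layout —
   baseline, robustness, heterogeneity, and mechanism (mediation-style)
   regressions;
4. a susceptible–infective–removed–susceptible (SIRS) diffusion model of
   the formal-care market with closed-form steady states.

Because real survey microdata of this kind are access-restricted, every
empirical claim the package makes is about the synthetic population, whose
truth is known; the analysis is then a parameter-recovery exercise rather
than a replication on restricted data.

## The synthetic population

Each respondent record carries: age (left-truncated normal, floor 45, mean
64.86, sd 10.21), nine further controls with Bernoulli or normal margins
calibrated to published first moments (urban 0.2888, east-province 0.3090,
social security 0.9697, married 0.8508, good health 0.2501, high-school+
0.1269, log expenditure N(7.1346, 1.0272²)), a household size (truncated
normal, mean 3.07, sd 1.84, cap 20 — the published descriptive table
duplicates the expenditure mean in the household-size row, so the size
level is taken from the companion descriptive split, which reports about
3.05–3.08 members), the five give/receive transfer pairs, the three
friendship indicators, a 0–6 contact frequency, a supplementary-medical-
insurance indicator and the binary care choice.

**Transfers.** Each of the ten give/receive cells is zero with probability
$p_0 = 0.454^{1/10} \approx 0.924$ and log-normal
$\mathrm{LN}(1.873, 2.3^2)$ otherwise. The two constants are calibrated so
that the share of respondents with *any* transfer is 0.546 and the kinship
index mean is 1.496; the heavy right tail and the exact zeros that the
published minimum/maximum imply come out of the zero-inflated log-normal
form directly.

**Friendship indicators.** Ceremonial/social spending (zero-inflated
log-normal), guest meals last week (zero-inflated Poisson) and a social-
activity count (Poisson) are drawn through a Gaussian copula with latent
equicorrelation 0.08. The copula is what makes the principal-component
step meaningful: it reproduces the weak positive dependence such items
show in surveys (overall KMO ≈ 0.515, leading eigenvalue just above 1, one
retained component). With a single dependence knob the KMO level and the
leading eigenvalue cannot both be matched exactly; the KMO level was
prioritised.

**Outcomes.** The insurance indicator is drawn first from a logit in the
two indices (friendship odds ratio 1.082); the care choice is then drawn
from a logit whose regressors are the *derived* indices, the insurance
indicator and the ten controls, with odds ratios 1.091 (kinship), 1.128
(friendship), 1.8 (insurance channel), 1.036 (age), 1.736 (social
security), 1.318 (east province) and the published values for the
remaining controls; the intercept −4.904 sets prevalence ≈ 0.1975.
Generating the outcome from the derived indices (rather than from latent
raw transfers) is deliberate: re-deriving the indices and refitting the
same logit *exactly* inverts the DGP, so parameter recovery is a clean
correctness test of the whole pipeline rather than an approximation claim.

An optional per-field missingness rate (independent Bernoulli; the default
is 0) exists solely to exercise listwise deletion; nothing in the
generator models informative missingness. A subgroup option can give the
kinship effect different odds ratios in urban and rural strata for power
studies of the heterogeneity battery.

What the generator does **not** attempt: joint distributions beyond first
moments and the single copula knob, survey weights, panel structure, or
any spatial/clustered dependence. Tests that pass on this population
therefore certify the *computational pipeline* (indices, estimators,
batteries, diffusion model) — not the substantive claims about any real
survey population.

## Index construction

**Kinship** is $\ln(1 + \sum \text{give} + \sum \text{receive})$ over all
five relative categories. The $1+{}$ offset (rather than $\ln x$) keeps
zero-transfer respondents at exactly 0, which is what the published
minimum of 0 requires; give and receive are summed symmetrically
(reciprocity, not net flows). The index is monotone in every amount and
zero iff all transfers are zero.

**Friendship** standardises the three indicators, eigendecomposes their
correlation matrix and scores respondents on the first retained component.
Retention keeps eigenvalues ≥ 1 (inclusive at exactly 1), flooring at one
component: the scored component is always the first. The eigenvector sign
is arbitrary, so it is oriented to load positively on the spending item.
Scores are exactly mean-centred by construction; the acceptance suite
checks |mean| against the printed survey value 8.37e−09, which is itself
just float noise around zero.

**KMO** follows the anti-image route: with correlation matrix $R$ and
$C = R^{-1}$, partial correlations are
$p_{ij} = -c_{ij}/\sqrt{c_{ii}c_{jj}}$ and
$\mathrm{KMO} = \sum_{i \ne j} r_{ij}^2 \big/ (\sum_{i \ne j} r_{ij}^2 +
\sum_{i \ne j} p_{ij}^2)$, with the same ratio restricted to row $i$ for
per-item MSA. For the degenerate all-orthogonal case (0/0) the package
reports 0 with a warning: with no shared variance there is nothing for a
component analysis to summarise. The tests cross-check against an
independent implementation that computes partial correlations by residual
regressions, and against the closed form 9/13 ≈ 0.6923 for the
equicorrelated design with ρ = 0.5.

**Robustness variants.** `clan` is 1 iff any economic transaction
occurred; `friend` is the validated 0–6 contact frequency (out-of-range
values are an error, not clipped).

## Estimation

`fit_binary()` maximises the exact binary likelihood by Newton–Raphson
with analytic gradient and observed-information Hessian (for the logit,
observed and expected information coincide; for the probit the standard
inverse-Mills expressions are used). Convergence is declared at score norm
≤ 1e−8 (with one extra polishing step, so reported optima are accurate to
roughly square that), capped at 100 iterations; non-convergence is flagged
on the returned object rather than raised. Steps are damped to a maximum
coordinate move of 10 to survive bad curvature far from the optimum.

Degenerate inputs are diagnosed, not silently absorbed: rank-deficient
designs name the collinear columns (via QR with pivoting); a single-class
outcome after listwise deletion is an error; (quasi-)separation is
reported explicitly, detected either as a diverging standardised
coefficient (|β·sd(x)| > 20) or as a singular information matrix reached
while a coefficient is running away. Standard errors are
observed-information ML errors — no clustering or sandwich corrections, as
the emulated analysis reports none. Missing data are handled by listwise
deletion per model, which is why sample sizes differ across batteries when
missingness is switched on.

Logit fits report odds ratios $e^{\beta}$, probit fits report raw
coefficients, and significance stars sit at the 10/5/1% levels from
two-sided Wald tests — stars follow the computed p-values strictly.
"Adjusted R-squared" for these models is McFadden's adjusted pseudo-R²,
$1 - (\ell - k)/\ell_0$; the unadjusted variant is reported alongside.
(The source tables do not define their pseudo-R²; McFadden's adjusted
version is the conventional reading for ML binary models.)

The four batteries mirror the published table layout: baseline (each index
with and without the ten controls), robustness (clan and friend as
replacement regressors; probit re-fits of both indices), heterogeneity
(east/mid-west and urban/rural splits, with the splitting dummy dropped
from its own subgroup's controls), and mechanism (index → insurance,
insurance + index → care choice, and the same restricted to healthy
respondents — if the insurance effect survives among the healthy, it is
tie-transmitted risk information rather than own health shocks doing the
work).

## The SIRS diffusion model

The formal-care market is a closed population $N$ split into $S$ (never
considered formal care), $I$ (risk-aware but undecided) and $R$ (formal-
care users):

$$
\frac{dS}{dt} = -\alpha S I + \lambda R + \delta I,\qquad
\frac{dI}{dt} = \alpha S I - (\beta + \delta) I,\qquad
\frac{dR}{dt} = \beta I - \lambda R,
$$

with contact/tie-strength rate $\alpha$, adoption (learning/imitation)
rate $\beta$, non-adoption reversion $\delta$ and abandonment $\lambda$,
all strictly positive. The terms cancel, so $S+I+R$ is conserved. The
interior steady state is

$$
S^* = \frac{\beta + \delta}{\alpha},\qquad
I^* = \frac{\lambda\,(N - S^*)}{\beta + \lambda},\qquad
R^* = \frac{\beta\,(N\alpha - \beta - \delta)}{\alpha(\lambda + \beta)},
$$

feasible iff $\alpha N > \beta + \delta$; otherwise the system settles at
$(N, 0, 0)$. The comparative-statics table makes the key qualitative claim
checkable: $S^*$ is exactly inversely proportional to $\alpha$ (and
independent of $\lambda$), so stronger ties strictly shrink the pool that
never considers formal care while $I^*$ and $R^*$ grow.

Numerics: incidence is bilinear $\alpha S I$ exactly as the model is
written; with the default $N = 1$ (compartments as shares) this coincides
with frequency-dependent transmission. Integration is classical
fixed-step RK4 (default dt = 0.05) with an optional step-halving
self-check; stability of the endemic equilibrium is verified numerically
(50 random endemic parameter draws converge to the closed form within
relative 1e−5) rather than through a Jacobian eigenvalue analysis. The
rates carry no empirical units — the model is used analytically, and its
link to the insurance-mediation regressions is qualitative: both describe
the same information channel, but no formal identification between them
is claimed. The regression symbols and the diffusion symbols (α, β)
collide in the source notation; the package namespaces them per module
(`true_logit_coefs` vs `sirs_params`).

## Reproducibility and problem sizes

All randomness flows from explicit seeds; `run_pipeline()` derives
per-stage substreams from one global seed so disabling a stage never
shifts another's draws, and reruns reproduce byte-identical artifacts
(MD5s in the manifest). Tables round-trip losslessly through the CSV
layer (doubles written with 17 significant digits; missing values as
empty fields).

The test and acceptance workloads use sizes chosen to make Monte-Carlo
checks sharp at interactive cost: n = 20,000 for calibration and
coverage checks (100 replicates for 95% CI coverage of the generating
odds ratios; 200 replicates at n = 4,000 for the size of the 5% Wald
test), n = 50,000 for the KMO closed-form check on an exactly
equicorrelated design, and 50 random endemic parameter draws for the SIRS
convergence sweep. The analysis drivers under `analysis/` use n = 10,000.

## Known limitations

- First-moment calibration only; recovered standard errors describe the
  synthetic DGP, not any real survey's design effects.
- The mechanism battery is three raw regressions, not a formal mediation
  decomposition (no Sobel test, no bootstrap of indirect effects).
- The friendship index is always scored on one component; no rotation or
  multi-component scoring.
- The SIRS model is deterministic and population-level; no stochastic or
  agent-based variant, and its parameters are not fitted to data.
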