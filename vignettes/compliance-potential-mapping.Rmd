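---
title: "Compliance Potential Mapping: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compliance Potential Mapping: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmap)
```

## The question the package answers

Walking for transport is, for many seniors, the main realistic source of
physical activity. Given a household travel diary — one day of trips per
person, with home locations, socio-demographics, mobility tools and
built-environment descriptors — how many weekly minutes of walking can a
given *kind* of senior at a given *location* be expected to accumulate,
and what share of a physical-activity guideline (150 min/week for
seniors) does that represent?

`cpmap` answers this in three stages:

1. a **trip-distance model**: a joint discrete-continuous model of mode
   choice (walk / car / transit) and log-normal trip distance,
2. a **trip-frequency model**: a trivariate ordered probit for the
   number of daily trips per mode, classes {0, 1, 2, 3+}, with
   correlated errors across modes,
3. **map algebra**: on a prediction grid, expected walking distance and
   walking-frequency probabilities are combined into expected total
   daily walking distance (TDWD), weekly walking minutes (WWM) and
   percent-of-guideline compliance.

## The trip-distance model

Each observed trip carries a chosen mode $m$ and a positive distance
$d$. Utilities are linear in the design vector $x$ (covariates plus the
spatial trend block described below) and mode probabilities $P_m(x)$
are multinomial logit, with car — the most frequent mode — as the
reference. Distance given the mode is log-normal,
$\ln d = \theta_m' x + \sigma_m \alpha$. Mode choice and distance are
tied together by a Gaussian copula on the standard-normal transforms of
each margin: the selection event is represented by the score
$J_1 = \Phi^{-1}(P_m(x))$ and the distance by
$u = (\ln d - \theta_m'x)/\sigma_m$, with $\mathrm{corr} = \rho_m$. The
contribution of a trip is

$$\Pr(d, m) = \frac{1}{\sigma_m d}\,\phi(u)\,
  \Phi\!\left(\frac{J_1 - \rho_m u}{\sqrt{1-\rho_m^2}}\right),$$

so $\rho_m$ captures selectivity: unobservables that make a mode more
attractive also shift the distances travelled with it. At $\rho = 0$
the likelihood factorizes exactly into the MNL log-probability plus the
log-normal density — the package special-cases this so the identity
holds to machine precision.

By default one shared $\sigma$ and one shared $\rho$ serve all three
modes (matching how such models are usually reported); per-mode values
are available with `pooled = FALSE`. Prediction uses the log-normal
mean $\exp(\theta_m'x + \sigma_m^2/2)$, since the downstream map
algebra needs an expectation; `type = "median"` drops the
$\sigma^2/2$ correction.

## The trip-frequency model

Per person and mode $j$, a latent propensity
$t_j^* = \beta_j' x_j + \epsilon_j$ is cut by strictly increasing
thresholds $\mu_{j,1} < \mu_{j,2} < \mu_{j,3}$ into classes
{0, 1, 2, 3+}. The error vector is trivariate normal with correlation
matrix $R$; off-diagonals are common unobserved factors (a person who
walks more than their covariates suggest tends to drive less). The
latent scale is fixed by unit error variance, and thresholds absorb the
intercept, so no separate constant is estimated. A mode's equation may
structurally exclude covariates (the `exclude` argument), mirroring the
sparse per-mode columns of published frequency tables.

The likelihood of a person is the probability that $\epsilon$ falls in
the box of threshold intervals. Two evaluators are provided:

* `exact` — deterministic quadrature: the first coordinate is
  integrated by Gauss–Legendre quadrature and the conditional bivariate
  rectangle evaluated through a Drezner–Wesolowsky/Genz bivariate
  normal CDF (compiled kernels; absolute accuracy ~1e-11 at the
  default 24 nodes, 16 during optimization). Zero couplings factor out
  exactly, so independence reproduces the univariate ordered-probit
  likelihoods to machine precision.
* `ghk` — the Geweke–Hajivassiliou–Keane recursive importance sampler,
  seeded and reproducible. It is retained as a stochastic cross-check
  and for extensions beyond three modes; with three modes the exact
  method is both faster and deterministic, so it is the default.

## Spatial structure: the trend surface

Smooth spatial variation in behavior is captured by a quadratic trend
surface in the home coordinates plus the straight-line distance to the
central business district in km: $(x, y, xy, x^2, y^2, d_{CBD})$.
Coordinates are standardized (z-scored, population standard deviation)
against the estimation sample before the polynomial expansion — raw
projected metres squared would make the design catastrophically
ill-conditioned — and the fitted scaler is serialized with every model
so grid prediction reuses the estimation-sample standardization. CBD
distance is Euclidean; network distance is a data-preparation concern
outside the package.

## Estimation

Both likelihoods are maximized by BHHH (outer-product Fisher scoring)
with analytic per-observation scores, on unconstrained
parameterizations: $\log\sigma$ and $\mathrm{artanh}\,\rho$ for the
joint model; first cut plus log-increments for thresholds; and
spherical-Cholesky angles for $R$ (positive definite by construction,
with angles bounded away from 0 and $\pi$ so any optimizer step stays
admissible). Starting values come from standard separable fits —
`nnet::multinom` for the utilities, per-mode least squares on log
distance, `MASS::polr` per mode for the ordinal equations, and a
truncated-normal residual-score correlation for $R$ — which are
consistent at the independence point, so BHHH typically converges in a
few dozen iterations even with ~120 free parameters. Convergence is
declared when the relative log-likelihood improvement falls below
1e-10 with a mean per-observation score norm below 1e-5. Standard
errors are outer-product-of-gradients at the optimum; thresholds and
correlations are delta-method transforms of the unconstrained
parameters.

### Significance of the selectivity correlation

With the same covariates in both equations, $\rho$ is identified only
through the nonlinearity of the selection correction, and its
likelihood is nearly flat around zero: Wald statistics computed from
the curvature at $\hat\rho$ over-reject badly when the true $\rho$ is
0. `selectivity_score_test()` therefore implements the score (LM) test
at $\rho = 0$, which needs only the restricted fit (an ordinary MNL
plus least squares) and is the appropriate test in this setting. The
analogous Wald tests for the frequency-model correlations also run
somewhat hot in finite samples (the model profiles ~60 nuisance
parameters); the recovery suite checks those correlations by magnitude
(within ±0.1 of zero at survey scale), which is the sharper and more
stable criterion. This is a known limitation to keep in mind when
reading significance stars on correlation parameters.

## Map algebra

For a fixed person archetype (`person_profile()`) and each grid-cell
centroid: trend terms are computed, the walking distance $\hat d$ and
walking class probabilities $P(k)$ predicted, and

$$\mathrm{TDWD} = \hat d \sum_{k} k\,P(k), \qquad
  \mathrm{WWM} = \mathrm{TDWD} \cdot w / s, \qquad
  \mathrm{compliance\ \%} = 100\,\mathrm{WWM}/G,$$

with $w = 5$ days/week, walking speed $s = 68.4$ m/min (a standard
senior walking speed), and guideline $G = 150$ min/week; at these
defaults the guideline equals 10.26 km of walking per week. The open
class "3+" is valued at $k = 3$ trips — a conservative floor,
configurable via `k_cap` — and the zero class contributes nothing.
Compliance is deliberately not capped at 100%. Only walking feeds the
maps; car and transit predictions are retained in the fitted object
but drive no layer. The grid is a visualization device with no role in
estimation; 250 m cells are the default. `area_by_compliance()` bins
cell areas (km²) by compliance with explicit underflow/overflow rows,
so tabulated area always equals grid area.

## The synthetic survey generator

`make_default_config()` defines a synthetic senior travel survey used
for validation. Its defaults are the study conditions: mode shares
near walk 17% / transit 19% / car 64%, mean walking trip distance near
0.74 km, log-distance scale 1.084, selectivity correlation −0.472,
average trip frequency near 2.4/person, and frequency error
correlations (−0.474, −0.231, −0.656). The synthetic city is a 20 km
square on a 250 m grid, CBD at the center; homes are denser near the
CBD and densities decay smoothly with CBD distance. Covariate
frequencies (age, gender, household, occupation, income, licence,
vehicles) were chosen once as plausible for a senior travel-diary
population; income is coarsened to four classes to keep the validation
models compact.

Crucially, the generator's law is *exactly* the law the estimators
assume: frequency classes come from thresholded correlated latents,
each trip's mode is drawn from the MNL probabilities, and its
log-distance score is drawn conditionally on the truncated-normal
selection score with correlation $\rho$ — the same Gaussian copula the
joint likelihood integrates. Parameter recovery on generated data is
therefore a valid test of the estimators. What passing those tests
does *not* show is robustness to the ways real diaries deviate from
the model: misreported distances, within-person correlation across
trips, network rather than Euclidean accessibility, non-normal latent
errors, or the truncation of persons who made no out-of-home trips on
the survey day (the generator records such persons with all-zero
counts; one-day diaries typically cannot).

Validation problem sizes are 5,000 persons (~12,500 trips) per
replicate and 20 replicates for the recovery studies — large enough
for the 3-standard-error coverage checks to be sharp, small enough to
keep the full suite quick.

## Numerical choices and degenerate inputs

* Bivariate normal CDF: 20-point Gauss–Legendre on the
  correlation-integral form for $|r| \le 0.925$, a conditional
  quadrature beyond; near machine accuracy in both branches.
* Trivariate rectangles: outer Gauss–Legendre in $z$-space over the
  clamped interval (the normal CDF saturates beyond $|z| = 8.3$).
* Probabilities are floored at 1e-300 before logs; MNL probabilities
  are clamped at 1e-12 before $\Phi^{-1}$.
* Thresholds carry a 1e-9 floor on increments so a wild line-search
  step cannot collapse two cuts onto each other.
* `read_trips()` drops rows with non-positive distance (the distance
  model conditions on a trip having happened) and reports the count.
* A coordinate axis with zero spread is centered but not scaled;
  a fully degenerate coordinate sample is an error.

## Limitations

* The trend surface is a global polynomial: it cannot represent
  neighborhood-scale discontinuities, and extrapolation beyond the
  estimation sample's coordinate range is as trustworthy as any
  quadratic extrapolation.
* $\rho$ is weakly identified without exclusion restrictions (see the
  score-test discussion above); treat its point estimate with care.
* The frequency model's estimation unit is the person; persons absent
  from a one-day diary because they made no trips are a truncation
  risk the package accepts as a property of the input data.
* Distances enter as reported; no speed or route correction is
  applied beyond the constant walking-speed conversion.
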