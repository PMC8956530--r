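---
title: "Models and methods behind the xylem-safety pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the xylem-safety pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xylemsafety)
```

`xylemsafety` analyses branch xylem hydraulic safety in hierarchical field
campaigns: many sites, several trees per site, one measured branch per
tree. This vignette explains the models, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices a maintainer would want to know about.

## The vulnerability-curve model

A flow-centrifuge (cavitron) run spins a flushed branch segment at
increasingly negative xylem pressure $\Psi$ (MPa) while measuring its
specific conductivity $K_s$ (kg m$^{-1}$ MPa$^{-1}$ s$^{-1}$). We model
the expected conductivity with the sigmoidal curve

$$K_s(\Psi) = K_{max}\left(1 - \frac{1}{1 + \exp\!\big(s\,(\Psi - P_{50})\big)}\right),$$

i.e. the fractional loss of conductivity is logistic in pressure with
midpoint $P_{50}$ (MPa) and logit-scale steepness $s$ (MPa$^{-1}$). Fitting
is done on the conductivities themselves, not on percent loss: converting
to PLC divides by the largest observation and thereby propagates its
measurement error into every point, while the $K_s$-scale fit estimates
$K_{max}$ as a free parameter. The quantile pressures follow in closed
form,

$$\Psi_q = P_{50} + \frac{\ln\!\big((1-q)/q\big)}{s},$$

so $P_{12}$ and $P_{88}$ (air entry, near-complete embolism) are exact
functions of the fitted parameters and obey the symmetry
$P_{12} + P_{88} = 2\,P_{50}$. Tests verify the closed form against
bisection root-finding to $10^{-9}$ MPa over the whole realistic parameter
range.

### Fitting and its numerical choices

* **Estimator**: nonlinear least squares (Levenberg–Marquardt via
  `minpack.lm`), bounded to $K_{max} > 0$, $P_{50} < 0$, $s > 0$.
* **Starting values** are deterministic: $K_{max,0}$ is the largest
  observation; $P_{50,0}$ the linearly interpolated pressure where the
  observations first cross half of it; $s_0$ the slope of a logit-linear
  regression of interior loss fractions. On failure, up to five seeded
  jittered restarts are attempted before the fit is flagged.
* **Identifiability**: a series whose conductivities never fall below half
  of the observed maximum cannot pin down $P_{50}$; such fits are returned
  with `converged = FALSE` and reason `"non-identifiable"` instead of an
  arbitrary extrapolation.
* **Degenerate inputs**: fewer than five observations, positive pressures
  or negative conductivities are rejected at construction
  (`cavitron_series()`).

### Bootstrap uncertainty

Uncertainty uses a pairs (case-resampling) bootstrap: the pressure
schedule is fixed by the instrument protocol, but the error structure of
conductivity measurements is unknown and possibly heteroscedastic, which
rules out residual resampling. Intervals are percentile-based with the
*expanded percentile* calibration: with $n$ observations the quantile
levels are widened to $\Phi\!\big(-\sqrt{n/(n-1)}\; t_{0.975,\,n-1}\big)$.
A cavitron series has only 12–22 points, where raw percentile intervals
are systematically narrow; in our calibration simulations the model-based
Wald-$t$ intervals attained their nominal 95% coverage while raw
percentile intervals covered only ~88%, and the expansion — the standard
small-sample correction within the percentile family — restores coverage
into the nominal band. Default $B = 1000$ replicates (500 in the
simulation studies); replicates that fail to converge or are degenerate
after resampling are dropped and counted. The pointwise curve band is the
2.5–97.5% envelope of the replicate loss curves.

## Site water availability

* **Climatic water balance**: CWB $= P - \mathrm{PET}$ per month (mm),
  aggregated over a reference period (default 1991–2018) together with
  MAP, MAT, early-growing-season (April–June) and growing-season
  precipitation. The growing season for MGSP defaults to April–September
  and is configurable, since no universal convention exists.
* **Retention**: van Genuchten curve
  $\theta(h) = \theta_r + (\theta_s-\theta_r)[1+(\alpha h)^n]^{-m}$ with
  $m = 1 - 1/n$, suction $h$ in cm of water. pF is $\log_{10}$ of suction
  in hPa; conversion uses 1 hPa $= 1.019716$ cm H$_2$O (from
  $\rho g$ exactly). Field capacity sits at pF 1.8 ($-60$ hPa), permanent
  wilting point at pF 4.2 ($-1.5$ MPa).
* **Pedotransfer**: full neural-network pedotransfer functions are not
  reproduced. `texture_to_vg()` classifies the composition on the USDA
  texture triangle and looks up class-average parameters
  (`vg_class_table()`); externally computed parameters can be passed
  through an override. The pipeline's contract is the retention-to-AWC
  math, not a specific pedotransfer calibration, so exact reproduction of
  any particular study's AWC values is not attempted.
* **AWC**: per layer, $[\theta(\mathrm{pF}\,1.8) - \theta(\mathrm{pF}\,4.2)]
  \times$ thickness $\times$ 10 mm/cm, summed to a standard depth of
  100 cm; the deepest sampled layer's parameters are reused below its
  bottom (homogeneous-subsoil assumption). Stone content does not correct
  AWC by default — the field convention is ambiguous — but
  `correct_stones = TRUE` multiplies each layer by
  $(1 - \text{stone fraction})$.

## Stand and branch covariates

The Hegyi index uses the three nearest neighbours by Euclidean distance on
the stand map, ties broken by tree id for determinism. The index is
computed from stem diameters, $CI_i = \sum_j (d_j/d_i)/Dist_{ij}$ — the
size-ratio form of the index — even though field protocols sometimes
record neighbour heights instead; the diameter form is the defined
quantity here. Xylem area comes from the linear allometry
$A_{xylem} = -3.715 + 0.770\,A_{cross}$ (mm$^2$), which is negative below
$A_{cross} \approx 4.8$ mm$^2$; such inputs are rejected rather than
clipped. The mm$^2\to$m$^2$ conversion for specific conductivity happens
at exactly one code site to avoid silent unit errors. Branch age is the
mean of basipetal and acropetal ring counts; an acropetal count exceeding
the basipetal one violates growth direction and is an error.

## The trait models

Five linear mixed-effects models are fitted independently by REML (one per
response: $P_{12}$, $P_{50}$, $P_{88}$, $\log$ slope, $K_s$), each with
fixed effects for CWB, AWC, tree height, $\log$ branch age and CI, and a
random intercept per site. Branch age and slope are natural-log
transformed; every predictor is centred and scaled to unit SD *within the
modelled dataset*, so coefficients are per-SD effects and the intercept
equals the population mean of the response. Scaling constants are stored
(`unscale_coefficient()`) for back-transformation. Rows with missing
values are dropped listwise with a logged count. No multiple-testing
correction is applied across the five models; they answer five separate
questions.

Inference is by Wald $t$ tests with Satterthwaite degrees of freedom
(`lmerTest`). The Nakagawa decomposition reports
$R^2_{marginal} = \sigma^2_f / (\sigma^2_f + \sigma^2_{site} + \sigma^2_{res})$
and $R^2_{conditional} = (\sigma^2_f + \sigma^2_{site})/(\cdot)$ with
$\sigma^2_f$ the sample variance of the fixed-effect linear predictor; the
same three components expressed as fractions of their sum give the
variance decomposition (fixed share $=$ marginal $R^2$; site share $=$
conditional $-$ marginal). A singular fit (site variance estimated at
zero) is flagged, not raised: it is a legitimate outcome on data without
site structure, and the fixed effects then reduce to ordinary least
squares.

## The synthetic-study generator

The generator exists so that every stage of the pipeline can be tested
end-to-end with known truth. Its defaults emulate a 30-site × 10-tree
campaign on sandy lowland soils:

* **Covariate ranges** (uniform draws per site): CWB $[-10.8, 25.5]$
  mm month$^{-1}$, AWC $[43.4, 301.0]$ mm, MAP $[522, 886]$ mm yr$^{-1}$,
  MAT $[9.0, 10.0]$ °C; tree DBH $[36, 58]$ cm and height $[21, 34]$ m;
  the observed extremes of the emulated design. Covariates are drawn
  independently, which automatically satisfies the $|r| < 0.7$
  collinearity screen.
* **Trait structure**: branch-level true values follow the mixed-model
  equation $y = \beta_0 + \sum_k \beta_k z(x_k) + b_{site} + \varepsilon$
  with the per-SD effect sizes, site SDs and residual SDs of the emulated
  study (e.g. for $P_{50}$: intercept $-3.381$ MPa, AWC effect $0.086$,
  log-age effect $0.088$, site SD $0.199$, residual SD $0.279$). The
  slope is generated on the log scale (intercept $1.049$) and $K_s$ on its
  natural scale (intercept $1.536$), with the rare draw below
  $0.05$ kg m$^{-1}$ MPa$^{-1}$ s$^{-1}$ redrawn rather than clipped.
  The branch table's flushed maximum conductivity is back-computed from
  the generated $K_s$ through the xylem-area allometry, so the covariate
  pipeline recovers $K_s$ exactly.
* **Branch age**: shifted lognormal, $1.5 + \mathrm{LN}$, calibrated to
  mean 6.0 years with range $[1.5, 20.5]$ (upper tail resampled);
  $\sigma_{\log} = 0.75$ gives the right-skewed shape typical of
  upper-canopy branch collections. Ring counts at the two segment ends are
  integers consistent with the drawn age.
* **Stand geometry**: each site is a jittered grid of at least 25 trees
  (sampled trees plus neighbours) with site-specific spacing drawn
  uniformly from 4.5–8 m, calibrated once so that Hegyi site means span
  the realistic 0.4–0.7 range of managed mature stands.
* **Cavitron schedule**: pressures start at $-0.37$ MPa and descend in
  steps of $-0.25$ MPa (the instrument raises tension stepwise) until the
  modelled loss first reaches 90%, the instrument's stopping rule; the
  grid is extended to at least 5 points if needed. Observations are model
  values plus additive Gaussian noise with SD $= c_v K_{max}$
  (default $c_v = 0.05$), truncated at zero — additive rather than
  multiplicative so that $K_{max}$ keeps its interpretation and the noise
  floor matches a flow meter's absolute resolution.
* **Climate**: deterministic cosine seasonal cycles whose monthly
  deviations sum exactly to zero, so annual aggregates reproduce the
  configured MAP, MAT and CWB to floating point. PET peaks in summer and
  stays positive over the whole configured covariate range.
* **Soil**: three layers (0–10, 10–30, 30–60 cm) with sandy textures
  (sand 0.55–0.90, clay 0.02–0.12), bulk density 1.3–1.6 g cm$^{-3}$ and
  stone fractions up to 0.15; the resulting class-lookup AWC values fall
  within the configured site AWC range. The site AWC covariate itself is
  drawn directly, not derived from the soil table — deriving it would
  require inverting the pedotransfer, and the trait models only need a
  covariate with the right range and hierarchy.
* **Determinism**: one global seed is fanned out to per-stage child seeds
  through a fixed affine map modulo $2^{31}-1$; identical configurations
  give byte-identical studies.
* One cavitron series is generated per tree-branch — the emulated design
  has no within-tree replication, so the generator does not invent one.

**What the generator does not emulate**: spatial autocorrelation of
climate or soil, genetic/provenance structure, within-crown variation,
open-vessel artefacts, heteroscedastic or autocorrelated instrument noise,
and any leaf-area traits. Passing tests therefore demonstrate that the
*analysis* is correct and well-calibrated under the stated stochastic
model, not that field data obey that model.

## Validation scale and calibration results

The test suite fits the whole pipeline at the design scale it targets:
200 simulated branches (≈15 pressure steps each, 5% noise) for parameter
recovery and bootstrap coverage with $B = 500$, 200 replicates of the
30 × 10 design for mixed-model recovery, and a 30-site run end to end.
These sizes give Monte-Carlo standard errors small enough to detect
meaningful bias while keeping the default suite quick to run. Two
statistical subtleties are deliberate:

* Variance-component recovery is assessed on the **variance scale**.
  REML estimates variances; their square roots are biased low by Jensen's
  inequality (about $\sigma/(4\,df)$, i.e. $\approx 0.002$ for a site SD
  of 0.199 estimated from 30 sites), and a SD-scale comparison would
  misread that known transform bias as an estimation failure.
* Bootstrap coverage is assessed with the expanded-percentile intervals
  described above, for the small-$n$ reasons given there.

## Known limitations

* Only the logistic vulnerability-curve shape is implemented (no Weibull
  or exponential alternatives), and curves are fitted per branch with no
  hierarchical pooling across branches.
* The pedotransfer step is a class-average lookup; studies needing
  continuous pedotransfer predictions should supply their own parameters
  via the override.
* The mixed models assume Gaussian residuals and a single random grouping
  level (site); random slopes, spatial covariance and model selection are
  out of scope.
* `run_pipeline()` is the orchestration surface; there is no shell
  executable, since the package is meant to be driven from R scripts.
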