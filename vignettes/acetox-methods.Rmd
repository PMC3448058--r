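---
title: "Methods: growth surfaces and acetic-acid toxicity metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth surfaces and acetic-acid toxicity metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetox)
```

This vignette documents the statistical and mechanistic models behind
`acetox`, the parameters that matter, the numerical choices, and what the
synthetic plate simulator does and does not establish about real data.

## The problem

Acetic-acid toxicity in yeast depends jointly on the total acid dose, the
medium pH and the glucose supply. Only the undissociated acid HA crosses
the plasma membrane, and its fraction

$$f_{HA}(\mathrm{pH}) = \frac{1}{1 + 10^{\,\mathrm{pH} - pK_a}},
\qquad pK_a = 4.76$$

falls steeply above the p$K_a$, so the same 50 mM dose that is lethal at
pH 3 is nearly inert at pH 6.5. Mapping such interacting effects requires
covering a three-dimensional condition space densely enough to interpolate
— the motivation for space-filling designs and non-parametric response
surfaces rather than factorial designs with polynomial fits.

## Axis transformations and experimental design

Every factor is mapped to $[0,1]$ before any distance or covariance is
computed. Linear axes map affinely; concentration axes use
$\log(x + \delta)$ (offset $\delta = 1$ unit by default) so that zero-dose
controls remain representable while low concentrations — where biochemical
systems respond most strongly — are expanded. The transformation is the
place to encode prior beliefs about sensitivity: the package default uses a
log axis for glucose and linear axes for pH and acetic acid. The acid axis
is kept linear deliberately: EC50 estimation needs uniform dose resolution
across the mid-to-high range, and a log axis would concentrate half the
design below 10 mM.

Designs are built sequentially: a Latin-hypercube candidate pool (default
1000 points, from the `lhs` package) is drawn in the transformed unit
cube, a start point is picked uniformly from the pool under the seed, and
each subsequent point is the candidate with maximal minimum Euclidean
distance (in transformed coordinates) to the already-selected set, ties
broken by candidate index. The procedure is deterministic given
`(factors, n_points, candidate_pool, seed)`; tests verify the maximin
property exhaustively against a brute-force oracle and check empirical
coverage (largest 1-D gap below $3/n$). Where strain is a factor, the same
conditions are replicated per strain rather than treating strain as a
design dimension — replication keeps the strain contrast free of design
confounding.

Buffer control of pH uses a measured titration table (mixing fraction of
the high-pH buffer vs resulting pH) interpolated by a Fritsch–Carlson
monotone piecewise cubic. Unlike a natural cubic spline this cannot
overshoot between knots, so it is invertible over the calibrated range;
the same primitive backs the pHluorin calibration.

## Growth kinetics

Exponential growth $dOD/dt = \mu(t)\,OD(t)$ implies
$\ln OD(t) = \ln OD(t_0) + \mu t$ locally, so $\mu(t)$ is estimated as the
least-squares slope of $\ln OD$ versus time (hours) in a sliding window of
`window` consecutive readings (default 5, i.e. 50 min at the 10-min reader
cadence — short enough to resolve sub-hour dynamics, long enough to
average reader noise). Windows slide with stride 1 and each slope is
assigned to the window's central time; the maximal rate takes the earliest
window on ties. Summaries per well: $\mu_{max}$, its time, the biomass
yield $\max(OD) - OD(t_0)$ (subtracting the fixed 0.2-OD inoculum), and
the **OD integral** — the trapezoidal area under the curve,
$\sum_i \tfrac12 (OD_i + OD_{i-1})(t_i - t_{i-1})$ — computed on
blank-corrected values without further baseline subtraction. The O₂
integral is the same functional applied to the oxygen-saturation curve;
because saturation *rises* when respiration stops, a high O₂ integral
means *low* respiratory activity.

On noiseless exponential data the estimator is exact to solver precision
for every window size, a property the tests assert at $10^{-10}$.

## Gaussian-process response surfaces

`gp_rsm()` treats the $n$ responses as a draw from a Gaussian process with
constant prior mean $\mu$ (set to the sample mean of the response) and the
anisotropic Gaussian covariance

$$k(x_i, x_j) = \sigma_f^2 \exp\Big(-\tfrac12 \sum_k
  \big((x_{ik}-x_{jk})/l_k\big)^2\Big) + \sigma_n^2\,\delta_{ij},$$

with one length scale per transformed dimension. Predictions are the
standard Kriging equations: mean $\mu + k_*^\top K^{-1}(y - \mu 1)$ and
variance $\sigma_f^2 - k_*^\top K^{-1} k_*$ (clamped at zero), where $K$
carries the nugget $\sigma_n^2$ on the diagonal and $k_*$ does not. The
implementation uses one Cholesky factorization per model; a dense
build-`K`-and-solve oracle in the tests confirms agreement to $10^{-8}$
relative error.

**Noise estimation.** For fixed length scales the noise-to-signal ratio
$\lambda = \sigma_n^2/\sigma_f^2$ minimizes the generalized
cross-validation score
$$\mathrm{GCV}(\lambda) = \frac{n\,\lVert (I - A(\lambda))\,y \rVert^2}
  {\mathrm{tr}(I - A(\lambda))^2},$$
where $A(\lambda) = R (R + \lambda I)^{-1}$ is the smoother matrix mapping
centred responses to fitted means. The search uses a 25-point log grid on
$[10^{-8}, 10^{2}]$ refined by golden section, on the eigendecomposition
of the correlation matrix so each $\lambda$ costs $O(n)$. $\sigma_f^2$ is
then the profile maximum-likelihood value
$y_c^\top (R+\lambda I)^{-1} y_c / n$.

**Length-scale estimation.** The outer loop runs Nelder–Mead (`optim`)
over log length scales, started at 0.3 in every transformed dimension
(one-dimensional models use Brent's method instead). The default objective
is the *profile negative log marginal likelihood* with $\sigma_f^2$ and
$\lambda$ profiled out. This was a genuinely open design choice, and the
package deliberately does **not** use the GCV score as the outer
objective: along the nugget–length-scale ridge (larger $l$ compensated by
larger $\lambda$) the GCV score is nearly flat, and in simulation even its
exact global argmin recovers a known length scale within a factor of two
only ~55% of the time, whereas the likelihood's log-determinant term
breaks the ridge and recovers it in ~85–100% of replicates. Predictions
along the ridge are nearly identical, so users who want the pure
cross-validation behavior can set `objective = "gcv"`; the returned
model's noise level is in both cases the GCV choice at the selected
length scales. Optimizer caps: 200 Nelder–Mead iterations at absolute
tolerance $10^{-6}$; hitting the cap returns the best-seen parameters
with a warning.

**Degenerate and ill-conditioned cases.** A constant response yields a
flat surface with $\sigma_f$ at a floor. When $\sigma_n = 0$ the Cholesky
factorization escalates a relative diagonal jitter ($0, 10^{-14}, \dots,
10^{-10}\,\sigma_f^2$), stopping at the first success, so a vanishing
nugget still interpolates the data to ~$10^{-7}$ while duplicated
noise-free points fail with an error advising a positive nugget.

## Toxicity metrics

A **dose–response curve** is a slice of a fitted integral surface along a
linear 101-point acetic-acid grid at fixed pH and glucose. The **EC50** is
the concentration at which the curve crosses the midpoint between its
maximum and minimum, scanning from the low-acid side with linear
interpolation between bracketing grid points; taking the *first* crossing
is the conservative (lowest effective dose) convention for non-monotone
interpolated curves. The midpoint level makes the estimate invariant under
positive affine transformations of the response. Two guards apply: a flat
curve has no defined level, and — at the pipeline level — curves whose
total relative effect is below `min_effect = 0.05` (less than 5%
inhibition across the whole grid) are flagged undefined, since a
self-normalizing midpoint would otherwise locate noise crossings on
surfaces where the acid did essentially nothing; the half-inhibitory dose
then lies beyond the tested range and is reported as censored rather than
invented.

The **toxicity integral** is the trapezoid area under the dose–response
curve (response units × mM); **relative viability** divides each integral
by the maximum within its (strain, channel) group, so each strain's best
condition maps to exactly 1. Channels normalize separately to keep units
coherent. For O₂-integral surfaces the curve is first reflected
(`max − response`) so that "viability" decreases with inhibition for both
channels; rows carry an `o2_reflected` flag.

## Sensor calibrations

The oxygen optode is calibrated with two standards (sulfite-scavenged
oxygen-free water and air-saturated water); with two points the defensible
model is affine in the signal, and saturation converts to partial pressure
as $\mathrm{sat}/100 \times 0.2095 \times (P_{amb} - P_{H_2O})$ with
$P_{H_2O} = 42.4$ hPa at the 30 °C incubation temperature and
$P_{amb} = 1013$ hPa by default. An optional Stern–Volmer mode accepts a
quenching constant when one is known; two calibration points alone cannot
constrain that curvature. Readings are clamped to $[-5, 110]$% and flagged
outside $[0, 100]$%.

The pHluorin calibration interpolates measured (pH, ratio) pairs —
typically pH 5.0–8.0 in 0.5 steps — with the monotone cubic, rather than
fitting a parametric sigmoid: seven knots over three pH units justify no
particular functional form. Ratios overshooting the calibrated range by up
to 2% of the span are clamped and flagged; ratios further out become
flagged missing values so one saturated reading cannot abort a plate.

## The synthetic plate simulator

The simulator generates the long-format plate tables the analysis
consumes, with the statistical and mechanistic structure the analysis
assumes:

* **Growth**: $dOD/dt = \mu\,OD$, $dS/dt = -(\mu/Y)\,OD - d$, with Monod
  kinetics in glucose and Hill inhibition by undissociated acid,
  $\mu = \mu_{max}\, \frac{S}{K_s + S}\, \frac{1}{1 + (HA/K_{i,\mathrm{eff}})^h}$,
  integrated by fixed-step RK4 at one tenth of the 10-min reader interval
  (a step-refinement oracle bounds the error at $10^{-4}$ OD; the fixed
  step keeps runs bit-reproducible where adaptive steppers need not be).
  Cultures start at the inoculum density 0.2 OD and are read for 114
  cycles at 10-min intervals, with multiplicative log-normal reader noise
  (sd 0.02 by default).
* **Effective inhibition constant**:
  $K_{i,\mathrm{eff}} = K_i \cdot 10^{\,s\,(\mathrm{pH} - pK_a)} \cdot
  \big(1 + g\,S_0/(S_0 + K_g)\big)$ with $s = 0.2$, $g = 2$, $K_g = 20$
  g/l. The pH term encodes that cells tolerate *less* undissociated acid
  at low external pH, where every protonation–reentry cycle dissipates a
  steeper proton gradient — with pure Henderson–Hasselbalch potency the
  EC50-vs-pH curve would be flat below $pK_a - 1.5$ (differences under 1
  mM), making the well-documented pH-protection trend structurally
  unresolvable by any interpolated surface. The glucose term is the
  ATP-dependent protection: proton export is glucose-fuelled, so tolerance
  rises (up to 3-fold) with the sugar supply.
* **Hill steepness** $h = 4$: steep enough that saturating doses (120 mM
  at pH 2.5) suppress growth essentially completely within the 19-h
  horizon, consistent with the all-or-none character of weak-acid growth
  arrest.
* **Gluconeogenic drain**: when inhibition exceeds 50%, glucose is
  additionally consumed without biomass gain (1 g/l/h per OD unit),
  representing diversion into gluconeogenic/storage-carbohydrate
  metabolism under acid stress. The *hap4*-like strain archetype runs with
  this drain nearly absent (×0.05), a 1.5× higher $K_i$ and a 0.9×
  $\mu_{max}$ — free parameters chosen to reproduce the qualitative
  contrast of a respiration-deficient, acid-tolerant mutant, not measured
  quantities.
* **Oxygen**: $d\,\mathrm{sat}/dt = k_La(100 - \mathrm{sat}) -
  q_{O_2}\,OD(t)\,R(HA)$ with respiratory inhibition
  $R = 1/(1 + (HA/K_{i,resp})^h)$, clamped to $[0,100]$%; an analytic
  steady state validates the integrator.
* **Cytosolic pH**: holds at 7.2 while glucose lasts and inhibition stays
  below 50%, then decays exponentially toward the medium pH (time constant
  2 h); the observable is the calibration interpolant applied forward,
  so calibration inversion can be validated end-to-end.

**What passing tests show — and what they do not.** The simulator shares
its *structure* with the analysis assumptions (smooth responses,
multiplicative noise, Henderson–Hasselbalch chemistry). Tests passing on
simulated plates therefore demonstrate internal correctness — estimators
recover known quantities, surfaces interpolate, qualitative orderings
(pH protection, glucose protection, strain contrast) propagate through
the full pipeline — but not that real plate data satisfy those
assumptions: real cultures show lags, diauxie, evaporation drifts,
edge-well effects and condensation artifacts that the simulator omits,
and the simulator's quantitative parameter values are placeholders, not
fits to any measured dataset.

## Problem sizes and reproducibility

The shipped checks use 48 conditions per strain for three-factor
experiments (the standard half-plate-per-strain layout) and one full
96-well plate of a single strain for the two-factor (pH × acid)
pH-protection analysis — with only 48 points over that plane, the
surface's mean-reversion dips in the uninformative high-pH region are of
the same order as the 5% effect threshold and can masquerade as spurious
dose responses. GP oracle checks run at $n = 30$ and recovery studies at
$n = 60$ over 20 replicates. All randomness flows from explicit integer
seeds: designs regenerate their candidate pools per call, the plate
simulator derives per-well child seeds from the master seed, and the
pipeline derives per-stage seeds from the master seed and stage name, so
every artifact is bit-reproducible and every run records its seed and a
configuration hash in the file headers.

## Known limitations

* The EC50 definition is grid-based with linear interpolation, not a
  parametric (Hill-equation) fit, and carries no confidence interval.
* The GP uses a stationary Gaussian kernel on transformed axes; truly
  non-stationary responses (sharp growth/no-growth boundaries) are
  smoothed, and axis transformations are the only tool offered for that.
* A constant prior mean pulls predictions toward the data mean in sparse
  regions; slices far from any design point should be read together with
  their predictive standard deviation.
* Calibration drift, photobleaching and background fluorescence are out of
  scope; calibrations are assumed stable within an experiment.
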