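# seamountr

Statistical machinery for quantifying how seamounts aggregate pelagic
life — the "oasis effect". Shallow seamounts concentrate sharks, predatory
fishes, seabirds and mid-trophic prey around their summits; marine-reserve
design needs to know **how far** that influence extends and **how strong**
it is. `seamountr` packages the full analytical pipeline used in integrated
seamount surveys: baited-video and visual-census reduction, penalized-spline
distance-effect models with a derivative-based *radius of influence*,
hydroacoustic echo-integration, chlorophyll enrichment indexing, tidal
spectral analysis, acoustic-telemetry residency analytics, and a
correlated-random-walk null test of site fidelity for satellite-tracked
animals. It is written for quantitative marine ecologists who have radial
survey data around a topographic feature and want defensible estimates of
the feature's footprint.

## The core model

For a survey response \(y_i\) (MaxN counts, frame biomass, NASC,
chlorophyll, ...) observed at distance \(d_i\) from the nearest summit, the
package fits the generalized additive model

g(E(y_i)) = β₀ + f_s(d_i) + β₁ x_i

where *f_s* is a penalized thin-plate regression spline of distance, *x* an
optional parametric covariate (season, vessel), and *g* the identity
(Gaussian) or log link (negative binomial for overdispersed counts, Tweedie
for nonnegative continuous responses, quasi-likelihood families for
proportions and rates). Transect random intercepts enter as ridge-penalized
terms, AR(1) residuals are available through a mixed-model fit, and
depth-stratified acoustic data use a 2-D tensor-product smooth
f(distance, depth).

Two estimators turn the fitted smooth into the quantities of interest:

* **Radius of influence (R)** — finite-difference first derivatives of the
  fitted smooth are evaluated on a 100-point grid with confidence bands
  propagated from the coefficient posterior covariance (simultaneous by
  default, so scanning the whole grid keeps a ~5% family-wise error); R is
  the furthest distance at which the slope differs significantly from zero.
  For near-zero count baselines, where the scan cannot separate a seamount
  effect from a monotone trend, an oceanic-baseline crossing rule with a
  0.05 response floor takes over.
* **Enrichment magnitude** — the ratio E(y | d = 0) / mean E(y | d > R)
  between the summit prediction and the pelagic baseline, with a credible
  interval from 1,000 multivariate-normal draws from the model posterior.

Everything downstream of a survey table is reproducible from a seeded
synthetic-data generator (`gen_radial_survey()`, `gen_nasc_field()`,
`gen_detection_log()`, `gen_tracks()`, `gen_environment()`) that plants
known ground truth — compact-support enrichment kernels, behaviour labels,
DCM depths, tidal periods, logistic detection ranges — so every estimator
is testable against truth without any external download.

## Worked example

Simulate a baited-video style survey around one seamount with a planted
oasis effect — baseline 0.5 animals per deployment, 20× enrichment at the
summit, true radius 5 km, strongly overdispersed counts — then recover the
effect:

```r
library(seamountr)

cfg   <- sim_config(seed = 11, n = 350, design = "stations",
                    distance_range = c(0, 20))
truth <- enrichment_kernel(baseline_mean = 0.5, summit_multiplier = 20,
                           radius_true = 5)
surv  <- gen_radial_survey(cfg, truth, family = "nb")

fit <- distance_gam(surv, family = "nb")
fit
#> Seamount distance-effect model (nb family, global smooth structure)
#>   n = 350, distance range 0-20 km
#>   total effective degrees of freedom: 8.281

seamount_effect(fit, draws = 1000, seed = 11)
#> Radius of influence: R = 5.66 km ( derivative-scan )
#>   predicted response at summit  : 10.73
#>   mean predicted beyond R       : 0.4757
#>   enrichment magnitude          : 22.55  (95% CI 15.08-31.27)
```

The estimated radius (5.66 km) and magnitude (22.6×) recover the planted
truth (5 km, 20×; summit mean 10, baseline 0.5) within the sampling
uncertainty the credible interval describes. `plot(fit)` draws the fitted
distance-response curve over the data; `derivative_band(fit)` exposes the
slope band behind the radius estimate.

A categorical comparison of presence probabilities (here, occurrence in 8
of 41 near-seamount deployments against 1 of 56 oceanic reference
deployments) uses the continuity-corrected proportion test:

```r
two_proportion_test(8, 41, 1, 56)
#> Two-sample proportion test (continuity-corrected)
#>   proportions: 0.195 vs 0.0179
#>   chi-square = 6.86 (df = 1), p = 0.0088
```

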