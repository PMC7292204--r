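---
title: "Methods: the fruit carbon-balance model, its inversion, and the synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the fruit carbon-balance model, its inversion, and the synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fruitcarbon)
```

## The model and its assumptions

A fleshy fruit is treated as a single well-mixed sink importing carbon from
the phloem as sucrose. Imported carbon enters the soluble-sugar pool
(`C_sol`), from which it can be polymerised into starch (`C_sta`), fixed
irreversibly into structural compounds — cell walls, proteins, organic
acids — (`C_str`), or respired. Starch is remobilised back to soluble
sugar; structural carbon is not. This yields a linear, time-varying
compartmental system:

$$\frac{dC_{sol}}{dt} = k_0\frac{dC_{sup}}{dt} + k_5 C_{sta}
  - (k_3(t) + k_{5m}(t) + k_6(t))\,C_{sol}, \qquad
  \frac{dC_{sta}}{dt} = k_{5m}(t) C_{sol} - k_5 C_{sta}, \qquad
  \frac{dC_{str}}{dt} = k_3(t) C_{sol}.$$

Respiration has a growth component proportional to the dry-weight growth
rate and a maintenance component proportional to standing dry weight with a
Q10 temperature response:
$dC_{rep}/dt = q_g\,dDW/dt + q_m\,DW\,Q_{10}^{(T-20)/10}$. Mass
conservation ties supply to growth: total fruit carbon is `c_DW · DW`, so
$dC_{sup}/dt = c_{DW}\,dDW/dt + dC_{rep}/dt$. The respiration coefficient
$k_6(t) = (dC_{rep}/dt)/C_{sol}$ is therefore directly computable and is
never a fitted parameter.

Key assumptions: all soluble sugars are pooled (no glucose/fructose/sucrose
split); water relations are outside the model (concentrations are converted
to carbon amounts before any dynamics); the phloem import fraction `k0` is
fixed at 1 for tomato; and starch breakdown `k5` is constant through
development, because the activities of the starch-degrading enzymes change
little as the fruit grows.

## Parameters and units

| Constant | Meaning | Default | Units |
|---|---|---|---|
| `c_DW` | carbon per g dry weight | 0.44 | g C/g DW |
| `q_g` | growth respiration cost | 0.088 | g C/g DW |
| `q_m` | maintenance respiration at 20 °C | 0.000168 | g C/g DW/h |
| `Q10` | temperature ratio of maintenance respiration | 1.4 | — |
| `k0` | phloem import fraction | 1 | — |
| `k5` | starch → sugar conversion | 0.296517337 | 1/day |

The internal clock is hourly, because the respiration constants are per
hour and temperature varies on a sub-daily cycle. All conversion rates
(`k3`, `k5m`, `k5`) and fluxes are per day at the user surface — the
natural scale for a process unfolding over a ~40-day window, and the one on
which the default `k5` has a sensible magnitude; its time unit is a
configuration default here, not an asserted fact. The day/hour factor is
applied in exactly one pair of functions (`per_day_to_per_hour()`,
`per_hour_to_per_day()`), so no second conversion site can drift out of
step.

## Numerical choices

*Integrator.* Fixed-step classical Runge–Kutta (default 1 h). The system is
linear and smooth, so adaptivity buys nothing, and a fixed step makes runs
bit-reproducible. Because the supply and respiration terms are integrated
with the same scheme as the pools, the conservation identity (pool gain =
cumulative supply − cumulative respiration) holds to roundoff, which the
test suite asserts. Schedules (`k3(t)`, `k5m(t)`, `T(t)`, `DW(t)`) are
linearly interpolated between grid points.

*Undershoot policy.* Aggressive rate schedules can transiently drive
`C_sol` slightly negative (the soluble balance has sinks not proportional
to the pool when `k0 < 1`). Pools are clipped at zero and a warning reports
the largest excursion; silent clipping would hide schedule problems.

*Division floors.* The inversion divides by `C_sol`; evaluation points
where the smoothed soluble pool is at or below 1e-6 g are flagged and
withheld rather than producing enormous rates.

## Inversion: smoothing and derivative estimation

The rates follow pointwise from the pool balances:
$k_3(t) = \dot C_{str}/C_{sol}$ and
$k_{5m}(t) = k_5 C_{sta}/C_{sol} + \dot C_{sta}/C_{sol}$. Everything
therefore hinges on estimating smoothed pools and their derivatives from
noisy, sparsely sampled observations.

`smooth_pools()` fits, at each grid age, a weighted quadratic in age with
tricube weights over a window whose half-width is a fixed fraction
(default 0.6) of the observed age span; the replicates of a treatment are
pooled into one regression. The derivative estimate is the analytic slope
of the local polynomial. Local quadratics reproduce any quadratic exactly,
so first derivatives are unbiased up to third-order curvature — the right
trade-off for sigmoidal pool trajectories. The smoother is written in the
package rather than delegated, because the derivative *is* the method's
input and off-the-shelf smoothers do not expose it.

*Edge policy.* Local-polynomial derivatives are least reliable at window
boundaries, so `estimate_rates()` reports rates only on the interior 80% of
the observed span by default. Negative rate estimates (smoothing artifacts)
are floored at zero but kept raw in `k3_raw`/`k5m_raw` diagnostic columns,
so flooring is auditable.

*Where recovery is measurable.* Both true rates decay towards zero well
before the last sampled age. Below roughly 10% of a rate's window maximum,
the truth is indistinguishable from zero at the study's noise level and a
relative error is uninformative; recovery tests therefore evaluate relative
accuracy only where the true rate exceeds 10% of its window maximum, and
separately assert that the recovered rates approach zero at the final age.
Under the default study conditions (3 replicates, 8 sampling ages, 5%
multiplicative noise) the median recovered rates across 50 seeded
repetitions sit within 25% of truth throughout the measurable region; on
dense noiseless data the round-trip is accurate to better than 2%.

## Why `k5` is fixed, not estimated

Since `k5` and `k5m(t)` are functions of each other, only their combination
is constrained by the starch balance: substituting the derived
$k_{5m}(t)$ back into $dC_{sta}/dt = k_{5m}C_{sol} - k_5 C_{sta}$ cancels
`k5` identically. A least-squares criterion comparing forward simulations
(with rates re-derived at each candidate `k5`) to the observations is
therefore flat up to smoothing error — `calibrate_k5()` implements exactly
this criterion, measures the objective's relative variation across the
search interval, and when the variation is negligible (including the
classical degenerate case of a starch-free trajectory) warns and returns
the interval midpoint with a flag. In practice the objective varies by only
a few percent across a twenty-fold range of `k5`, with a shallow minimum
whose location reflects smoothing bias rather than the data-generating
value; the package consequently treats `k5` as a fixed constant, and its
default is the conventional calibrated value quoted above.

## The synthetic-data generator

The generator emulates the factorial glasshouse experiment the analysis
assumes: four water levels (control CK plus three treatments receiving half
the control irrigation in exactly one growth stage) crossed with two
potassium levels (none, or two equal K2O applications of 0.46 g per kg of
pot soil — 7.82 g each, 15.64 g in total for a 17 kg pot), fruits sampled
at 34, 37, 48, 57, 58, 65, 66 and 73 days after anthesis with three
replicates.

*Growth.* Fresh and dry weight follow logistic curves; treatment effects
scale the asymptotes (deficit water lowers both, potassium raises both), so
every reported contrast direction — control outweighing deficit treatments
in fresh weight, potassium raising dry weight and sugar concentration — is
reproduced without targeting any particular mean.

*Allocation.* Pool fractions of total carbon follow normalised logistics:
soluble rising, starch falling, structural as the remainder. The reported
allocation endpoints are mutually inconsistent as a sum (starch 16%,
soluble 13% and structural 75% early sum to 104), so the generator anchors
the three quantities its tests actually measure — starch 16% and
structural 75% at the first sampled age, soluble 45% at harvest — and lets
the soluble share at the first sampled age be the remainder (9%); a 13%
soluble share is then a value attained before the first sampled age, and
structural carbon ends at 53% (against "about 50%" reported). Starch
declines from its early peak across the sampled window, matching the
post-peak regime the sampled ages cover.

*Implied truth.* The true `k3(t)`, `k5m(t)` are computed from the noiseless
curves with analytic derivatives — the exact quantities the inversion
should recover — and are returned alongside the observations as the test
oracle.

*Noise.* Measurement error is multiplicative lognormal with unit mean and
5% CV, applied independently to fresh weight, dry weight and the two
concentrations: positive-valued assay measurements with roughly constant
relative error. Each treatment draws from its own RNG substream derived
from the global seed and the treatment label, so adding a treatment never
reshuffles another's draws.

What the generator does **not** emulate: truss-level structure (ages map to
trusses, but no truss random effect), correlated errors between fresh
weight and concentrations measured on the same fruit, year or greenhouse
effects, and any water-balance mechanism — the dilution effect appears only
through the treatment multipliers. Passing tests therefore demonstrate that
the pipeline recovers what this idealised data-generating process encodes,
not that the model is adequate for any particular real dataset.

## Treatment statistics

The ANOVA stage requires a balanced design, where sequential and marginal
sums of squares coincide and the classical decomposition is unambiguous;
unbalanced input is an error directing the user to subset, not a silent
fallback. Fitting is delegated to `stats::aov()`; the test suite checks the
F statistics against an independent projection oracle built directly from
model matrices. A term with exactly zero explained variance reports F = 0
by convention, including the degenerate all-constant-response case.

Fisher's LSD letters are assembled from all pairwise comparisons at
α = 0.05 without family-wise correction, as the LSD procedure prescribes.
The compact letter display is built from the maximal cliques of the
non-significance graph, which guarantees the display's defining property —
two levels share a letter exactly when they do not differ beyond the LSD —
and the suite verifies this against brute-force pairwise checks. The
Kruskal–Wallis stage wraps `stats::kruskal.test()` (tie-corrected H,
chi-square reference), with H defined as 0 when every observation is tied.

## Problem sizes used by the test suite

Simulations integrate 39 days at a 1 h step (a 0.01 h step for closed-form
comparisons over 10 days). Stochastic properties use 50 seeded repetitions
of the 24-observation control table for rate recovery, 500 replications of
the 48-observation factorial for the type-I error check, and 4000
permutations for the Kruskal–Wallis oracle. These sizes give comfortable
Monte-Carlo margins for the asserted tolerances while keeping the whole
suite fast.

## Known limitations

- Rates at the very start and end of the sampled window are boundary
  estimates; the default interior-80% policy drops them, so conclusions
  about the first/last three days of a 39-day window need denser sampling.
- The soluble-sugar fraction recovered at the harvest boundary has a
  standard deviation of about two percentage points under the default
  noise conditions; single-run values a few points from the generating
  endpoint are expected behaviour, not bias.
- `calibrate_k5()` exists to document non-identifiability; do not interpret
  its non-flat-case minimiser as an estimate of starch breakdown.
- The balanced-design restriction of `factorial_anova()` is deliberate;
  severely unbalanced field data needs a different (Type II/III) analysis
  outside this package's scope.
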