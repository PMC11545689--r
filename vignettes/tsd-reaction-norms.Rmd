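---
title: "Modelling temperature-dependent sex determination and embryonic growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling temperature-dependent sex determination and embryonic growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(tsdnorm)
```

## The problem

In sea turtles, gonadal sex is set by the temperature an embryo experiences
during a restricted developmental window, the thermosensitive period (TSP;
embryonic stages 23–27 in leatherbacks). Two summary quantities describe a
population's TSD pattern: the pivotal temperature `P`, the constant
incubation temperature producing a 1:1 sex ratio, and the transitional range
of temperatures (TRT), the interval producing mixed sex ratios between `l`
and `1 - l` (conventionally `l = 0.05`). Published leatherback datasets are
small, scattered across regions (regional management units, RMUs), and were
produced under heterogeneous protocols, so apparent among-region differences
can reflect study and clutch effects rather than biology. `tsdnorm`
implements the full analysis chain needed to compare those datasets on one
scale: an asymmetric sex-ratio curve, a thermal reaction norm of embryonic
growth, growth-weighted constant-temperature equivalents (CTE) for nests
with fluctuating temperatures, a hierarchical Bayesian fitter with nested
random effects, and per-draw AICc model comparison.

## The flexit* sex-ratio model

The proportion of females at a constant (or equivalent) temperature `T` is

$$\mathrm{sr}(T) = \left(1 + e^{4\,(S + \Delta S \cdot \mathrm{QBT})\,(P - T)}\right)^{-1},
\qquad \mathrm{QBT} = \left(1 + e^{100 (P - T)}\right)^{-1}.$$

`S1 = S` is the slope parameter below `P` and `S2 = S + dS` above it; the
quasi-binary threshold QBT is a logistic so steep that it switches the
active slope essentially at `P` (it is exactly 0.5 at `T = P`, and within
`1e-4` of its limit 0.1 °C away) while keeping the curve smooth and
overflow-safe. Celsius is an interval scale, so there is no reason to force
the pivotal temperature to sit at the centre of the TRT; the two slopes let
the curve be asymmetric. With `dS = 0` the model is the ordinary logistic.
TRT limits have closed forms (`trt_limits()`), and the width is reported as
`upper - lower` (a positive number).

Counts of males and females per incubation group enter a binomial
likelihood with success probability `sr(T)`; the combinatorial constant is
omitted since it cancels from every comparison made here. Intersex
individuals are excluded by default (configurable: count as female, male,
or half each), because how experimenters interpret intersexes is one of the
study-level effects the hierarchical model is meant to absorb.

## The growth reaction norm, TSP and CTE

The instantaneous embryonic growth rate follows the 4-parameter
Schoolfield form with low-temperature inhibition,

$$r(T) = \rho_{25}\,\frac{T_K}{298.15}\,
\frac{\exp\!\big[\tfrac{\Delta H_A}{R}(\tfrac{1}{298.15} - \tfrac{1}{T_K})\big]}
{1 + \exp\!\big[\tfrac{\Delta H_L}{R}(\tfrac{1}{T_{1/2L}} - \tfrac{1}{T_K})\big]},$$

with `T_K = T + 273.15` and `R = 8.314` J mol⁻¹ K⁻¹. We take this variant
as the normative formula for the package. Embryo size (straight carapace
length, SCL) grows exponentially, `dSCL/dt = r(T(t)) · SCL`, from
`scl0 = 1.7` mm to the hatchling size (defaults 59.3 mm for the Northwest
Atlantic, 57.3 mm for Malaysia; configurable per dataset and per duration
row). The growth law itself is a modelling choice — the quantities used
downstream (relative stage timing, CTE weights) are invariant to monotone
re-parameterisations of size, so the exponential form is the simplest
adequate one. Integration is a fixed-step trapezoidal update on log-SCL
(step 60 min, linear interpolation of temperatures); halving the step
changes durations by well under 0.05%.

The TSP is delineated on the size axis: stages 23 and 27 are mapped to SCL
thresholds expressed as fractions of hatchling size. The exact SCL values
for those stages come from external staging tables that are not reproduced
here, so the defaults (1/3 and 2/3) are explicit placeholders, exposed as
`stage_fracs` everywhere they are used. Because growth accelerates with
temperature, the TSP is generally *not* the middle third of incubation
time — a warm late phase shifts it later in absolute time than a warm
early phase, and even at constant temperature exponential growth places the
middle third of size late in incubation.

The constant-temperature equivalent of a fluctuating series is the
time-average of temperature within the TSP weighted by the instantaneous
growth rate at the recorded temperature (the growth-rate-weighted "model 6"
proxy); the plain mean is provided as a comparator only. Since `r(T)`
increases over the relevant range, the weighted CTE is at least the mean,
with equality only for constant series. When posterior draws of the growth
parameters are supplied, the TSP is re-delineated for every draw (its
timing depends on the growth norm) and the posterior median CTE is
reported; for near-constant tropical series the credible interval is very
narrow.

## Bayesian estimation

Both fitters use an adaptive Metropolis-within-Gibbs sampler written for
this package. Each iteration makes one Gaussian random-walk proposal per
parameter; per-parameter scales adapt in batches of 50 during burn-in
toward a 0.44 acceptance rate and are then frozen. Because the three curve
parameters are strongly correlated a posteriori, the sampler additionally
makes three multivariate random-walk proposals per iteration on the global
block, with covariance `2.38²/d` times the running empirical covariance of
the chain history (Haario-type adaptation, whose recursive form diminishes
naturally). Chains are bit-reproducible given a seed; the default protocol
is 1000 burn-in iterations, 10,000 sampling iterations, thinning of 10.

Priors are deliberately wide: `P ~ U(25, 35)` °C, `S ~ U(0.05, 20)`,
`dS ~ U(-S + 0.05, 20)` (keeping both limbs increasing), and uniform boxes
on the four growth parameters. Random-effect structures form the nested
chain `1`, `(1|RMU)`, `(1|RMU/ID)`, `(1|RMU/ID/Clutch)`; group deviations
are additive on each of `P`, `S`, `dS`, independent across parameters, in
non-centred parameterisation (`theta_group = theta + sigma * z`,
`z ~ N(0,1)`) with half-normal(1) priors on the level SDs. Treating "random
effects on the three parameters" as additive deviations, and treating the
deviations as independent across parameters, are interpretations; both are
stated here rather than buried in code. Initial values are data-informed
(median observed temperature, unit slope); if the posterior is not finite
there, starts are re-drawn from the prior (at most 100 times) before
failing loudly.

The growth likelihood is Gaussian on each duration-summary row's mean with
standard error `sd_days / sqrt(n)`, which carries the same information as
simulating individual Gaussian durations per egg while keeping summaries —
the form the literature actually reports — as the interface. Records with
fluctuating temperatures enter the TSD fit at one temperature each, their
posterior-median CTE|TSP.

Model comparison follows the posterior-predictive convention: for every
retained draw, each model's AICc (`-2 loglik + 2k + 2k(k+1)/(n-k-1)`) is
evaluated at that model's own draw-d parameters, the set is converted to
Akaike weights, and means and standard errors are taken across draws.
`k` counts the global parameters plus one per estimated random-effect SD
(three per nesting level); `n` is the number of sexed eggs for TSD models
and the number of duration observations for growth models. Both conventions
are configurable choices, documented because the comparisons among
random-effect structures depend on them.

## What the synthetic generators emulate

`gen_sexcounts()` is the generative twin of the hierarchical model:
nested Gaussian deviations on `P`, `S`, `dS`, then binomial sex counts per
clutch. `gen_temperature_series()` emulates tropical incubation-box
records: a mean level, a small sinusoidal nychthemeral cycle, smooth drift
and Gaussian jitter, sampled daily by default (the cadence of the
historical Malaysian records). `gen_durations()` adds Gaussian noise to
deterministic predictions. The defaults are chosen to look like the real
study systems: means 27–31 °C, sub-degree daily amplitude, durations of
roughly 53–76 days across 27–31 °C under `default_growth_params()`
(about 60 days at 29.5 °C), and the TSD curve of
`default_flexit_params()` (`P = 29.49`, `S1 = 2.34`, `S2 = 2.83`, TRT95
about 0.6 °C). What the generators do *not* emulate: metabolic heating,
beach thermal microclimate, stage-dependent sexualisation strength within
the TSP, or sub-lethal growth decline at high temperature. Tests passing on
these generators therefore validate the estimation machinery, not those
field complications.

## Validation designs and problem sizes

The package's own validation suite uses deliberately modest problem sizes
so that it runs quickly while remaining informative:

* Parameter recovery: growth — five constant temperatures (27–31 °C),
  20 eggs per temperature, duration noise SD 2 days; posterior-median
  `r(T)` within 10% of truth on 27–33 °C. TSD — 20 clutches of 10 eggs
  across 27–32 °C; posterior-median `P` within 0.2 °C of truth.
* Pooled-versus-separate growth norms: a common-norm dataset at the real
  sample sizes (110 constant-temperature eggs in five groups plus four
  fluctuating series carrying 70 eggs); the pooled model should take the
  majority of the Akaike weight.
* Clutch-effect detection: 12 clutches of 15 eggs with `sigma_P = 0.3` °C
  at five temperatures spanning the TRT (29.2–29.8 °C), 20 replicates;
  the clutch-RE model should win the weight comparison, and the clutch SD
  should be recovered within [0.1, 0.6], in at least 80% of replicates.
  The temperatures sit inside the TRT by design: a 0.3 °C clutch shift is
  only observable where the sex ratio responds to it, which is also how
  real TSD experiments place their incubators. Replicated studies use
  shortened chains (burn-in 400, 2000 iterations, thin 4), which recover
  the same posteriors as the default protocol to within Monte-Carlo error
  on these small datasets.
* CTE invariants (bounds, weighted ≥ mean, constant-series identity) on
  1000 random sinusoid-plus-drift series.

## Numerical choices and degenerate inputs

Probabilities inside the binomial likelihood are clipped to
`[1e-15, 1 - 1e-15]`; all logistics are evaluated through `plogis`, so
nothing overflows even 100 °C from the pivot. A series too short for the
embryo to hatch raises a structured error carrying the attained SCL
(`tsdnorm_no_hatch`); inside the growth fitter the series is instead
extended at its final temperature, which keeps the likelihood finite for
parameter values proposed during burn-in. Empty data, zero-count records,
missing nesting labels, non-overlapping TSP windows and too-small `n` in
AICc each raise their own condition classes. Records are sorted into a
canonical order before fitting, so posterior draws are invariant to input
row permutation at a fixed seed. Sex-ratio ties in the TRT round-trip are
only meaningful where the limits sit outside the QBT transition zone
(about 0.12 °C around `P`); for extremely steep curves the blending
contributes at the `1e-5` level there.

## Known limitations

The TSP stage fractions are placeholders pending a staging table. RMU and
study effects are nearly confounded in the published datasets (few studies
per RMU), so the hierarchical model can rank their structures but not
separate their variances well. The growth-norm likelihood treats group
means as Gaussian, which is adequate for the reported summaries but ignores
any skew in individual durations. Within-record temperature fluctuation
effects on sexualisation (beyond the CTE summary) are out of scope, as is
hatching-success modelling.
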