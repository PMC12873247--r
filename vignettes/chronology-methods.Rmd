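---
title: "Bayesian phase chronologies for fossil collections: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian phase chronologies for fossil collections: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neochron)
```

This vignette is the package's own account of its science: the model and
its assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, the numerical choices, and the design
decisions that were genuinely open. It states no empirical result that the
test suite does not itself compute.

## The problem

Fossil collections in community-paleoecology databases are organized as
collection units holding analysis units (typically strata). A minority of
analysis units carry geochronological dates — mostly uncalibrated
radiocarbon ages, occasionally luminescence, uranium-series, or
pre-calibrated ages — and those dates anchor the ages of everything else in
the collection. To compare assemblages across sites and against other
proxies, all of this must be translated into calendar years (cal BP, before
1950 CE) with honest uncertainty, including for the undated units.

`neochron` does this in four stages: calibrate individual dates, fit a
Bayesian phase model per collection unit, extract two styles of chronology
from the posterior, and propagate ranges to undated units through
stratigraphic rules.

## Calibration

A radiocarbon measurement $x \pm \sigma$ relates to calendar age $\theta$
through a calibration curve $\mu(\theta)$ with curve uncertainty
$\sigma_c(\theta)$. The calibrated density on a grid of calendar ages is

$$p(\theta) \propto \frac{1}{s(\theta)}
  \exp\!\left(-\frac{(x-\mu(\theta))^2}{2\,s(\theta)^2}\right),
  \qquad s(\theta)^2 = \sigma^2 + \sigma_c(\theta)^2,$$

normalized to sum to one over the grid. Curves are read from the IntCal
`.14c` dialect (comment lines, then cal BP / ¹⁴C age / 1σ columns, comma- or
whitespace-separated, extra columns ignored), re-sorted if necessary, and
linearly interpolated onto a uniform 1- or 5-year grid clipped at 55,000 cal
BP — the practical ceiling of the radiocarbon method.

**Asymmetric errors.** A handful of legacy dates carry asymmetric errors
(e.g. "1200, −110/+70"). These are modeled as a *two-piece* Gaussian: the
older-side spread applies above the measurement, the younger-side spread
below, with the shared two-piece normalizer $2/\sqrt{2\pi}(\sigma_-+\sigma_+)$
so the density is continuous at the mode and the below-mode mass is
$\sigma_-/(\sigma_-+\sigma_+)$, as the closed form requires. A per-side
$1/\sigma$ would be discontinuous at the mode and silently equalize the two
side masses; the symmetric case reduces to the standard $1/s(\theta)$
weighting either way. How the original OxCal runs treated these twelve dates
is not recorded; this is our choice and it is tested against the closed-form
two-piece quantiles.

**Calendar-scale dates** (TL, OSL, U-series, Ar-Ar, paleomagnetic,
pre-calibrated radiocarbon) skip the curve: the (two-piece) Gaussian sits
directly on the calendar axis, truncated to the model grid and renormalized.

**Quantile convention.** All quantiles in this package are measured *from
the old end*: `density_quantile(d, q)` is the age with a fraction `q` of
the mass at older ages. Hence the 0.05 quantile is an *older* limit and
0.95 a *younger* limit, and reported triples always satisfy
younger ≤ age ≤ older. This is the only convention consistent with the
database fields the output mirrors (`agelimitolder` > `age` >
`agelimityounger`). Quantiles are linearly interpolated within a grid cell
and rounded to integer years, matching the integer ages the database
schema stores.

**Chron controls.** Each usable date is also summarized independently of
the model — median and 5%/95% from-old limits of its own calibrated
density — as the chronology's control points. Using the independent density
rather than the per-date model posterior is a documented choice; the two
coincide for single-date units.

## The phase model

All dates in one analysis unit are grouped into a *phase*: conditional on
an older boundary $\alpha$ and younger boundary $\beta$ (cal BP), the event
ages $t_i$ are i.i.d. uniform on $[\beta, \alpha]$. With $n$ dated events,

$$p(\alpha, \beta, t \mid \text{data}) \;\propto\;
  \prod_{i=1}^n d_i(t_i)\,\mathbf{1}[\beta \le t_i \le \alpha]\;
  (\alpha-\beta)^{-n}\,(\alpha-\beta)^{s},$$

where $d_i$ is the calibrated density of date $i$ and $s$ is the span-prior
exponent (below). Boundaries are supported on the calibration-curve range.
If the analysis units have a clear stratigraphic order — an explicit
declared order, or distinct numeric depths (deeper = older) — phases are
chained oldest→youngest by $\beta_{\text{older}} \ge \alpha_{\text{younger}}$,
each phase keeping its own boundary pair. Ambiguity (ties in depth, partial
depths) degrades to an unordered model with a warning: a "clear" order
either exists or it does not.

### The span prior: why the default is $s = 0$

The only stated constraint from the modeling tradition this follows is
"uniform prior distributions", which leaves the boundary prior open. The
package exposes the exponent (`span_prior_exponent`): $s=0$ is the flat
prior on the boundary pair (the classical uniform-phase posterior), and
`"n-1"` makes the *posterior span distribution* asymptotically flat.

The default is $s = 0$, for two reasons the test suite reproduces:

* **Frequentist calibration.** On the parameter-recovery design the
  acceptance suite runs (50 simulated collections, 2 units × 2 dates,
  spans 200–2,000 yr, lab errors 30–150 ¹⁴C yr), the 95% posterior
  intervals of the boundaries cover the true boundaries ~93% of the time
  under $s=0$. Under $s = n-1$ with curve-range boundary support, the
  posterior span is nearly flat up to the full support width, boundary
  posteriors become extremely diffuse yet *shifted away from the data*
  (the lower edge of the $\alpha$ interval hugs the oldest event while the
  mass runs to the support ceiling), and measured coverage drops to ~70%.
* **Proximity to published output.** Reconstructing the published worked
  example's two phases from its printed calibrated medians and sigmas, the
  $s=0$ posterior boundary medians overshoot the printed values by roughly
  1–3 kyr on a 55 kyr support, while $s=n-1$ overshoots by 6–9 kyr. Neither
  is exact — the original software restricts boundary support in ways that
  are not documented in the publication — but $s=0$ is clearly the closer
  simple convention.

Because of that support sensitivity, reproduction of the published
per-collection numbers can only be approximate; the acceptance test for the
worked example carries a ±150 yr stochastic tolerance and reports the span
prior used.

### Sampling

The sampler is Metropolis-within-Gibbs in which every conditional is drawn
*exactly* (all proposals accepted):

* each event from its calibrated density restricted to $[\beta, \alpha]$,
  by inverse CDF on the grid;
* each boundary from its power-law conditional
  $(\alpha-\beta)^{s-n}$ on the interval allowed by the events, the curve
  range, and any ordering neighbor, by closed-form inverse CDF;
* a predictive event — "the expected value of a new date drawn from the
  same pool" — uniformly on $[\beta, \alpha]$ at each kept iteration.

Defaults: 2 chains × 25,000 iterations, 5,000 burn-in, thinning 5,
initialization at the calibrated medians with boundaries one grid step
outside the phase extremes (ordered models first repair any
order-incompatible medians by redrawing events inside order-compatible
windows; an unrepairable start is an error). Split-chain $\hat R$ and an
autocorrelation-sum effective sample size are computed for every monitored
quantity; any $\hat R > 1.05$ attaches a warning to the result — never
silently. Because the conditionals are exact, mixing is essentially
immediate and chain length only controls Monte-Carlo noise; the test suite
exploits this by running shorter chains where it says so.

**Span floor.** Events live on a grid while boundaries are continuous. For
net exponents $s - n \le -2$ (e.g. the default with $n \ge 2$), a state
with all events on one grid node and $\alpha,\beta$ collapsing onto it is
absorbing — the exact continuous-boundary posterior is improper at zero
span. Fully gridded implementations are immune by construction; the
continuous equivalent used here floors the span at one grid step inside the
boundary updates (yielding to a tighter ordering window where necessary).
The test oracle integrates boundary cells in closed form under the same
floor, and sampler-vs-oracle medians agree to a few years.

## The two chronologies

From the posterior of each dated analysis unit:

| chronology | older limit | central age | younger limit |
|---|---|---|---|
| bounds | median of $\alpha$ draws | — | median of $\beta$ draws |
| event | 0.3173 from-old quantile of predictive draws | median | 0.6827 from-old quantile |

The *bounds* chronology estimates the depositional window and is the
conservative default: boundary distributions are strongly outward-skewed,
and their medians avoid the worst of that artifact while still widening
honestly when dates are few. The *event* chronology gives a central age
with deliberately damped 32%/68% limits, because predictive distributions
for sparse phases sit between normal and uniform and tail quantiles would
be noisy. All ages are rounded to integer years. Bounds rows never carry a
central age; event rows carry one exactly for directly dated units.

## Undated analysis units

Undated units receive ranges from the dated ones by deterministic rules,
classified from a `subset_of` link, shared numeric depths, or the declared
order (in that precedence); "top" of a unit maps to its younger limit and
"bottom" to its older limit, per superposition:

* **a** subset of a dated unit → copy its range;
* **b** bounded between dated units → older limit from the top of the unit
  below, younger from the bottom of the unit above;
* **b1** as b but the two dated ranges overlap (closed-interval test) →
  time-averaging is assumed; full combined range;
* **c** above all dated units → older limit from the top of the unit
  below; younger limit 0 cal BP (1950 CE) unless externally constrained;
* **d** below all dated units → younger limit from the bottom of the unit
  above; older limit only from an external (biostratigraphic or
  archeological) constraint, else left undefined with a warning — a
  configurable cap exists but synthesizing a constraint by default would
  manufacture information;
* **e** no apparent stratigraphic relation → full range of all dated units.

No central age is ever estimated for an undated unit. Each chronology
(event, bounds) feeds its *own* dated ranges into the rules — the source
material does not say which was used, and this is the only choice that
keeps each chronology self-consistent. Collection-level bounds are then the
most generous max/min over *all* units, dated and inferred; a rule-d unit
with undefined older limit contributes only its younger limit.

## Date filtering and eligibility

Before modeling, dates are excluded with one primary reason each, checked
in a fixed order: `single_sided` (e.g. ">31,500"), `modern` (stored age
≤ 10), `zero_error` (missing or zero errors), `rejected` (by the original
author), `human_remains`. Flags are authoritative on fixtures; an optional
keyword scan of the material/method text ("reject", "human") is off by
default because free-text matching is site-idiosyncratic. A collection is
eligible only if at least one usable *radiocarbon* date has a younger
1-sigma estimate (age − error) under 30,000 ¹⁴C BP; collections with only
calendar-scale dates get no new chronology.

## Synthetic data: what a green test establishes

The generator emulates exactly the statistical structure the model assumes:
a curve of known form (identity, linear, or linear plus bounded sinusoidal
wiggles), phase windows with log-uniform spans of 200–2,000 yr, events
uniform within windows, observed ages $\mu(t) + \mathcal N(0, \sigma_{lab})$
with $\sigma_{lab}$ log-uniform on 30–150 ¹⁴C yr — values chosen once to
resemble a Holocene-dominated small-mammal date set at desk-scale runtimes —
plus optional ordering and undated units placed to exercise every inference
rule. It does *not* emulate real-data pathologies: calibration-curve
plateaus and reversals at full IntCal scale, inter-laboratory offsets,
outliers and misassigned dates, reservoir effects, taphonomic and geographic
bias, or violated phase-uniformity. Green parameter-recovery tests
therefore establish internal correctness and calibration of the
implementation under its own assumptions, not robustness to model
misspecification.

## Numerical choices

* Grid resolution 1 yr (5 yr option for speed); quantiles interpolated then
  rounded to integers.
* Densities normalized to $\sum p = 1 \pm 10^{-9}$; a date whose density is
  numerically zero everywhere on the grid is an out-of-range error, not a
  silent flat density.
* Boundary support = curve range; span floored at one grid step (above).
* Ties in collection-level max/min need no tie-break (equal values).
* No reservoir or δ¹³C corrections: ages are used as stored.
* Seeds: one user seed drives per-chain seeds; identical seeds give
  identical draws, bit-for-bit.

## Known limitations

* The exact prior normalization of the original OxCal runs is not
  recoverable from the publication; per-collection reproduction is
  approximate by construction (span-prior and boundary-support sensitivity
  above).
* Asymmetric-error handling is a documented assumption, not a reproduction.
* Outlier models, deposition-rate models (P/V_Sequence), marine curves,
  F14C input, and curve mixing are out of scope.
* The stratigraphic classifier consumes explicit metadata (links, depths,
  declared order); it does not parse free-text stratigraphic descriptions.
* The Neotoma API reader maps one specific response shape and is exercised
  only when a network is available; all other tests run on bundled or
  generated fixtures.
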