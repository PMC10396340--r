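---
title: "Boundary-layer shedding and chemical uptake at a contracting surface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary-layer shedding and chemical uptake at a contracting surface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shedflux)
```

## The model

Small sessile aquatic animals such as the freshwater polyp *Hydra* exchange
chemical compounds — oxygen, metabolites, antimicrobials — with the
surrounding water across their epithelial surface, where their symbiotic
microbes also live. At the sub-millimetre scales and sub-mm/s speeds involved,
the Reynolds number is of order $10^{-2}$ and the Péclet number far below one:
between movements, transport is purely diffusive, and a chemically depleted
*concentration boundary layer* grows around the animal. Recurrent whole-body
contractions, however, are fast enough (head speeds of order 10 mm/s for about
a second) to *shed* the fluid envelope that travels with the body — and with
it the depleted layer — so that each contraction restarts the diffusion
transient from a fresh, compound-rich environment.

`shedflux` implements this picture as a coupled physical–stochastic model:

1. **Transport.** The head is idealised as a sphere of radius $a$ absorbing a
   compound of diffusivity $D$ from a quiescent fluid at far-field
   concentration $C_\infty$. After a reset at $t = 0$ the concentration field
   is
   $$C(t, r) = C_\infty\left[1 - \frac{a}{r} +
     \frac{a}{r}\,\mathrm{erf}\!\left(\frac{r - a}{\sqrt{4Dt}}\right)\right],$$
   the uptake rate is
   $I(t) = I_{ss}\bigl(1 + \sqrt{\tau/(\pi t)}\bigr)$ with the Smoluchowski
   rate $I_{ss} = 4\pi D C_\infty a$ and the diffusion time
   $\tau = a^2/D$, and the uptake accumulated over an inter-contraction
   interval $T_i$ is
   $J_i = I_{ss} T_i\bigl(1 + \tfrac{2}{\sqrt{\pi}}\sqrt{\tau/T_i}\bigr)$.
   An emitting surface (compound produced at the surface, zero far field) is
   the exact mirror image, $\tilde C = C_\infty - C$, so absorption covers
   both directions of exchange.

2. **Contractions.** Contraction events form a Poisson process of rate
   $\lambda$; inter-contraction intervals are exponential with mean
   $1/\lambda$. Over a horizon $T$ partitioned by resets into intervals
   $T_i$, the cumulative uptake in excess of steady state is
   $$\frac{\Delta J}{J_{ss}} =
     \frac{1}{T}\sum_i \frac{2}{\sqrt{\pi}}\sqrt{\tau T_i},$$
   a sum of non-negative terms: contractions can only add uptake. The
   per-interval excess $y_i = \tfrac{2}{\sqrt{\pi}}\sqrt{\tau T_i}$ (in
   seconds of steady-state uptake) follows a Rayleigh law with mean
   $\sqrt{\tau/\lambda}$ and variance $(4-\pi)\tau/(\pi\lambda)$, and the
   cumulative gain has mean $\sqrt{\lambda\tau}$ and variance
   $(4-\pi)\tau/(\pi T)$. More frequent contractions shorten each interval's
   harvest but reset the depletion layer more often; the net effect grows as
   $\sqrt{\lambda}$.

3. **Kinematics.** The parameters that feed the stochastic layer are
   estimated from tracking data: body length from head/foot coordinates,
   peak contractions from the shortening rate (25% of body length per second
   or more), contraction episodes and their inter-event intervals, and the
   contraction rate both as a direct average and as an exponential
   maximum-likelihood fit. The fluid-boundary-layer thickness is read off
   velocity-magnitude profiles as the distance at which the speed has decayed
   by 90% toward the free stream.

## Two bookkeeping conventions for the event process

The package deliberately contains two constructions of a contraction
schedule, used in different places:

* `sample_schedule()` draws i.i.d. exponential gaps until the horizon is
  exceeded — a genuine renewal construction of the Poisson process. This is
  what a recorded animal produces and what the synthetic kinematics
  generator uses.
* The Monte-Carlo layer (`run_realization()`, `sweep_uptake()`) instead
  draws the number of intervals $N$ from Poisson($\lambda T$), counting the
  $t = 0$ reset among the events, and places the $N - 1$ interior reset
  times uniformly on $(0, T)$; the final interval is censored at $T$.

The distinction matters for precision claims. The model's moment formulas
are derived from $T = \sum_{i=1}^N T_i$ with $\mathbb{E}[N] = \lambda T$,
which is exactly the second bookkeeping. A renewal draw that keeps the
censored tail as an extra interval has mean gain
$\sqrt{\lambda\tau}\,\bigl(1 + 1/(2\lambda T)\bigr)$ — a bias of 2% at
$\lambda = 0.5$/hr over 48 hr, which is some twenty Monte-Carlo standard
errors at $10^4$ replicates; discarding the tail gives the mirror-image
deficit. The interval-count construction reproduces both the mean and the
variance within Monte-Carlo error at all rates we test, and is therefore
the default for simulation experiments. The censored tail is always
*included* as an uptake interval (a depletion layer grows there too);
at $\lambda = 0$ this leaves the single pure-diffusion transient
$\tfrac{2}{\sqrt{\pi}}\sqrt{\tau/T}$ rather than exactly zero, which is the
physically sensible limit of an animal that never contracts but still starts
from fresh fluid.

## Parameters, units, defaults

Internally everything is seconds and millimetres; rates cross the interface
in events per hour and horizons in hours, and file columns carry unit
suffixes (`_s`, `_mm`, `_per_hr`) so the two systems cannot be silently
mixed.

| parameter | default | why |
|---|---|---|
| head radius $a$ | 0.25 mm | typical polyp head scale |
| diffusivity $D$ | 1.5e-3 mm²/s | oxygen-like value in cool fresh water |
| far concentration $C_\infty$ | 1 | normalized; all results of record are relative ($I/I_{ss}$, $\Delta J/J_{ss}$) |
| $\tau = a^2/D$ | derived (41.7 s; sweeps use a round 40 s) | diffusion time of the head |
| horizon $T$ | 48 hr | length of the emulated chronic experiments |
| contraction budget | 144 events | $3\,\mathrm{hr}^{-1} \times 48\,\mathrm{hr}$, the baseline activity |
| PC threshold | 0.25 /s | definition of a peak contraction |
| PC merge gap | 10 s | see below |
| viscosity $\nu$ | 1.0034 mm²/s | water at 20 °C |

The absolute values of $a$, $D$ and $C_\infty$ are conveniences for
dimensional output only; none of the normalized results depend on them
except through $\tau$.

**Merge gap.** Peak contractions belonging to one spontaneous-contraction
episode are separated by at most the ~1 s shortening phase plus a brief
plateau, so any merge window comfortably above a few seconds groups them.
The window must also stay well below typical inter-episode gaps: with
Poisson events at $\lambda$, a window $g$ fuses a fraction
$1 - e^{-\lambda g}$ of genuine episode pairs — at 3/hr, about 4.9% for a
60 s window but only 0.8% for 10 s. Since the recovery requirements on the
estimated rate are of the same few-percent order, the default is 10 s
(configurable).

**Sub-frame detection.** At the time-lapse rate of 20 frames/min a 1-s peak
contraction lives between two frames. The detector therefore thresholds the
*drop* of relative length between consecutive frames against
`threshold × min(frame interval, 1 s)`: at video rates this is the
instantaneous rate criterion; at time-lapse rates it assumes the drop took
at most the ~1 s a peak contraction lasts. The relative length is computed
against a trailing 5-minute running maximum of the median-filtered length,
which tracks the extended state without absolute calibration and makes
detection invariant to spatial scaling of the tracks.

## The synthetic-data generator

`generate_kinematics()` emulates the recordings the kinematics module was
built for: Poisson-timed episodes; a linear drop to 20% of extended length
within ~1 s (optionally split into two peak contractions with a 1 s
plateau, an even mix by default since the relative frequency of one- versus
two-peak episodes is not quantified); exponential re-extension with a 60 s
time constant (95% re-extension in ~3 min, i.e. "slow, over minutes", and
fast enough that an episode following within ~20 s is still detectable);
a slowly revolving body axis; i.i.d. Gaussian positional noise (1% of body
length by default); sampling at 20 frames/min. `generate_velocity_profile()`
plants a known 90%-decay distance into linear, exponential or erf-shaped
profiles; `generate_intervals()` supplies exponential gaps for the rate
estimator.

What the generator does *not* emulate — and what passing the end-to-end
tests therefore does not demonstrate on real data: manual-tracking error
structure (drift, mislabels rather than i.i.d. jitter), episodes with
irregular multi-step shortening, somersaults and other non-contraction
movements that could trigger the rate criterion, refractory periods or
circadian modulation of the event process, and any flow-field physics (the
velocity profiles are parametric shapes, not PIV output).

## Numerical choices

* All uptake quantities come from closed forms; quadrature of the flux
  transient exists only as a test oracle (agreement to $10^{-6}$ relative).
  The diffusion-equation residual of the concentration field is likewise a
  finite-difference test oracle, evaluated away from the first instants
  after a reset where no fixed grid resolves the $\sqrt{t}$-thin layer.
* At $t = 0$ the erf argument is taken in the limit (far-field value off
  the surface) rather than raising an error.
* Monte-Carlo sweeps derive one RNG substream per (seed, rate-index) pair
  and draw all replicates of that rate vectorised from it, so a sweep is
  bit-reproducible for a given seed; replicate-level substreams were
  rejected because R's RNG makes them prohibitively slow at this scale.
* `find_optimal_rate()` breaks plateau ties toward the smallest rate within
  one Monte-Carlo standard error of the maximum.
* An event falling exactly on the horizon contributes a zero-length
  censored stub, which is dropped.
* Degenerate inputs (zero rate, empty schedules, fewer than two intervals
  for the exponential fit, profiles that never reach the decay threshold)
  return documented zero/`NA` results or fail with descriptive validation
  errors rather than propagating `NaN`s.

## Problem sizes used in the shipped analyses

The numbered scripts under `analysis/` and the acceptance script run the
sweep on a $0$–$10$/hr grid at $0.25$ steps with 2,000 replicates per rate
(the full experiment uses $0.05$ steps and 10,000 replicates; the
reduction factors are recorded in the output sidecars), the moment checks
with 10,000 replicates, and the end-to-end rate recovery with 20–50
replicate 48-hr recordings. These sizes hold every Monte-Carlo standard
error an order of magnitude below the effects being measured.

## Known limitations

* The transport model is a single non-interacting sphere; the static foot
  is represented only as the permanent steady state, and the head–foot
  separation, while recorded, enters no formula.
* Resets are instantaneous and complete; partial shedding or post-
  contraction refilling dynamics are not modelled.
* Advection is neglected throughout (the Pe ≪ 1 regime); the package
  provides the Péclet calculator but no advective transport.
* The contraction budget is a hard cap, the crudest possible energetic
  constraint.
* The exponential-fit rate estimator inherits the detector's episode
  merging: at very high rates or very long merge windows it
  underestimates; the bias is quantified on synthetic data in
  `analysis/04_rate_recovery.R`.
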