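---
title: "A hybrid Boolean/piecewise-linear model of the mammalian cell cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid Boolean/piecewise-linear model of the mammalian cell cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`hybridcycle` simulates proliferating mammalian cells with a hybrid of
discrete and continuous dynamics.  Three cyclins (A, B, E) are tracked
as continuous concentrations obeying, within any regulatory state, the
linear kinetics

    d[CycX]/dt = ks_x - kd_x [CycX]

whose solution is the closed form

    [CycX](t) = ks/kd + ([CycX](0) - ks/kd) exp(-kd t).

The regulators — two lumped transcription factors (TFE, driving
cyclins E and A early in the cycle; TFB, driving cyclins B and A late)
and four ubiquitination activities (SCF on cyclin E; Cdc20A on cyclin
A; Cdc20B on cyclin B; Cdh1 on cyclins A and B) — are Boolean
variables.  Rather than updating by Boolean functions, they traverse a
fixed sequence of nine states once per cycle (the dominant path of
Boolean cell-cycle networks, the "super highway"): G1a, early G1b,
late G1b, S, G2, prophase, prometaphase/metaphase, anaphase,
telophase.  Each state contributes additive terms to the effective
`ks`/`kd` of each cyclin, so every cyclin follows a piecewise-linear
ODE that is solved analytically — the production code never integrates
numerically.

The time spent in state *i* is `T_i = T_det,i + T_stoch,i`:

* `T_det` is 0 in states 1, 6, 7, 8; a fixed 7 h in state 4 (a minimum
  duration for DNA synthesis); and a threshold-crossing time in states
  2, 3, 5, 9.  State 2 exits when the cyclin E *amount*
  `[CycE]·M` reaches `theta_E` (size control); state 3 when `[CycA]`
  reaches `theta_A` (S entry); state 5 when `[CycB]` rises past
  `theta_B'` (mitotic entry); state 9 when `[CycB]` falls below
  `theta_B''` (division).
* `T_stoch` is exponentially distributed with mean `lambda_i`,
  computed from a uniform deviate `r` as `-lambda_i log r`.

Cell mass grows exponentially, `M(t) = M(0) exp(gamma t)` (a linear
mode is provided as a configuration switch and gives similar
behaviour).  At division the mother splits into fractions `delta` and
`1 - delta`, with `delta ~ Normal(0.5, 0.0167)`; daughters inherit the
mother's cyclin *concentrations* unchanged.  Because state 2 couples
exit to `[CycE]·M`, large-born cells commit sooner and small-born
cells later, which drives the birth-size distribution to a stable
stationary form and locks the mean cycle length to the mass doubling
time `ln 2 / gamma` in balanced growth.

## Parameters

All defaults live in a single packaged YAML file
(`hc_default_config_path()`), each key tagged with its provenance:

* **Fixed by the underlying study** (tag `paper`): the state-1
  effective rates for cyclin A (`ks = 5`, `kd = 1.4` AU/h and 1/h),
  `lambda_1 = 2` h, the 7 h S-phase floor, the threshold quartet
  {`theta_A = 12.5`, `theta_E = 21.25`, `theta_B'' = 3`,
  `theta_B' = 80`}, `delta ~ N(0.5, 0.0167)`, the per-cycle threshold
  noise factor `G ~ N(1, 0.033)`, instrument noise SDs (0.03 DNA,
  0.15 cyclin), and the initial conditions `[Cyc] = 1`, `M = 3`.
* **Calibrated by this package** (tag `calibrated`): the remaining
  rate increments and `lambda_i`.  They were chosen once so that the
  default parameter set satisfies three structural properties: a mean
  cycle of about 20 h (`gamma = ln 2 / 20` per hour), cyclin A at S
  entry near 8% of the population-maximum total cyclin A (mean
  S-entry total ≈ 50 AU against a 99th percentile ≈ 600 AU), and a
  contact-inhibited culture that plateaus around day 6.  A cell
  spends roughly 2 h in G1a, 5.5 h in early G1b, minutes in late G1b,
  7.5 h in S, 2.5 h in G2 and 2.5 h in mitosis.

Calibration choices worth recording:

* `lambda_2 = 0`: the transition out of early G1b has no stochastic
  component; its timing is entirely set by the size-control threshold.
* `lambda_3 = 0`: with a stochastic tail in late G1b, cyclin A
  overshoots `theta_A` before S entry and the S-entry total lands far
  above the ~8% anchor; with `lambda_3 = 0` S entry occurs at the
  crossing itself.  The remaining `lambda_4..9 = 0.5` h supply the
  cycle-length variability.
* Threshold symbol assignment: `theta_E` acts on the amount
  `[CycE]·M` (that is what makes it a size control), `theta_A` on the
  cyclin A concentration, and the two cyclin B thresholds on its
  concentration for the rising (80) and falling (3) crossings.  The
  assignment is config-overridable.
* The per-cycle noise factor `G` multiplies the thresholds: one draw
  per threshold per cycle, giving cell-to-cell variability in
  commitment points.  Setting `threshold_noise_sd: 0` disables it.

## Numerical choices

* Concentration crossings are inverted in closed form,
  `t* = log((C0 - ks/kd)/(theta - ks/kd))/kd`.  Amount crossings
  solve the transcendental `C(t) M(t) = theta` by doubling a bracket
  and refining with `stats::uniroot` at tolerance 1e-10 h.
* A threshold on the wrong side of the asymptote `ks/kd` (or not
  reached within 10^4 h for amount crossings) is *unreachable*:
  solvers return `Inf` and the simulator aborts with a diagnostic
  naming the state — this indicates a mis-specified configuration.
* A threshold already satisfied at state entry returns crossing time
  0; with monotone progression along the fixed state sequence this is
  the consistent continuation (it occurs, for example, when a low
  draw of `G` puts `theta_A` below the cyclin A level carried in from
  state 2).
* Division asymmetry is clipped to `(0.1, 0.9)`; at SD 0.0167 the
  clip is a ~18-sigma event, so it exists only as a guard and clip
  events are counted in the lineage output.
* Boundary convention: a cell exactly at a state boundary belongs to
  the later state (half-open residence intervals).  In a fully
  deterministic configuration state 1 has zero residence, so a
  newborn is located in state 2 at age 0.

## The asynchronous flow sample

To emulate flow cytometry of an exponentially expanding culture, each
simulated life history is assigned a cycle fraction `phi` with density
proportional to `2^-phi` on [0, 1] (newborns are twice as dense as
dividing cells), inverted from a uniform deviate as
`phi = -log2(1 - r/2)`.  At age `phi · A9` the cell's state, exact
cyclin concentrations, mass and DNA content (1 before S, linear
through S, 2 after) are read out; the instrument observables are the
*total* amounts `[CycX]·M`.  Measured channels are the true values
times independent `Normal(1, sd)` factors (0.03 for DNA, 0.15 for
cyclins); true values are kept alongside, and mass is exported
noise-free.  Negative measured values are possible in principle but
vanishingly rare; they are left in place and counted.

## Contact inhibition

The population simulator tracks every cell with an event queue (a
binary min-heap on event time).  The G1a exit rate falls with the
number of live cells `N` through the logistic form

    p(N) = p0 / (1 + exp((N - N0) / N1)),

which satisfies the documented limits (≈ `p0` for small `N`, sharp
drop around `N0` when `N1 << N0`).  Each cell entering G1a draws its
waiting time as exponential with mean `1/p(N)` evaluated at that
moment, and keeps it (no re-evaluation during the wait); cells whose
wait extends past the simulation horizon are left arrested in G1a —
the quiescent G0 interpretation of state 1.  Defaults follow the
study conditions: 500 starting cells, `p0 = 0.5` per hour,
`N0 = 11000`, `N1 = 500`, 10 days, daily snapshots of count and
G0/G1-S-G2/M fractions.

With these settings the culture crosses `N0` during days 4-5, the
cells already committed complete one further division, and the count
levels off near 2.4 × `N0` with >98% of cells in G0/G1.  Under the
operational plateau definition used here (first day with <5% daily
increase) the default run plateaus on day 7, the tail end of the
committed-cell wave; the population is within a few percent of its
final size from day 6 onward.

## What the generator does and does not emulate

The synthetic data reproduce the *mechanisms* the model contains:
balanced exponential growth, size-controlled commitment, stochastic
state residence, division asymmetry, the asynchronous age density,
multiplicative measurement noise, and density-dependent arrest.  They
do not contain features of real cytometry data that the model
excludes by construction: cell death or detachment, 4C→8C cycling,
doublets and debris, gating or compensation artefacts, autofluorescence
background, or biological heterogeneity beyond the modelled noise
sources.  Tests passing on these data therefore validate the
simulator's internal consistency and its agreement with the printed
model properties — not the model's fidelity to any particular
experimental dataset.

## Problem sizes

The test suite runs the study-scale configurations directly: 32,500
lineage iterations with 500 discarded as burn-in (the retained 32,000
histories feed a 32,000-event flow sample), 10^5-10^6 draws for
distributional checks, and the full 10-day contact-inhibition run.
Unit tests use smaller lineages (1,000-5,000 cells) where only
consistency, not tail behaviour, is at stake.

## Limitations

* The Boolean layer is not autonomous: perturbations that leave the
  fixed nine-state sequence (drug treatments, checkpoint mutants)
  cannot be represented without additional update rules.
* `gamma` is a free parameter; the default ties it to a 20 h doubling
  time.  A helper experiment (fit of log-counts in the uninhibited
  population test) checks that realized growth matches `ln 2 / mean
  cycle`, but no experimental counts are fitted by the package.
* The contact-inhibition form of `p(N)` is one sigmoid satisfying the
  documented limits; the exact functional form is pluggable via the
  parameters rather than asserted.

## A worked single cell

```{r example}
library(hybridcycle)

cfg <- model_config()
set.seed(1)
cell <- simulate_cycle(cfg)
cell
# boundary concentrations, one row per state exit
round(cell$conc, 3)
```
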