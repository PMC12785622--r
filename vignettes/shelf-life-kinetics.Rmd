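---
title: "Shelf-life kinetics: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shelf-life kinetics: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shelfkin)
```

## The procedure

Accelerated shelf-life testing stores a product at elevated temperatures to
speed up its dominant degradation chemistry, fits a kinetic model to each
storage condition, and uses the Arrhenius relation to carry the rate
constants to the temperatures a consumer will actually see. `shelfkin`
implements that chain for quality attributes measured over storage time —
instrumental values such as CIELAB lightness, and hedonic panel means on
the 9-point scale — and validates the predictions against the panel data
themselves.

The pipeline is: (1) per packaging × temperature condition, fit a
zero-order (linear) and a first-order (log-linear) decay to the attribute
series and keep the order with the higher coefficient of determination;
(2) regress `ln k` on reciprocal absolute temperature to estimate the
activation energy `Ea` and, where needed, extrapolate `k`; (3) invert the
selected model at the rejection value `Qe` to get the predicted shelf life
`t_s`; (4) read the experimental shelf life off the censored sensory series
and tabulate actual vs predicted.

### Assumptions

* One dominant, temperature-accelerated degradation mechanism per
  attribute, so a single (Ea, A) pair describes all temperatures. The
  packaged study itself illustrates the limit of this assumption: in the
  best barrier packaging at 4 °C the browning chemistry is largely
  suppressed and failure shifts to slower mechanisms, so the long
  extrapolated shelf life there is a projection, not a validated value.
* Quality decays monotonically and the panel mean is the quality signal;
  individual-consumer variation enters only through the session mean and
  its standard deviation.
* Rejection is an absorbing state: once a session fails, later sessions
  are not observed (the storage tables' `-` cells), which censors the
  series rather than truncating the analysis.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `q0` | 6.3 | hedonic score | measured week-0 color-acceptance mean of the packaged study |
| `qe`, `threshold` | 5.0 | hedonic score | the scale midpoint "neither like nor dislike"; below it a product is disliked |
| `attribute` | `color_acceptance` | — | color drives consumer rejection for this product class |
| `include_baseline` | `TRUE` | — | the week-0 value is a real observation; excluding it is offered because it moves `k` in its last digit |
| `rounding` | `floor` | weeks | completed weeks is the conservative label claim |
| `k_source` | `fitted` | — | `printed` and `arrhenius` re-use a published rate table instead |
| gas constant | 8.314 | J/(mol K) | Kelvin conversion adds 273.15, applied only inside the Arrhenius module |

Rejection uses a *strict* inequality (a mean of exactly 5.0 passes). This
is not cosmetic: the air-packed aluminum series at 4 °C ends at exactly 5.0
in week 24, and only the strict rule reproduces its observed open bound
`>24` weeks. Experimental shelf life is the last passing session time, not
an interpolated crossing — panels every three weeks simply cannot resolve
the crossing finer, and pretending otherwise would manufacture precision.

The deciding attribute defaults to color acceptance rather than overall
acceptance: color is what drives rejection for this browning-limited
product, and the overall-acceptance series disagree with the recorded
shelf-life endings in one condition (the nitrogen bag at 45 °C), while the
color series reproduce all of them.

## Fitting choices

Both kinetic fits are two-parameter ordinary least squares (through
`stats::lm`) with a free intercept; `k = −slope`. The first-order fit runs
on `ln Q`, and its R² is reported on that fitting scale. Free intercepts
matter: forcing the regression through the measured baseline produces rate
constants far from the published tables, while free-intercept fits land
within rounding of them. Fits are unweighted — the source tables publish
single R² values consistent with unweighted fits and no weighting scheme —
and detection-limit records (`<limit`) are excluded, since a non-detect is
not a value. A constant series has zero explained variance; we define
R² = 0 there (rather than NaN) so flat attributes select cleanly.

Published rate tables could not be reproduced exactly from the published
series under any standard OLS variant (with or without the baseline, free
or forced intercept); the original fitting protocol is ambiguous, and two
table cells are off-scale by an order of magnitude against their
neighbours (kept verbatim in the fixtures, flagged `scale_suspect`).
Consequently the package's tests hold fixture-derived rate constants to
closed-form OLS oracles, not to the printed digits, and activation
energies only loosely (the refits land within ±3 kJ/mol of the published
45.74/44.85/40.38 kJ/mol). Similarly, the published 58/23/14-week
predictions at 4 °C (and the nitrogen bag's at 25 °C, whose printed
k = 0.002 implies 115 weeks) follow from an unstated extrapolation and are
not targets; the ambient-and-above cells all reproduce exactly.

## The synthetic generator

`decay_scenario()` emulates an instrumental decay series: a known `Q0`, a
rate constant per storage temperature (defaults are the published
clear-plastic first-order color constants 0.012/0.028/0.075/0.11 per week
at 4/25/35/45 °C, a monotone, realistic set), Gaussian measurement noise
(default sd 0.05 score units), and measurements every 3 weeks to week 24.
`panel_scenario()` turns it into a consumer study: 50 consumers per
session, individual scores `Normal(model mean, 1.5)` clipped to [1, 9] and
rounded to whole scale points before averaging — so synthetic session
means show the same ±0.02 granularity as real panel tables — and censoring
of all sessions after the first failing one, driven by the *same* strict
threshold rule as the analysis.

Each temperature draws from its own seeded RNG substream, so a single
series can be regenerated without simulating the whole study, and
identical scenario + seed gives byte-identical CSV output.

What the generator does **not** emulate: correlated noise across sessions
or attributes, panelist-specific effects (each session redraws 50
independent consumers), drift in panel composition, and any microbial
dynamics. Passing the recovery tests therefore shows the estimator chain
is correct and adequately powered under idealized panel noise — not that
real panels satisfy those assumptions.

### Calibrated recovery rates (run once, then frozen)

* Instrumental noise (sd 0.05, nine points, k = 0.02/week): the refitted
  k landed within 15% of truth in 1000 of 1000 seeds.
* Full pipeline under panel noise (50 consumers, sd 1.5, sessions every 3
  weeks, censoring on, k = 0.028/week): predicted shelf life within ±3
  weeks of the analytic `ln(Q0/Qe)/k` in 487 of 500 seeds.
* Fast decay (k = 0.047/week, threshold crossing at 4.9 weeks): the
  simulated experimental shelf life was exactly 3 weeks in 176 of 200
  seeds (score discretization occasionally pushes a borderline session
  mean to 5).

These runs take seconds; they are part of the default test suite.

## Degenerate inputs and tie-breaks

Kinetic fits require at least three usable observations and non-constant
times; first-order fits refuse non-positive values, naming the offending
week. Arrhenius fits require three *distinct* temperatures and positive
rate constants. An exact R² tie between orders selects first order, the
conventional model for sensory decay. `qe ≥ q0` yields `t_s = 0` with an
"already rejected" flag rather than an error, so batch comparisons keep
going. Colour change is summarised with the CIE76 Euclidean ΔE against the
week-0 measurement of the same condition — the plain convention, chosen
because nothing in the source data constrains a fancier one.

## Known limitations

* Arrhenius extrapolation far below the calibration range inherits the
  single-mechanism assumption; treat long low-temperature predictions as
  projections (the packaged study's own 4 °C cells are the cautionary
  example: its nitrogen-bag Arrhenius fit has R² = 0.48 because one
  published rate constant is internally inconsistent).
* Experimental shelf life is resolved only to the panel schedule; with
  three-week sessions the `±` on an "exact" value is inherently one
  session.
* Sensory means are the modelling unit; no survival analysis of
  individual-consumer rejection is attempted, and panel sizes enter only
  through the recorded `n` and `sd` columns.
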