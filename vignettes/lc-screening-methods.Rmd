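---
title: "In silico screening of RP-LC conditions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico screening of RP-LC conditions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcscreen)
```

## The problem

Developing a reversed-phase liquid chromatography (RP-LC) method for a known
mixture means finding a mobile-phase pH and gradient time that separate every
pair of compounds, tolerate small perturbations of the conditions, and keep
the run short. The screening phase explores that factor space cheaply before
any optimization. `lcscreen` performs this screening in silico: it models
each compound's retention over pH and gradient time from a small designed
experiment (or from upstream retention predictions), propagates model error
by Monte Carlo, scores every candidate condition on three criteria, and
aggregates the scores into a desirability index whose robustness to the
analyst's criterion weights is quantified explicitly.

## Retention models selected by pKa

Retention versus pH follows a sigmoid around each pKa, because ionization
sharply reduces RP retention; only the part of the sigmoid inside the
working pH range is observable. Instead of stepwise selection, the model
equation is fixed by chemistry. With `log` the natural logarithm:

* no pKa anywhere near the pH range (`NO_PH`):
  \(\log t_R = \beta_0 + \beta_2 t_G\);
* a pKa within `outside_margin` of a range edge but not well inside
  (`ONE_PLATEAU`):
  \(\log t_R = \beta_0 + \beta_1 pH + \beta_2 t_G + \beta_{11} pH^2 +
  \beta_{12}\, pH\, t_G\);
* a pKa at least `edge_margin` inside the range (`TWO_PLATEAU`): the same
  plus \(\beta_{111} pH^3\), the cubic being the lowest-order polynomial
  able to carry two plateaus and the transition between them.

Both margins default to 1 pH unit: one unit changes the ionized fraction
roughly tenfold, i.e. about one sigmoid shoulder, so a pKa more than a unit
outside the range leaves no visible pH effect, and one more than a unit
inside shows both plateaus. When a compound has several pKa values, any
value in the interior window forces the cubic case — it is the transition
inside the range that matters. Both margins are user-configurable
(`select_equation()`).

Log retention, not retention, is modeled: the log scale makes the
gradient-time effect close to linear, makes multiplicative noise additive,
and guarantees positive back-transformed predictions. Coefficients are
estimated by ordinary least squares (`rsm_fit()`, QR-based, with explicit
rank and design checks: at least two distinct gradient times, and three or
four distinct pH levels for the quadratic and cubic cases). Calibration and
prediction diagnostics (R², RMSE, MAPE) are computed in minutes after
exponentiating predictions, the scale on which chromatographers read them.

## Error propagation

The predictive distribution of retention at a new condition is Student-t on
the log scale: located at the fitted linear predictor, scaled by the
residual standard deviation, with the model's residual degrees of freedom,
then exponentiated (`simulate.rsm_model()`). The t replaces the normal as a
heavier-tailed, more cautious choice given the very small residual degrees
of freedom (4–8 under the default ten-condition design). Locating and
scaling on the log scale rather than in minutes is a deliberate choice: the
model, its residuals, and the residual sd all live on the log scale, and
exponentiation keeps every draw positive. The default is 1000 draws per
compound and condition, a compromise between the Monte-Carlo error of a 10%
quantile and runtime; each compound receives an independent seeded stream
derived from the configuration seed.

## The three criteria

Over a uniform condition grid (default pH 2.7–8.0 in steps of 0.1 and tG
20–60 min in steps of 2, 1134 conditions), computed from the draw cube
(`criteria_surfaces()`):

* **Separation S** (minutes, maximize): per condition, compounds are
  ordered by decreasing point-predicted retention; for each adjacent pair
  the per-draw gap minus the later peak's left and the earlier peak's right
  baseline half-widths is formed; the 10% quantile over draws is taken per
  pair and the minimum over pairs kept. The ordering is fixed per condition
  from point predictions, not per draw — re-sorting every draw would
  conflate elution-order uncertainty with gap uncertainty, and near a
  crossing would make the "critical pair" ill-defined. Negative S flags
  predicted co-elution at baseline. User-supplied left/right half-widths
  let peak asymmetry and large concentration imbalances be represented.
* **Sensitivity R** (maximize its desirability by minimizing it — the
  criterion itself is a robustness penalty, see below): the mean of the
  absolute first derivatives of S along the two axes, by central finite
  differences inside the grid and one-sided differences at its borders.
  Derivatives are taken on coded axes, each mapped linearly to [−1, 1], so
  a dimensionless pH step and a gradient-time step in minutes contribute
  comparably; raw-axis derivatives would let the axis units set the
  balance.
* **Analysis time A** (minutes, minimize): the maximum over compounds of
  the 90% quantile of each compound's draws — the run length needed for
  everything to elute with high probability.

S is maximized, R minimized (a separation that collapses under a small
drift of pH is not robust), A minimized.

## Desirability and weight robustness

Each criterion surface is rescaled to [0, 1] by a linear ramp between its
observed minimum and maximum over the evaluated grid (`scale_criterion()`),
so the analyst supplies no limits; fixed limits can be given to override.
The ramp is linear by design — with run-relative limits any smooth
monotone alternative mostly reparameterizes the same ordering, and the
function sits behind an interface so another family can be substituted. A
constant criterion rescales to 1 everywhere (it cannot discriminate). The
desirability index is the weighted geometric mean

\[D = d_S^{w_S/\Sigma w}\, d_R^{w_R/\Sigma w}\, d_A^{w_A/\Sigma w},\]

with default weights 1 (separation, the "must have"), 0.5 (sensitivity)
and 0.1 (analysis time, "nice to have"). Weights are normalized to sum to
one before exponentiation so that D is a true mean: it stays in [0, 1],
equals the common value when all desirabilities agree, and is zero whenever
any positively-weighted criterion is fully undesirable — the veto property
that motivates the geometric over the arithmetic mean. Only weight ratios
matter, which is also what makes the Dirichlet construction below coherent.

The analyst's weights are an honest statement of relative importance, not
exact numbers. That uncertainty is modeled by a Dirichlet distribution on
the weight simplex with concentration \(\alpha_i = w_i \times c\); the
confidence factor \(c\) (default 100, giving \(\alpha = (100, 50, 10)\))
sets how tightly draws cluster around the stated ratios. For each of 1000
sampled weight vectors the index is recomputed — the per-criterion
desirabilities are frozen, only the weights vary, which isolates weight
uncertainty from retention uncertainty — and each condition receives the
probability of reaching the desirability threshold
(`probability_surface()`). A condition exactly at the threshold counts as
reaching it. The default Dirichlet sample size (1000) mirrors the
retention draw count; both are configurable.

## Threshold, regions, optima

The desirability threshold is chosen automatically as the smallest observed
index value whose super-level set has strictly positive separation
everywhere — acceptable conditions must never imply co-elution
(`auto_threshold()`). The search runs over the sorted distinct index
values, which suffices because admissibility can only change at an observed
value. A fixed threshold (e.g. 0.5) can be supplied instead. If every
condition co-elutes, screening fails with a diagnostic rather than
recommending an unusable condition; if the index maximum itself co-elutes
while some other condition separates, no threshold exists and the same
failure is raised.

Cells whose probability meets the probability threshold (default 30% — at
the screening stage a modest chance of success suffices) are segmented into
connected regions, under 8-connectivity by default (a raster band crossing
the grid diagonally remains one region; 4-connectivity is available).
Regions are ranked by size, ties broken by lower minimum pH then lower
minimum tG. Two conditions are reported: the global index maximum, and the
best condition inside the largest region — the latter leaves room to move
the condition later in the method's lifecycle without redeveloping it. All
argmax ties break lexicographically (lower pH, then lower tG) so results
are independent of traversal order.

## The synthetic generator

`sigmoid_truth()` / `generate_mixture()` emulate exactly the structure the
strategy assumes: a two-state ionization model in which log retention
interpolates between a neutral-form and an ionized-form linear function of
gradient time, with ionized fraction
\(f = 1/(1 + 10^{s k (pH - pK_a)})\) (\(s = +1\) for acids, \(-1\) for
bases, \(k\) the Hill-type steepness), plus lognormal observation noise.
The packaged seven-compound mixture (`demo_mixture()`) spans all three
model cases, spreads the compounds out around pH 6 at moderate gradient
times, and lets elution orders cross elsewhere, so its screening map shows
both a well-separated pocket and dark co-elution bands. Its transitions use
Hill slope 0.5 — broad, as for partially buffered methanol–water gradients
— which keeps the cubic's tracking error of the sigmoid below 0.02 log
units over the grid at unit log-amplitude; noise sd 0.03 corresponds to
roughly 3% multiplicative retention error, the scale of routine
instrument-to-instrument variability. Half-widths are 0.5 min for all
peaks.

What the generator does **not** emulate: peak shapes and widths as
functions of conditions (widths are user-supplied constants), detector
response, retention mechanisms beyond the two-state model (ion pairing,
silanol interactions, temperature), or correlated errors between
conditions. Passing tests on synthetic data therefore demonstrate that the
pipeline's statistics behave as designed when their assumptions hold — not
that the polynomial models fit any particular real sample.

## Numerical choices and degenerate inputs

* Natural log throughout; back-transformed predictions are base-invariant,
  coefficients are not.
* Empirical quantiles use the standard interpolation between order
  statistics (R's default type 7).
* Retention tables must be strictly positive; non-positive values are
  rejected with their line numbers at read time and row indices at fit
  time.
* Mild extrapolation beyond the training box warns and proceeds (the
  design itself predicts at an interior gradient time from a two-level
  training design); it is never silent.
* A constant criterion surface maps to desirability 1; a zero desirability
  under a zero weight is treated as \(d^0 = 1\) (the criterion is dropped,
  not vetoed).
* Zero Dirichlet concentrations are refused: a criterion is dropped
  explicitly, not by zeroing its weight.
* Seeded functions snapshot and restore the caller's RNG state.

## Problem sizes

The test suite exercises the full default problem size — 7 compounds,
54 × 21 grid, 1000 retention and 1000 weight draws — in its end-to-end
determinism check (a few seconds), and smaller grids (e.g. 11 × 5, 150–200
draws) elsewhere so that oracle comparisons across hundreds of random cases
stay fast. Oracle checks cover: OLS versus the normal equations, quantile
criteria versus sort-based recomputation, finite differences versus an
explicit stencil, weight-robustness probabilities versus brute-force
per-draw recomputation, and region labeling versus flood fill.

## Known limitations

* The strategy inherits the accuracy of its inputs: with experimental
  retention times it screens the measured mixture; with upstream-predicted
  retention times all of their error propagates.
* The gradient-time effect is first-order; strongly curved \(\log t_R\)
  versus \(t_G\) relationships (very early or very late eluters under
  steep gradients) are approximated.
* Expected peak half-widths must be supplied by the user; they are not
  predicted.
* The Student-t error model is a pragmatic frequentist stand-in for a full
  posterior predictive; a Bayesian retention model would propagate
  parameter uncertainty too, at the cost of priors and sampling.
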