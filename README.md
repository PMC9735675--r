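# lcscreen

In silico screening of reversed-phase liquid chromatography (RP-LC)
conditions for known small-molecule mixtures.

Choosing a mobile-phase pH and gradient time that separate every compound
in a mixture, tolerate small perturbations, and keep the run short is the
slowest part of early LC method development. `lcscreen` replaces the
trial-and-error part of the screening phase with computation: from a small
designed experiment (or upstream retention predictions) it models each
compound's retention surface, propagates model error by Monte Carlo, scores
every candidate condition on separation, robustness and analysis time, and
recommends conditions whose quality is insensitive to how the analyst
weights those criteria. It is written for analytical chemists and
method-development scientists.

## The model

For each compound, the natural log of retention time is a fixed polynomial
in pH and gradient time t<sub>G</sub>, selected from the compound's pKa
(retention versus pH is sigmoidal around a pKa, and only the part inside
the working range is visible):

| case | when | equation |
|---|---|---|
| `NO_PH` | no pKa within 1 unit of the pH range | log t<sub>R</sub> = β₀ + β₂t<sub>G</sub> |
| `ONE_PLATEAU` | pKa near a range edge | log t<sub>R</sub> = β₀ + β₁pH + β₂t<sub>G</sub> + β₁₁pH² + β₁₂pH·t<sub>G</sub> |
| `TWO_PLATEAU` | pKa ≥ 1 unit inside the range | … + β₁₁₁pH³ |

Models are fitted by OLS; prediction error at new conditions is sampled as
exp(μ̂ + σ̂·T) with T Student-t on the residual degrees of freedom. From the
draws, three criteria are computed over a pH × t<sub>G</sub> grid: the
baseline separation of the critical pair S (10% quantile of the adjacent-
pair gap minus peak half-widths), the sensitivity of S to the conditions
(mean |∂S| on coded axes), and the analysis time (max over compounds of the
90% retention quantile). Each is rescaled to [0, 1] and combined into the
weighted geometric-mean desirability index

D = d_S^(w_S/Σw) · d_R^(w_R/Σw) · d_A^(w_A/Σw),  weights (1, 0.5, 0.1).

Robustness to the weights is quantified by sampling weight vectors from a
Dirichlet distribution (concentration = weights × 100) and mapping, per
condition, the probability that D reaches its threshold. Grid cells with
probability ≥ 30% form connected candidate regions; the global and
largest-region optima are reported.

## Worked example

The package ships a seven-compound synthetic mixture generator spanning all
three model cases (see `?demo_mixture`; the generator emulates sigmoidal
pH dependence around a pKa, a linear gradient-time effect on log retention,
and 3% multiplicative noise):

```r
library(lcscreen)
mix <- demo_mixture()                                  # 7 compounds x 10 conditions
res <- lc_screen(mix$retention, mix$metadata, lc_config(seed = 1))
summary(res)
```

```
In silico LC screening of 7 compounds over 1134 conditions
Model cases: neutralA (NO_PH), neutralB (NO_PH), acidEdge (ONE_PLATEAU),
  baseEdge (ONE_PLATEAU), acidMid (TWO_PLATEAU), baseMid (TWO_PLATEAU),
  acidMid2 (TWO_PLATEAU)
Desirability threshold used: 0.6688; 7 robust region(s)
Global optimum: pH 4.80, tG 56 min (D = 0.761)
Largest-region optimum: pH 4.80, tG 56 min (D = 0.761, 9 cells)

Per-compound calibration:
 compound        case r_squared rmsec_min mapec_pct
 neutralA       NO_PH     0.984     0.119      1.78
 neutralB       NO_PH     0.986     0.351      2.58
 acidEdge ONE_PLATEAU     0.993     0.155      1.55
 baseEdge ONE_PLATEAU     0.992     1.487      2.05
  acidMid TWO_PLATEAU     0.999     0.287      1.20
  baseMid TWO_PLATEAU     0.997     0.954      2.23
 acidMid2 TWO_PLATEAU     0.996     0.808      1.75

Robust regions (P >= 0.3 ):
 region_id size best_ph best_tg best_index
         1    9     4.8      56      0.761
         2    4     3.4      60      0.707
         ...
```

Reading this: every compound was assigned its equation from its pKa and
calibrates with R² ≥ 0.98 and 1–3% mean absolute error. The automatic
desirability threshold (0.6688) is the lowest index level above which no
condition co-elutes. The recommended starting point for optimization is
pH 4.8 with a 56-min gradient, which also sits in the largest
weight-robust region (9 grid cells) — the screening map's dark bands
elsewhere are predicted co-elutions. `plot(res)` draws the desirability
heatmap with the region contour and optimum markers;
`write_screening(res, "out/")` exports models, surfaces, region
membership, a provenance record and a text report.

A thin CLI wraps the same functions
(`inst/cli/lcscreen <fit|screen|simulate|report> ...`).

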