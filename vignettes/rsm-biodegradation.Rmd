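---
title: "Response-surface optimisation of n-dodecane biodegradation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-surface optimisation of n-dodecane biodegradation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsmbe)
```

## The problem

Hydrocarbon-degrading bacteria mineralise *n*-alkanes at rates that depend
strongly on culture conditions — medium pH, incubation temperature, substrate
(diesel) load and salinity. Optimising those conditions one factor at a time
misses interactions, so the standard workflow in this field is two-stage
design of experiments: a Plackett–Burman screen to confirm which factors
matter, then a central composite design (CCD) to map the response surface and
predict the optimum. `rsmbe` implements that workflow end to end for a
percentage response (here, *n*-dodecane mineralisation measured by GC-FID),
and ships the 30-run CCD tables of two Antarctic diesel-degrading isolates —
a *Pseudomonas* strain (ADL15) and a *Rhodococcus* strain (ADL36) — as
plain-text fixtures against which every stage is validated.

## Factor coding

Each factor is defined by a centre and a step (`factor_def()`), so that the
coded level $x = (\text{actual} - \text{centre})/\text{step}$ places the
design on the integer grid $\{-2,-1,0,+1,+2\}$. The packaged geometry is:

| factor | units | centre | step |
|---|---|---|---|
| pH | – | 7.25 | 0.75 |
| temperature | °C | 20 | 10 |
| diesel | % v/v | 2.5 | 1.5 |
| NaCl | % w/v | 1.0 | 1.0 |

Two concentrations have planned coded $-2$ levels that are physically
negative (diesel $-0.5$ % v/v, NaCl $-1.0$ % w/v). Those runs are *executed*
at zero (the `clamp_floor` of the factor, applied by
`decode_level(..., for_bench = TRUE)`), but all coding arithmetic and all
regression use the planned coded levels. This matters: the predicted-value
columns of the packaged tables are only reproduced when the clamped runs keep
their coded $-2$, which is how the original analysis treated them.

## Designs

`make_ccd()` builds the Box–Wilson CCD: $2^k$ factorial points at $\pm 1$,
$2k$ axial points at $\pm\alpha$ (default $\alpha = 2$, matching the
five-level geometry above), and replicated centre points (default 6). For
$k = 4$ that is the 30-run design of the packaged tables. The generated
coded matrix is orthogonal between linear terms and between linear and
interaction terms; tests verify this by brute-force inner products.

`make_plackett_burman()` implements the standard cyclic constructions for 8,
12, 16 and 20 runs. Columns not assigned to real factors are retained as
dummy factors; `pb_effects()` estimates each main effect as
$\bar y_{+} - \bar y_{-}$ and tests it against the pseudo standard error
$\sqrt{\text{mean}(\text{dummy effects}^2)}$ with one degree of freedom per
dummy column. The original screen's data were never published — only the
conclusion that all four factors were influential — so the screening stage is
validated by its orthogonality and contrast properties, not against printed
numbers.

Generated designs come out in canonical order with an optional seeded
shuffle; the randomised bench order of the packaged tables is preserved by
the fixture loader rather than re-simulated.

## The second-order model

`fit_quadratic()` fits, by ordinary least squares in coded units,

$$Y = \beta_0 + \sum_{i=1}^{k} \beta_i x_i + \sum_{i=1}^{k} \beta_{ii} x_i^2
  + \sum_{i<j} \beta_{ij} x_i x_j,$$

with $p = 1 + 2k + k(k-1)/2$ terms (15 for $k = 4$). Responses are the
printed triplicate means treated as single observations; per-run replicate
spreads were not published, so replicate-level variance is not modelled.

`anova_quadratic()` reports:

* **per-term partial SS** (extra sum of squares: the rise in residual SS
  when that single term is dropped from the otherwise full model). Whether
  the original software used sequential or partial SS is not documented; the
  partial choice is the one that reproduces the published term rows, and
  tests verify each term's SS against an explicit refit-without-term oracle.
  On an orthogonal CCD the distinction is minor, but the squared terms are
  mutually correlated, so it is not vacuous.
* **lack of fit vs pure error**: replicate groups are runs with identical
  coded rows (tolerance $10^{-9}$) — here the six centre replicates — giving
  pure-error SS $\sum (y - \bar y_{\text{group}})^2$ and the lack-of-fit
  $F$ ratio against it.
* **fit statistics**: residual SD, CV%, $R^2$, adjusted $R^2$,
  $\text{PRESS} = \sum_i (e_i/(1-h_{ii}))^2$ (the hat-diagonal shortcut,
  proven in tests to equal explicit leave-one-out refitting), predicted
  $R^2 = 1 - \text{PRESS}/SS_{\text{total}}$, and adequate precision — the
  signal-to-noise measure
  $(\max \hat y - \min \hat y)/\sqrt{p \cdot \text{MSE}/n}$ over the design
  points, the definition that reproduces both published values (12.8 and
  18.5).

p-values come from the $F$ distribution; values below $10^{-4}$ print as
"< 0.0001" in text reports, mirroring the convention of the source tables.
All internal arithmetic is full precision; only display rounds.

## Optimisation

`stationary_point()` performs canonical analysis: with
$Y = \beta_0 + b^\top x + x^\top B x$ (where $B$ carries $\beta_{ii}$ on the
diagonal and $\beta_{ij}/2$ off it), the stationary point is
$x^* = -\tfrac{1}{2} B^{-1} b$, classified by the eigenvalues of $B$.

`maximize_box()` maximises the quadratic *exactly* over a coded box by
enumerating all $3^k$ face configurations (each coordinate free or pinned at
a bound), solving the reduced stationary system on each face and keeping the
best feasible candidate; vertices are the all-pinned configurations, so the
maximum cannot be missed. Ties break towards lexicographically smallest
coordinates for determinism. The default region is the factorial cube
$[-1,+1]^k$: the exact region used by the original optimisation is not
documented, but the factorial cube reproduces the published predicted
optimum for the *Pseudomonas* fit (36.33 %), whereas wider boxes give larger
values; it is also the region actually spanned by non-axial experiments. The
region is an explicit argument, not a constant.

Desirability uses the single-response "maximize" ramp with `low = 0` and
`target = 100` (the response is a percentage): the *Rhodococcus* optimum
predicts ≥ 100 % mineralisation inside the cube, hence desirability 1 —
matching the published optimisation summary.

## Biodegradation efficiency

GC-FID peaks are assigned to the C8–C20 *n*-alkane ladder by nearest
retention time within `rt_tol` (default 0.05 min; each label used at most
once, equidistant ties to the earlier peak), and each alkane's loss relative
to the abiotic control is

$$BE(\%) = 100 - \frac{A_s \times 100}{A_{ac}}.$$

Per-alkane BE uses per-compound areas; the pooled total uses summed areas
over the control's alkanes. Negative BE (a grown peak) is reported flagged,
not clipped, since it is useful abiotic-control QC. No retention times or
raw areas were published, so peak tables are CSV-level inputs and the
chromatogram stage is validated by generator round-trips.

## Synthetic data

`simulate_ccd_response()` draws CCD responses from a known coefficient set
plus iid Gaussian noise. The packaged coefficient sets (`eq_adl15`,
`eq_adl36`) with noise SDs 4.17 and 7.50 — the residual SDs of the two
packaged fits — are the calibration conditions used throughout the tests:
noiseless data must be recovered exactly, and at noise SD 7.50 the 95 %
coefficient confidence intervals cover the truth at nominal rate over 500
seeded replicates (observed ≈ 0.95; the acceptance test accepts 0.90–1.00).
Homoscedastic Gaussian noise is an assumption: the real responses are
bounded percentages whose variance likely shrinks near 0 and 100, so
passing simulations say nothing about heteroscedasticity in real data.

`simulate_chromatograms()` builds control/sample/standard peak tables from a
linear elution model `rt = 2.0 + 0.9 × carbon number` (minutes) — an
arbitrary but documented stand-in, since no retention times back the
fixtures — with specified per-alkane fractional reductions and optional
multiplicative area noise.

All generators are seeded and byte-reproducible; design noise and
chromatogram noise use independently seeded streams.

## Numerical choices and edge cases

* Rank-deficient model matrices and $n \le p$ abort with the offending
  terms named; leverages of 1 make PRESS undefined and are reported as
  missing with a warning rather than as infinities.
* Unicode minus signs (U+2212), common in copied tables, are normalised by
  the CSV readers; coded/actual column inconsistencies beyond $10^{-6}$ are
  rejected with row numbers.
* Designs with no replicated points omit the lack-of-fit split with a
  warning instead of dividing by a zero-df pure error.
* Fixture agreement tolerances reflect the fixtures' printing precision:
  the packaged responses carry two decimals, so refitted statistics on the
  sum-of-squares scale can differ from the published ones by order 0.1–1
  (< 0.05 % relative); coefficients and predictions agree to the printed
  two decimals.

## Problem sizes

Every validation runs at desk scale: 30-run fixtures, 50 random designs for
the leave-one-out identity, 500 simulation replicates for coverage. The
full suite completes in a few seconds.

## Known limitations

Single-response desirability only (no multi-response compromise); no ridge
analysis for near-singular quadratic forms; no Box–Behnken or fractional
factorial designs beyond Plackett–Burman; no chromatogram signal processing
(peak picking and integration are upstream of the peak-table inputs); no
model reduction — both published equations keep all 14 non-intercept terms,
significant or not, and the package follows that.
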