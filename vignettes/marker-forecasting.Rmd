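---
title: "Forecasting stem-cell marker kinetics with genetic programming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting stem-cell marker kinetics with genetic programming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerGP)
```

## The problem

Cancer stem-cell (CSC) subpopulations are tracked by flow cytometry as the
percentage of gated cells positive for stemness and drug-resistance markers
(ABCG2, ALDH1, CD24 and CD44, singly and in double-positive combinations).
When cultured tumour cells (the colorectal line HCT-116 and the metastatic
breast-cancer line MDA-MB-231) are exposed to 40 nm carboxylate-modified
polystyrene nanoparticles (PSNPs), these marker percentages change over the
hours following treatment. markerGP models each marker's time course with a
symbolic regressor evolved by a genetic algorithm, validates the fitted
expression *blind* at a held-out timepoint, and extrapolates expression
beyond the observation window.

The experimental design the package works with: measurements at
24, 33, 43 and 52 h after treatment are the training data; the 76 h
measurement is withheld as blind validation; 96 h is a pure forecast.
Each timepoint has three independent replicates, summarised by their mean.

## The model: symbolic regression by genetic programming

A candidate model is a rooted expression tree over the function set

> add, sub, mult, div, max, min (binary); sqrt, log, abs, neg, inv, sin,
> cos, tan (unary)

with leaves drawn from the terminal set: the time variable `t` or a constant
in a configured range (default $[-10, 10]$). Evaluation uses *protected*
operators so every tree is a total function: `div(a, b)` returns 1 when
$|b| \le \varepsilon$, `inv` likewise, `sqrt(a) = \sqrt{|a|}`,
`log(a) = \ln|a|` (0 near zero), and `tan` is clamped to $\pm 10^6$
($\varepsilon$ = `protected_epsilon`, default $10^{-6}$).

Fitness is the coefficient of determination on the training means,

$$R^2 = 1 - \frac{\mathrm{SSR}}{\mathrm{SST}},$$

with SSR the residual sum of squares of the tree's predictions and SST the
total sum of squares about the mean of the observations. When all observed
values are equal (SST $= 0$) the score is defined as 1 for an interpolating
model (maximum absolute residual below $10^{-9}$) and 0 otherwise.

Evolution is the standard generational loop: ramped half-and-half
initialization over depths 2–4, tournament selection (size 5) on the
*penalized* fitness $R^2 - c \cdot (\text{node count})$ with parsimony
coefficient $c = 0.001$, subtree crossover (p = 0.70), subtree mutation
(p = 0.15), point mutation (p = 0.10), reproduction (p = 0.05), one elite
carried unchanged per generation, a hard depth limit of 6, population 500,
and at most 100 generations or until the best raw fitness reaches 0.9999.
Every default is overridable through `ga_config()`.

Several design choices deserve explanation:

* **Parsimony pressure.** With only four training points, unconstrained
  trees interpolate the data exactly and extrapolate wildly. The per-node
  penalty and the depth cap push selection toward smaller expressions. The
  penalty acts on selection only; raw fitness decides elitism, early
  stopping and the final reported model, so the best training $R^2$ per
  generation is non-decreasing.
* **Constant refinement.** Point mutation of a constant leaf either
  redraws it uniformly or perturbs it by Gaussian creep at one of two
  scales (sd 0.5 or 0.02, equal odds, clamped to the constant range).
  In addition, the constants of each generation's best individual are
  polished by a bounded local search (Brent for one constant,
  Nelder–Mead for several) on the training $R^2$ — Lamarckian constant
  optimization, as used by mature symbolic-regression systems. Expression
  structure is searched by evolution; constants, a continuous
  sub-problem, respond far better to local optimization than to random
  redraws.
* **Diversity restart.** Targets that are nearly constant over the
  training window (e.g. a sine plus an offset) create a deceptive
  landscape: a well-tuned constant beats every structural stepping stone
  whose own constants are still rough, and the population can collapse to
  single-leaf constants that crossover cannot escape. After 15
  generations without improvement of the best raw fitness, the non-elite
  population is replaced by fresh random individuals; elites (and with
  them monotonicity of the best score) are preserved, so well-behaved
  runs are unaffected while collapsed ones get repeated fresh starts
  within the same generation budget.

**Time scaling.** Trees see $t = \text{hours}/24$, so the training inputs
are 1, 1.375, 1.79 and 2.17 — commensurate with the default constant range.
The scaling is recorded in every fit result, making expressions portable.

**Tie-breaking.** Tournaments resolve equal penalized fitness toward the
smaller tree, then the earlier draw; crossover children violating the depth
cap are retried up to 10 times before falling back to a copy of the first
parent. Both rules are deterministic under the seed.

## The fit / blind-validate / forecast protocol

`fit_predict_protocol()` computes per-timepoint replicate means, passes
*only* the four training means to the optimizer (the 76 h value is never
visible to `evolve()` — an interface guarantee, tested by perturbing the
blind value and checking that nothing upstream changes), then reports:

* `r2_train` — $R^2$ over the four training means;
* `r2_overall` — $R^2$ over all five means including the blind 76 h point.
  A single blind point admits no $R^2$ of its own (SST over one value is
  undefined), so the five-mean score is the reported "prediction score",
  with the absolute blind error reported separately;
* `abs_error_blind` — |prediction − observed mean| at 76 h, in percentage
  points;
* predictions at 76 h and 96 h, clamped to [0, 100] for reporting
  (unclamped values are retained under `predicted_raw`; all scores are
  computed from the unclamped predictions).

Fitting targets the per-timepoint means by default, matching how such
measurements are summarised (mean ± error over three experiments); fitting
every replicate point is available via `fit_replicates = TRUE`.

`run_suite()` applies the protocol to each of the nine model systems with a
per-system seed derived by hashing the system label into the master seed,
so results are reproducible and independent of suite composition.

## The synthetic-data generator

No per-timepoint measurement table is published for this design — only
per-system percentage ranges and qualitative descriptions of the kinetics.
The generator therefore *emulates* the study: it is parameterized by the
printed ranges and prose trends, and is not a reconstruction of the real
data. Each system is a `generator_spec` with one of five smooth trend
families anchored to its range over 24–76 h:

| family | shape | anchors |
|---|---|---|
| monotone_increase | linear | low at 24 h, high at 76 h |
| monotone_decrease | linear | high at 24 h, low at 76 h |
| dip_then_rise | quadratic | minimum (low) at 33 h, high at 76 h |
| rise_then_plateau | quadratic rise, then flat | low at 24 h; plateau at 95% of the range from 43 h |
| acute_peak_then_decline | quadratic decline | high at 24 h, flattening to low at 76 h |

These are the minimal smooth curves consistent with the described kinetics
(an early dip with a late rise; a steady increase; a steady decrease; an
early rise that stabilizes; an acute 24 h peak). The plateau sits at 95% of
the way up the range (rather than at the literal maximum) so that the
family, like all others, degenerates to a constant when the range collapses.

Replicate noise is additive Gaussian on the percentage scale (default sd
0.5 percentage points), truncated by clamping to [0, 100] — the published
summaries give dispersion only as mean ± error, so the noise level is a
declared emulation parameter, not an estimate. Control arms are flat at the
range midpoint by default; when a treated/control fold change at 52 h is
specified (2.5-fold for HCT-116 ALDH1), the control level is set to
trend(52 h)/fold so the noiseless ratio holds by construction. Whether real
control cultures drift over time is not quantified in the source material;
a flat control is an assumption.

The nine default systems and their ranges (percent of gated cells):

```{r suite}
specs <- default_study_specs()
data.frame(
  system = names(specs),
  family = vapply(specs, function(s) s$trend_family, character(1)),
  low = vapply(specs, function(s) s$range_low, numeric(1)),
  high = vapply(specs, function(s) s$range_high, numeric(1)),
  row.names = NULL
)
```

The MDA-MB-231 CD44 range is printed nowhere and is an assumption
(80–95%, typical of this strongly CD44-positive line), flagged by
`assumed_range = TRUE` and overridable in the YAML generator config. The
two MDA-MB-231 rows labelled "ABCG2+CD24+" and "ALDH1+CD24+" carry the
single-marker ABCG2 and ALDH1 ranges, the only printed ranges available
for them.

**What passing tests on synthetic data do and do not show.** The generator
reproduces the design (timepoints, replicates, ranges, qualitative shapes,
a fold-change anchor) but not features of real cytometry data: replicate
correlation within an experiment, heteroscedastic gating noise near 0% and
100%, day effects, or any biological feedback between sampling times.
Pipeline correctness and reproducibility claims transfer to real data;
accuracy numbers measured on synthetic data do not.

## Treated-vs-control comparison

`mann_whitney_exact()` computes the Mann–Whitney U from mid-rank sums. For
pooled sizes up to 12 the two-sided p-value is exact by full enumeration of
all $\binom{n_a+n_b}{n_a}$ group assignments of the pooled values (ties
handled exactly); beyond that the tie-corrected normal approximation with
continuity correction is used. With three replicates per arm the smallest
achievable two-sided exact p is $2/20 = 0.1$ — worth keeping in mind when
interpreting significance claims from triplicate designs. `compare_arms()`
tests every shared timepoint; no multiple-testing correction is applied
across timepoints or systems.

## Numerical and degenerate-case conventions

* $R^2$ on constant observations: 1 if interpolated to $10^{-9}$, else 0.
* Reported predictions clamped to [0, 100]; scores use raw predictions.
* Expression serialization prints constants with 17 significant digits, so
  text and JSON round trips preserve evaluation bit-for-bit.
* All randomness flows from explicit seeds (`withr::with_seed`); generator
  substreams per system come from a stable label hash, and callers' RNG
  state is never disturbed.

## Known limitations

Four training points under-determine a symbolic regression severely. The
depth cap and parsimony penalty temper, but cannot eliminate, interpolation
of replicate noise, and expressions that nearly interpolate four noisy
means can extrapolate poorly at 76 h and beyond; blind-validation scores on
noisy synthetic suites are therefore highly variable between systems and
seeds. Treat forecasts as hypotheses to test, not measurements. The
single-predictor design (time) is intentional: no dose, uptake or
mechanism covariates are modelled.

## Problem sizes used by the test suite

The package's tests exercise the full default configuration (population
500, up to 100 generations) for the nine-system suite run and the
function-recovery checks, and reduced budgets (populations 30–150, a
handful of generations) where only mechanics — determinism, leakage
isolation, invariants — are under test. Property sweeps use 200–1000
random cases per invariant under fixed seeds.
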