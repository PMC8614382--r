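---
title: "Benchmarking sheep meat farms: the DEA model, its reporting layer and the known-truth generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking sheep meat farms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sheepdea)
```

## The problem and the model

Farm accounting networks collect, for each sheep meat farm, a handful of
input aggregates and the revenue they generate. The question the package
answers is relative: given the inputs a farm actually used, how much more
revenue could it have generated if it were managed like the best farms of
its own production system? Data Envelopment Analysis answers it without
assuming a functional form for the technology: the production possibility
set is the convex hull of the observed farms (plus free disposability), and
each farm is scored against that empirical frontier.

The package implements the single-output, output-oriented model under
variable returns to scale. Four inputs describe a farm: flock size (ewes),
total labor in hours/year (family plus hired), variable costs (EUR/year) and
fixed capital costs (EUR/year); the output is gross revenue (EUR/year,
subsidies and compensations included). For farm $i$ among the $n$ farms of
one type, the radial phase solves

$$\max_{\theta_i, \lambda} \theta_i \quad \text{s.t.} \quad
\sum_j \lambda_j y_j \ge \theta_i y_i,\qquad
\sum_j \lambda_j x_{kj} \le x_{ki}\ \forall k,\qquad
\sum_j \lambda_j = 1,\ \lambda \ge 0 .$$

The convexity constraint $\sum_j\lambda_j = 1$ is what makes returns to
scale variable: a small farm is never benchmarked against a scaled-down copy
of a large one. Output orientation is the natural choice for a sector that
uses resources which would otherwise go unexploited (marginal grazing land):
inputs are held fixed and the feasible expansion of output is measured.
Technical efficiency is $TE_i = 1/\theta_i \in (0,1]$, and the frontier
(efficient-target) output is $y_i^{*} = \theta_i y_i + s_{out}$ after the
slack phase below. Farm types are always solved separately — four
independent frontiers for the four default types — because an extensive
farm and an intensive farm do not share a technology.

### Two-phase solution and slacks

The radial $\theta$ alone understates the distance to the frontier for
farms projected onto a weakly efficient facet: output can be expanded
radially no further, yet some input could still be reduced (or output
increased) without leaving the hull. Following the standard envelopment
treatment, a second LP at fixed $\theta_i$ maximizes the total slack
subject to $\sum_j\lambda_j y_j = \theta_i y_i + s_{out}$,
$\sum_j\lambda_j x_{kj} = x_{ki} - s_k$, $\sum_j\lambda_j = 1$, all slacks
nonnegative. Efficient targets therefore include both the proportional
increase and any further change associated with nonzero slacks.

The default slack objective is the raw sum across slacks in original units
(EUR, hours, head), matching the behaviour of common envelopment software;
because a raw sum across heterogeneous units is unit-sensitive, an
`input-mean-scaled` option divides each slack by the sample mean of its
dimension. The choice affects which of several alternate optimal slack
vectors is reported, never $\theta$ or TE.

A farm is *classified* efficient for grouping purposes when
$TE \ge 1 - \varepsilon$ with $\varepsilon = 10^{-6}$ (the published
groupings are by TE score alone), while the per-farm `is_efficient` flag is
stricter in the Koopmans sense: TE at one *and* all slacks zero at the
scale of the data. Both tolerances are exposed in `solver_settings()`.

### The LP engine and numerical choices

Each farm contributes two small LPs (a handful of rows, one column per peer
farm). These problems are routinely degenerate — ties on the frontier give
zero right-hand sides and multiple optimal bases — and off-the-shelf
routines available to the package proved fragile exactly there. The package
therefore carries its own dense two-phase simplex with Bland's anti-cycling
rule throughout: a few extra pivots on average, guaranteed termination, and
full control over tolerances (feasibility/pivot tolerance $10^{-7}$ by
default, configurable in `(0, 10^{-3})`). Inputs and outputs are scaled by
their column maxima before solving — $\theta$ is invariant to that — and
slacks are rescaled back to original units afterwards. The test suite
checks the engine against an exact vertex-enumeration oracle on small
instances and against an independent LP implementation on random programs;
alternate optimal $\lambda$ vectors are deliberately not disambiguated
(only $\theta$, TE, slacks and projections are contract-bearing).

Degenerate inputs are rejected early with row-level messages: nonpositive
revenue, fractional or zero flocks, negative inputs, or revenue components
that do not sum to gross revenue within a relative $10^{-3}$.

## The reporting layer

The reporting functions reproduce the standard presentation of farm
benchmarking studies, computed from unrounded internals:

* `te_frequency_table()` bins TE into `<0.60`, decade bins to `0.90`, a
  near-frontier bin and the efficient group. Intervals are half-open on the
  unrounded score with the top bin defined by $\varepsilon$, so a score of
  0.695 counts in `0.60-0.69` — printed interval labels describe rounded
  endpoints, but binning never rounds first.
* `projection_summary()` averages existing and slack-adjusted target output
  per flock-size class. Default class cuts are 350/450 ewes for both French
  types, 600/1000 for Spain and 400/900 for the UK; boundary flocks go to
  medium, matching interval labels such as "350–450". Empty classes are kept
  with a zero count rather than propagating NaN.
* `revenue_composition()` and `economic_indicators()` profile the efficient
  and inefficient groups. Group figures are **unweighted means over farms of
  per-ewe ratios**, not ratios of group sums; the choice is robust to
  flock-size skew and is recorded in the tables' `group_means` attribute.
  Unavailable components (UK subsidies) are excluded from totals and
  reported NA, never zeroed. Gross margin is gross revenue less feed plus
  variable capital cost — the only definition consistent with the published
  indicator tables, where e.g. 157 − 45 − 26 = 86 EUR/ewe — and profit is
  gross revenue less the four-component production cost.
* `category_adoption()` and `practice_frequency_ranking()` tabulate
  best-practice selections of efficient farms over a nine-category catalog;
  ranking ties keep catalog order (the published rankings do not order
  ties). The default catalog carries the twenty practices of the published
  cross-type ranking plus two generic product-processing entries, since the
  processing category appears in the category tables with no named
  practices; `practice_catalog()` accepts arbitrary replacements.

The shipped `benchmark_table()` aggregates (frequency bins, projection
pairs, composition means, indicator cells, practice counts for the four
farm types, accounting year 2015) serve two purposes: calibration targets
for the generator below, and worked-example inputs — e.g. re-tabulating the
frequency bins reproduces overall mean TE 0.709 (French extensive) and
0.873 (French intensive) at three decimals, and the projection pairs give
the published percent increases (37.2 %, 13.6 %, 13.0 %, 28.1 % for the
average farm of each type). Two cells are internally inconsistent in the
source material at the last printed digit (the French intensive small-farm
increase prints 7.16 where the printed means give 7.15; the Spanish and UK
overall mean TE round to 0.875/0.774 where 0.874/0.773 are printed); tests
assert those at one unit in the last printed digit instead of half a unit.

## The known-truth generator

Validating a frontier estimator on real data is circular: the true frontier
is unknown. The generator therefore *constructs* populations whose true
efficiencies are known exactly, while emulating the published structure of
the four farm types.

**Frontier.** $K$ anchor farms (default 8) are placed on a strictly
concave, increasing curve $y = c_0 + a\,s^{0.88}$ of an EUR-denominated
aggregate input $s = 25\,\text{ewes} + 12\,\text{labor} +
\text{variable} + \text{fixed}$, with flock sizes spread geometrically over
the type's size range and per-ewe input intensities declining gently with
size (labor exponent −0.12, fixed capital −0.15), echoing the economies of
scale visible in the published indicator tables. The positive intercept
$c_0$ makes returns to scale genuinely variable. Strict concavity
guarantees every anchor is a vertex of the VRS hull, so the hull of the
anchors *is* the true frontier.

**Farms.** Every non-anchor farm is placed at a convex combination of
anchor input profiles — concentrated on the two anchors bracketing its
target flock size, with a small random admixture (up to 12 %) of the others
so the inputs are not collinear — and its true frontier output $F(x)$ is
evaluated there by exact vertex enumeration (`frontier_output()`), a route
independent of the simplex engine. Its observed output is
$y = TE_{true}\cdot F(x)$: inefficiency is multiplicative in output, not
additive noise. Because scaled-down points never extend the hull and all
anchors are in the sample, the DEA-estimated frontier coincides with the
true one and the recovery property $|\widehat{TE} - TE_{true}| \le 10^{-6}$
is provable, not statistical; removing anchors shrinks the estimated hull
and biases $\widehat{TE}$ upward, never downward, which the tests also
assert.

**Calibration.** Per type, the defaults reproduce the published study
conditions: size-class counts (80/45/116, 22/13/26, 13/13/11, 44/46/29),
fully efficient counts (25, 22, 14, 22), the observed TE minima (0.313,
0.576, 0.57, 0.31), and inefficient TE drawn from a Beta law (concentration
6) rescaled to $[te_{min}, 0.995]$ with its mean set to the published
inefficient-group mean (0.675, 0.802, 0.798, 0.722) — which makes the
expected overall mean TE land on the published 0.709/0.873/0.874/0.773
without further tuning. Revenue components are drawn around the published
composition shares (log-normal jitter, sd 0.12) and forced to sum exactly
to gross revenue; UK subsidies are generated as NA. Per-ewe techno-economic
fields are derived from the generated inputs (wage 12 EUR/h, 1800 h per
annual labor unit, feed share of variable cost per the published split), so
the accounting identities hold by construction. Practice flags are
independent Bernoulli draws whose per-practice rate is solved from the
published category-level adoption rates via
$p = 1 - (1-c)^{1/k}$ for a $k$-practice category.

**What the generator does not emulate.** Real accounting data carry
measurement error on both sides of the frontier, correlation between farm
size and efficiency, within-type technology heterogeneity and reporting
gaps; the generator has none of these (inefficiency is one-sided and
independent of size). Passing the recovery tests therefore demonstrates the
correctness of the estimator and pipeline on the model's own assumptions —
it does not certify behaviour under noisy real-world data, where DEA is
known to be sensitive to outliers on the frontier.

**Determinism.** Each generation call consumes a single seeded RNG stream,
records the seed in its output, and restores the caller's RNG state, so a
given spec and seed reproduce a byte-identical population.

## Problem sizes and runtime

All defaults were chosen so a full validation run is interactive: the four
default populations total 458 farms, i.e. 916 LPs of at most 242 columns,
which solve in a few seconds; the enumeration oracle is exercised on
instances with $n \le 6$ DMUs and $m \le 2$ inputs (hundreds of instances
per minute); the known-truth recovery test uses a 250-farm population. The
per-farm LPs are independent, so n-fold larger samples scale linearly.

## Known limitations

* Only the output-oriented VRS model is provided — no input orientation, no
  CRS/scale-efficiency decomposition, no super-efficiency, no bootstrap
  confidence intervals.
* TE scores carry no sampling uncertainty: DEA is a deterministic
  benchmarking tool, and group comparisons in the reporting layer are
  descriptive, not inferential.
* The vertex-enumeration frontier evaluator is exponential in the anchor
  count and is intended for the generator's small anchor sets (up to ~12),
  not as a general solver.
* Monetary fields are taken as given; there is no currency conversion or
  deflation.
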