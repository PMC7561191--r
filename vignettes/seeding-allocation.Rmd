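---
title: "Hybrid seeding allocation of land-use change: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid seeding allocation of land-use change: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedalloc)
```

## The problem

County-scale land-use projections — so many cells of Forest becoming
Developed in a county over a decade — are too coarse for ecological
indicators such as forest fragmentation, water yield, or habitat
connectivity, which react to *where* on a 90 m raster the change lands.
`seedalloc` downscales such projections: given a time-1 categorical raster
(classes Developed `d`, Forest `f`, Agriculture `a`, Water `w`, Other
`o`), a county partition, and per-county gross transition quotas
$q_{ml}$ (cells of donor class $m$ to convert to target class $l$), it
produces stochastic fine-grain realizations of the time-2 raster whose
aggregate pattern statistics can be compared distributionally against
observations.

The central design goal is *distributional* analysis: rather than one
"best" map, the allocator generates a library of equally plausible
realizations, tunable along a continuum from random to contagious
allocation, so that landscape-pattern uncertainty can be propagated into
downstream analyses.

## The allocation algorithm

Allocation runs county by county (counties are independent; patches never
cross county lines), and within a county, target class by target class.
For a target class $l$ with outstanding quota:

1. **Seed selection.** From the cells that could still convert to $l$ —
   positive generalized probability $\hat p_{il}$, current class not $l$
   and not Developed, not yet converted this step — draw $n$ cells
   without replacement with equal probability and take the one with the
   largest $\hat p_{il}$; ties are resolved by a uniform draw among the
   tied cells. The sample size $n$ is the tuning parameter: $n = 1$ is
   random allocation; $n$ at or above the number of eligible cells always
   picks the global maximum, i.e. contagious allocation.
2. **Patch size.** Note the seed's class $m'$ and draw a patch size $k$
   from the fitted patch-size model for $(m', l)$ in that county. Even
   draws are adjusted upward by one, so $k$ is odd and defines a square
   window of radius $r = (k-1)/2$.
3. **Patch window.** Collect the in-county cells within *annular*
   (Chebyshev) distance $r$ of the seed,
   $\mathrm{dist}(i', j) = \max(|x_j - x_{i'}|, |y_j - y_{i'}|)$, and
   flag as candidates those whose class is neither $l$ nor Developed
   (Water never donates) and whose $\hat p_{il} > 0$.
4. **Distance modifier.** Rank candidates by
   $p'_{ij} = p_{ij} + (1 - \mathrm{dist}_{ij}/r)(1 - \sigma)$, where
   $\sigma$ is the population standard deviation of the candidates'
   generalized probabilities. When the local surface is flat
   ($\sigma \approx 0$) the distance term dominates and patches grow
   compactly around the seed; where the surface is informative, the
   probabilities keep more influence. The scores are used only for
   ranking: they may exceed 1 and are never renormalized, so adding a
   constant to all candidate probabilities cannot change the outcome.
5. **Conversion.** Visit candidates in descending score (ties: ascending
   distance, then row-major index) and convert each one whose own donor
   quota $q_{m l}$ is still positive, stopping after $k$ conversions —
   effectively $k' = \min(k, \|\text{candidates}\|, q_{\cdot l})$.
   Converted cells take class $l$, have all their transition
   probabilities zeroed (no cell converts twice), and decrement their
   donor's quota.

The loop repeats until the class's quotas are spent, no eligible seed
remains, or `max_failed_seeds` consecutive seeds convert nothing; unmet
quota is recorded as *shortfall*, never silently dropped, and the ledger
identity `converted + shortfall = initial` holds for every (county,
donor, target) at termination.

### Choices the algorithm statement leaves open

Several details are under-determined by the procedure above; the package
fixes them as follows.

* **Seed sampling frame.** Only cells that could actually convert
  (positive probability, valid donor class, unconverted) are sampled.
  Zero-probability seeds could never yield a conversion, and including
  them would only rescale the effective $n$.
* **Mixed-donor windows.** The quota bound $q_{\cdot l}$ is ambiguous
  when a window holds candidates of several donor classes. We enforce
  quotas per donor and *skip* spent-donor candidates rather than
  truncating the whole patch: no $q_{ml}$ is ever overshot, and quota
  fulfillment is maximized.
* **Target-class order.** Developed, then Forest, Agriculture, Other
  (configurable). Developed is terminal, so it wins the competition for
  donor cells; the remaining order matters little because quotas are
  donor-specific.
* **$\sigma$** is the population (not sample) standard deviation, which
  is defined (zero) for a single-candidate window; $r = 0$ windows pass
  probabilities through unchanged.
* **Termination.** The procedure has no intrinsic guarantee of
  termination when quotas exceed the convertible supply, so a stall
  guard (`max_failed_seeds`, default 25 consecutive zero-conversion
  seeds) abandons the class and books the shortfall.

### Determinism

Every entry point that consumes randomness is seeded. `allocate_all`
derives a per-county RNG stream from `(seed, county id)`, so results are
bit-identical across reruns *and invariant to the order in which counties
are processed*; the trajectory driver likewise derives per-realization
and per-step streams from its master seed. This is what makes a
realization library reproducible from a single integer.

## Transition probabilities

Observed transitions between two reference dates are modelled per county
*grouping* (clusters of similar counties, built by k-means on
standardized county features with 10 restarts; the cluster count is the
user's choice). Within a grouping, up to 500 cells per gross transition
type (Agriculture-to-Developed is a distinct label from
Agriculture-to-Forest; persistence labels included; only Forest,
Agriculture and Other donate) are sampled without replacement, each
carrying predictor values: elevation, multi-scale slope, a wetness-index
layer, distance to water, protection status, multi-scale focal percents
of each class, and the time-1 class.

The classifier itself is *delegated* to an established random-forest
implementation behind a three-verb adapter (fit / per-label
probabilities / out-of-bag error): tree ensembles are mature commodity
code and are deliberately not reimplemented here. Any object providing a
`predict_prob` function satisfies the adapter, which the test-suite uses
to substitute analytic probability surfaces.

Predicted label probabilities become the stack $P = \{p_{il_1l_2}\}$
after donor masking ($p_{il_1l_2} = 0$ wherever the cell's class is not
$l_1$) and zeroing of disallowed pairs; the generalized surface is the
collapse $\hat p_{il} = \sum_{l_1} p_{il_1l}$, which after masking equals
the cell's own-donor probability. Masked per-cell mass is $\le 1$ and is
not renormalized. Developed and Water cells persist with probability 1:
the transition table allows every class to persist, Forest/Agriculture/
Other to convert among themselves and to Developed, and nothing else (14
allowed pairs in the 5x5 table).

## Patch sizes

Observed change patches are extracted per (county, donor, target) as
8-connected components (diagonals join — the allocator's square windows
produce diagonal adjacency; 4-connectivity is available for sensitivity
checks). Sizes are modelled with a negative binomial *shifted by one*
(fit on size − 1), so that size 1 has positive mass while the support
stays $\ge 1$. Fitting is maximum likelihood with method-of-moments
initialization; underdispersed tables fall back to a shifted Poisson,
all-equal tables to a point mass, and empty tables to the fallback model
that always returns 1 — so a county with no observed history still
allocates, one cell at a time. A single size-1 pseudo-observation is
appended to every table (configurable off): it guarantees small patches
are attainable everywhere, at the cost of a slight downward skew for
large-patch transitions — a bias worth knowing about when rare-class
areas are compared.

## Fragmentation assessment

Forest fragmentation is measured at windows of 3x3, 9x9 and 27x27 cells:
percent forest among the in-study-area cells of the centered window
(partial windows at edges use only real cells in the denominator — no
zero padding; Water counts in the denominator because it is real
landscape), classified into Rare [0,10), Patchy [10,40), Transitional
[40,60), Dominant [60,90), Interior [90,100]. The printed band labels are
integers; the half-open convention extends them to continuous percents
without gaps or overlaps. Tallies are *focal-class*: only forest cells
are classified and counted (a developed cell surrounded by forest is not
counted; a forest cell surrounded by development is), aggregated by
reporting region in cells and hectares.

An ensemble *covers* an observed class area when the observation lies
within the min-max envelope of the realizations; otherwise the minimum
absolute deviation as a percent of the observed area is reported. The
trajectory driver chains decadal steps — recomputing the
land-use-derived predictor layers from each realized grid while keeping
the fitted models and geophysical layers fixed (groupings are also held
fixed) — and summarizes per-class area change against the base year by
the median and interquartile range across realizations (type-7
linear-interpolation quantiles; a base area of zero flags the change
undefined rather than dividing by it).

## The synthetic generator

`generate_landscape()` places exact class counts by seeded region
growing: each class receives `count * (1 - clumpiness)` seeds and grows
by random frontier expansion, so `clumpiness = 0` reproduces independent
labels and values near 1 produce large contiguous patches. Counties tile
the grid in rectangles. Predictors are synthesized (smooth elevation
with derived slope, wetness stand-in, chamfer distance to Water,
rectangular protection masks) except the focal class percents, which are
*computed* from the generated grid. `generate_reference_pair()` plants
connected change patches with known sizes — kept at Chebyshev distance
$\ge 2$ within a transition so they never merge under 8-connectivity —
and returns the exact truth table, so recovery tests never re-derive
truth through the code paths under test. `generate_quotas()` derives
demand as a fraction of each county's donor supply, capped at 80% so
generated scenarios are always satisfiable.

What the generator does *not* emulate: real legends and geographies,
road-network-shaped development corridors, spatially autocorrelated
protection status, or temporally varying transition models. Passing
tests therefore certify the algorithmic contracts (quota accounting,
continuum limits, determinism, oracle equivalence, parameter recovery),
not predictive skill on real landscapes.

## Problem sizes and tolerances

The test-suite runs at desk scale, chosen to keep the full suite around
a few minutes while leaving each property statistically sharp: quota
conservation on ten 120x120, 4-county landscapes; the random-allocation
limit on 20,000 seed draws over 50 cells (chi-square, p > 0.001); the
contagious limit on 1,000 trials; oracle equivalence on one hundred
random grids up to 40x40 across all three windows; negative-binomial
recovery from 500 planted patches (mean within 10%, dispersion within
30%); classifier sanity on separable (OOB $\le$ 5%) and pure-noise
(OOB within 10 points of $1 - 1/L$) samples; and ensemble-spread and
trajectory properties on 3-step, 5-realization runs. `scripts/acceptance.R`
replays a 100x100, 4-county pipeline end to end and reports its computed
quantities.

## Known limitations

* County independence is an algorithmic guarantee, not an ecological
  one: real development clusters can straddle county lines.
* The quota ledger is integer cells; area quotas must be converted
  (`hectares_to_cells()`, round-half-up) before allocation.
* The negative binomial understates heavy-tailed patch-size
  distributions; the pseudo-observation further thins the upper tail.
* Probability surfaces are held to one fitted model per grouping;
  model-choice uncertainty is not propagated.
* Raster I/O is plain-text ASCII grid (single band, integer codes,
  explicit no-data); georeferencing beyond origin and cell size is
  passed through, not managed.
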