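# seedalloc

Stochastic seeding demand-allocation of land-use change.

`seedalloc` is for landscape ecologists and land-use modellers who have
*coarse* projections of land-use change — per-county gross transition
quotas such as "convert 1,200 cells of Forest to Developed this decade" —
and need *fine-grain* (e.g. 90 m) raster realizations of where that
change could land, in enough stochastic replicates to support
distributional analysis of landscape pattern.

## The algorithm

Land use is categorical (Developed `d`, Forest `f`, Agriculture `a`,
Water `w`, Other `o`); every class may persist, `f`/`a`/`o` may convert
among themselves and to Developed, Developed is terminal and Water
exchanges with nothing. For each county and target class *l* with
outstanding quota, the allocator repeats:

1. **Seed**: sample *n* eligible cells without replacement and pick the
   one with the highest generalized transition probability
   p̂<sub>il</sub> (ties broken uniformly). *n* tunes a continuum:
   *n* = 1 is random allocation, large *n* is contagious allocation.
2. **Patch size**: draw *k* (adjusted to odd) from a per-county,
   per-transition negative-binomial patch-size model fitted to observed
   change patches (shifted to support ≥ 1; empty tables fall back to
   single-cell patches).
3. **Window**: take the in-county cells within annular (Chebyshev)
   distance r = (k−1)/2 of the seed, dist(i′,j) = max(|x_j − x_i′|,
   |y_j − y_i′|).
4. **Rank**: score each candidate by p′ = p + (1 − dist/r)(1 − σ), σ the
   standard deviation of candidate probabilities — compact patches where
   the surface is flat, probability-driven patches where it is not.
5. **Convert** up to k′ = min(k, ‖candidates‖, remaining quota) cells in
   descending score, decrementing each donor's quota; converted cells
   are frozen for the rest of the step.

Unmet demand is booked as *shortfall* and the ledger identity
`converted + shortfall = initial` holds exactly. Everything is seeded:
per-county RNG streams make results bit-identical and independent of
county processing order.

Around the core the package provides: random-forest transition
probability surfaces (delegated classifier behind a thin adapter) with
county clustering into model groupings; patch extraction by
8-connectivity components; multi-scale focal percent-forest
fragmentation classes (Rare/Patchy/Transitional/Dominant/Interior) over
forest cells only; ensemble min–max coverage assessment; a multi-decade
trajectory driver; and a synthetic landscape generator so every piece is
testable offline.

## Worked example

```r
library(seedalloc)

# a 60x60 synthetic landscape with four counties
land <- generate_landscape(shape = c(60, 60), county_grid = c(2, 2),
                           clumpiness = 0.7, seed = 42)
land$grid
#> <lu_grid> 60 x 60 cells, 90 m resolution
#>   counts: d=288 f=1800 a=900 w=180 o=432 background=0

# demand: convert 10% of each county's Forest and 5% of its Agriculture
quotas <- generate_quotas(land$grid, land$counties,
                          c("f->d" = 0.10, "a->d" = 0.05))
head(quotas, 4)
#>   county donor target cells
#> 1    c01     f      d    43
#> 2    c01     a      d    12
#> 3    c02     f      d    42
#> 4    c02     a      d    14

# a flat probability surface and size-1 patches keep the example minimal
stack   <- probability_stack(
  list("f->d" = matrix(0.5, 60, 60), "a->d" = matrix(0.5, 60, 60)),
  land$grid)
ledgers <- build_quota_ledgers(quotas, counties = land$counties$county_ids)
res <- allocate_all(land$grid, land$counties, stack, ledgers,
                    patch_models = list(),
                    seeding_config(n = 16, seed = 1))
allocation_report_table(res$reports)
#>    county donor target initial converted shortfall
#> 1     c01     a      d      12        12         0
#> 5     c01     f      d      43        43         0
#> 10    c02     a      d      14        14         0
#> 14    c02     f      d      42        42         0
#> 19    c03     a      d      11        11         0
#> 23    c03     f      d      43        43         0
#> 28    c04     a      d       8         8         0
#> 32    c04     f      d      52        52         0
```

Every quota was met (shortfall 0): 225 cells changed class, no Developed
or Water cell moved. The fragmentation shift shows what the conversion
did to forest pattern at the 9x9 window:

```r
before <- summarize_frag_areas(land$grid, land$counties, windows = 9)
after  <- summarize_frag_areas(res$t2,   land$counties, windows = 9)
data.frame(class = before$class, cells_before = before$cells,
           cells_after = after$cells)
#>          class cells_before cells_after
#> 1         Rare            0           0
#> 2       Patchy          208         345
#> 3 Transitional         1054        1055
#> 4     Dominant          533         220
#> 5     Interior            5           0
```

Scattered development (n = 16 leans random here) eroded Dominant and
Interior forest into Patchy — exactly the kind of pattern response the
realization ensembles are built to quantify. For fitted probability
surfaces see `fit_grouping_model()` / `predict_probability_stack()`; for
multi-decade ensembles see `run_trajectory()`. A thin CLI wrapper lives
in `inst/scripts/seedalloc-cli.R`.

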