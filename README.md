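# woodmatch

Wood is a terrible control substrate. In a choice test — the standard
bioassay for food preferences of wood-eating insects such as termites — the
two offered samples must be near-identical, or differences in consumption
reflect the wood rather than the treatment under test. Yet wood varies
strongly even within one tree, and experiments often need more specimens
than a single board can supply.

`woodmatch` quantifies specimen similarity from three cheap physical
measurements per circular veneer disc — dry weight (g), moisture absorption
(% of dry weight, `(wet − dry)/dry × 100`), and the mode skewness
`(mean − mode)/sd` of the disc's photographed pixel-intensity distribution
(a proxy for the pale-earlywood/dark-latewood ratio) — and then:

1. **clusters** the specimens by fuzzy c-means, minimising
   `J = Σᵢ Σⱼ uᵢⱼᵐ ‖xᵢ − vⱼ‖²` (fuzzifier `m = 2`, 6 clusters by default),
   splitting each cluster into a *unique region* (membership ≥ 0.5) and a
   *fuzzy region*;
2. **scores sorting quality** with an ordered neighbour search: along each
   descending-membership cluster list, the cumulative probability `P(i)` of
   meeting at least one disc from the same source sheet within a
   neighbourhood of width `i = 1…10`;
3. **benchmarks** those curves against a hypergeometric (urn,
   without-replacement) null and bootstrapped uniform sheet-label nulls
   (8 repeats at matched cluster lengths, 10 repeats at identical balanced
   lengths), with a Lilliefors-screened ANOVA comparing median
   probabilities;
4. **emits matched pairs** — the closest specimen couples within each
   cluster under a distance threshold — ready for use as choice-test pairs.

A synthetic-data module generates sheet-structured specimen tables and
banded disc images, so the entire pipeline is testable without any
external data.

## Worked example

```r
library(woodmatch)
library(dplyr)

spec <- simulate_specimens(n_sheets = 10, discs_per_sheet = 50, seed = 42)
res  <- run_pipeline(spec, n_clusters = 6, seed = 42, n_init = 3)

glance(res$fit)
#>       n n_clusters     m n_iter final_cost converged
#> 1   500          6     2     34       130.      TRUE

res$curves |> filter(width == 1) |>
  group_by(kind) |> summarise(mean_pct = round(mean(probability_pct), 1))
#>   kind                    mean_pct
#> 1 balanced_bootstrap          57.3
#> 2 experimental                74.4
#> 3 hypergeometric_analytic      8.8
#> 4 uniform_bootstrap            9.4

glance(res$test)
#>   test          statistic   df1   df2  p_value
#> 1 one-way ANOVA     1105.     1    10 1.44e-11

head(res$pairs, 4)
#>   specimen_a specimen_b cluster distance both_unique_region
#> 1 S05-D029   S05-D047         1   0.0167 TRUE
#> 2 S04-D040   S05-D014         1   0.0212 TRUE
#> 3 S05-D024   S05-D030         1   0.0518 TRUE
#> 4 S03-D010   S03-D013         1   0.0537 FALSE
```

Reading the numbers: with 10 sheets, a random (uniform) labelling would
find a same-sheet direct neighbour about 10% of the time — the uniform
bootstrap reports 9.4% and the hypergeometric null 8.8%. The fitted
clustering reaches 74.4%: discs that sit next to each other in membership
order overwhelmingly come from the same sheet, so ordering by the three
physical properties recovers provenance. The ANOVA on per-cluster median
probabilities confirms the separation (p ≈ 1.4e-11). The pairs table lists
the closest specimen couples per cluster; `distance` is Euclidean in
z-scored feature space, so the top pair differs by under 2% of a population
standard deviation across all three properties.

`autoplot(res$fit)` draws the cluster scatter (fuzzy region in grey);
`plot_neighbor_curves(res$curves)` draws experimental and null curves.

A thin command-line interface wraps the same functions:

```sh
inst/cli/woodmatch simulate --out specimens.csv --n-sheets 10 --seed 42
inst/cli/woodmatch run --input specimens.csv --out results/ --seed 42
```

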