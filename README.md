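# flaps: Farm Location and Agricultural Production Simulation

Livestock in the United States can only be mapped publicly at a county
resolution or worse: the Census of Agriculture publishes aggregate farm and
population counts for counties, states and the nation, and redacts any
population figure that would reveal an individual operation. Spatial
epidemiology, emergency-response planning and biosecurity work, however, need
the locations and herd sizes of *individual* farms.

`flaps` is a spatial microsimulation tool that turns those censored
aggregates into a synthetic population of georeferenced farms. It has three
interacting parts:

1. **Missing-data model.** Census tables pair, for every unit, the number of
   farms (never redacted) and the animal population (possibly redacted) over
   seven farm-size bins (1–24, 25–49, 50–99, 100–199, 200–499, 500–999,
   ≥ 1000 head). Redacted cells are imputed with a customized iterative
   proportional fitting (IPF) scheme: with `p_ij` the population of unit *i*
   in bin *j*, rows are rescaled to the unit totals `Q_i` and columns to the
   parent-level bin subtotals `Q_j`,

       p_ij(k+1) = p_ij(k) / Σ_j p_ij(k) × Q_i
       p_ij(k+2) = p_ij(k+1) / Σ_i p_ij(k+1) × Q_j

   iterating until the largest marginal discrepancy is below 0.5 animals or
   2000 iterations elapse. Published cells are hard constraints — only
   seeded (imputed) cells, initialized at bin midpoints `n_b (lo_b+hi_b)/2`,
   absorb the discrepancies — and every imputed cell is confined to its
   known range `[n_b·lo_b, n_b·hi_b]`. The hierarchy is processed in two
   steps (national→states, then states→counties), and an exact
   integerization keeps every row, column and hierarchy sum consistent to
   the animal.

2. **Distribution model.** Farm occurrence at 100 m resolution is modelled
   by logistic regression on landscape covariates (distances to open areas,
   cropland, roads, forest, urban areas, wetlands, barren land; slope,
   temperature, precipitation). Covariates are screened for collinearity
   (|Spearman r| ≥ 0.7), each enters linearly or as a squared term
   (whichever has the lower AIC), all subsets of the global model are ranked
   by AIC, and coefficients are model-averaged with Akaike weights over the
   candidates with ΔAIC ≤ 2. The published national swine equation ships as
   `builtinSwineModel()`.

3. **Simulation model.** Each county's binned totals are downscaled to
   individual farms: per-farm populations start as U(a, b) draws over the
   bin range and are raked to the bin subtotal with a bounded
   one-dimensional IPF plus exact integerization. Farms then receive
   coordinates by sampling a target probability from the empirical
   distribution of predicted values at known presence locations and choosing
   an available pixel with a matching occurrence probability, processing the
   largest (≥ 1000 head) farms first and blocking a 5×5-pixel neighborhood
   around them (3×3 for intermediate classes) so farms are not stacked.

Synthetic-data generators (`makeCensus()`, `makeLandscape()`, `samplePA()`)
produce census hierarchies, landscapes and presence/absence samples with
known ground truth, so the whole pipeline is testable without restricted
data. Verification utilities implement the absolute-percent-difference
reaggregation and substitution analyses.

## Worked example

Disaggregate the published 2012 national hogs-and-pigs distribution
(63,246 farms, 66,026,785 head) into individual farms:

```r
library(flaps)
rec <- censusUnits(swineCensus2012())[1, ]
drafts <- disaggregateUnit(rec, seed = 1)
nrow(drafts)
#> [1] 63246
tapply(drafts$population, drafts$bin, sum)
#>        1        2        3        4        5        6        7
#>   244250   116808   146967   201460   683977  1384921 63248402
sum(drafts$population)
#> [1] 66026785
```

Every bin subtotal and the grand total match the published aggregate
exactly, for any seed; only the individual farm sizes vary.

A full synthetic run — impute a redacted census, then place farms on a
landscape:

```r
cfg  <- synthConfig(nStates = 2, countiesPerState = 3, rows = 60, cols = 60)
syn  <- makeCensus(cfg, seed = 1)
syn$observed
#> CensusTable: 1 national, 2 state, 6 county units; 24 redacted population cells
ls   <- makeLandscape(cfg, seed = 2)
pa   <- samplePA(cfg, ls, syn$observed, n = 1000, seed = 3)
pool <- presenceProbabilityPool(builtinSwineModel(), pa)
run  <- runFlaps(syn$observed, ls$surface, pool = pool,
                 scope = "national", seed = 1)
head(run$records[, 1:6], 3)
#>    fips state     lat      lon population commodity
#> 1 01001    01 35.0565 -99.9915      15189     swine
#> 2 01001    01 35.0385 -99.9815      13787     swine
#> 3 01001    01 35.0525 -99.9925       9167     swine
run$report
#> VerificationReport [farm-to-county reaggregation], 1 iteration(s)
#>   level mean se n n_undefined
#>  county    0 NA 6           0
```

The records carry county FIPS code, state, pixel-center coordinates in
decimal degrees, herd size and commodity; reaggregating them recovers the
county totals with zero absolute percent difference.

A command-line front-end over the same functions is installed at
`inst/scripts/flaps.R` (`synth`, `impute`, `run`, `verify` subcommands).

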