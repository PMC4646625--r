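---
title: "Methods: simulating individual livestock farms from censored census aggregates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating individual livestock farms from censored census aggregates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flaps)
```

# The problem

Agricultural censuses publish paired frequency distributions for every
administrative unit: the number of farms in each of seven population-size
bins (1–24, 25–49, 50–99, 100–199, 200–499, 500–999, ≥ 1000 head), which is
never confidential, and the animal population in each bin plus a grand
total, which is withheld whenever it could reveal an individual operation.
The hierarchy is functionally constrained — county figures sum to state
figures, state figures to the national figure — and those constraints,
together with the farm counts, bound every censored value: a bin holding
`n_b` farms of size class `[lo_b, hi_b]` holds between `n_b·lo_b` and
`n_b·hi_b` animals. `flaps` exploits exactly this structure to impute the
censored cells, and then disaggregates the completed county distributions
into individual, georeferenced farms.

# Missing-data model

## Pinned iterative proportional fitting

Each parent unit defines one matrix: rows are its children, columns the
seven bins, pre-defined row totals `Q_i` are child population totals and
column totals `Q_j` the parent's bin subtotals. Classical IPF alternately
rescales rows and columns to these marginals. Censored cells are seeded at
bin midpoints (`n_b (lo_b + hi_b)/2`; the unbounded bin uses the midpoint
between its lower bound and the unit's population cap) to speed
convergence.

The classical update would also alter published values, which must never
happen: published data are facts, not estimates. We therefore *pin*
published cells and apply each rescaling only to the seeded cells of a row
or column, which absorb the whole discrepancy proportionally. With every
cell seeded this reduces exactly to the classical update (the test suite
checks agreement with an independent brute-force iterator to 1e-9), and
with published cells present it is the natural constrained extension.
Iteration stops when the largest marginal discrepancy falls below
`tol = 0.5` animals — an exact zero is unattainable in floating point and
meaningless for count data — or after `mMax = 2000` iterations.

A row whose total is itself censored gets no row constraint; its cells are
driven by the column fits and its total emerges as the row sum. This
avoids fixing a possibly-infeasible total up front and guarantees that the
completed children sum exactly to the parent total.

## Bound refinement

Bin bounds alone are not the sharpest information available. Within a row
whose total is published, a censored cell can be no smaller than the total
minus the maxima of its siblings and no larger than the total minus their
minima; within a column whose subtotal is published, the same holds across
rows. Alternating these row and column interval passes to a fixpoint
propagates forced values through the block — a lone censored cell in a
published column pins its row, which can pin another column, and so on.
The same aggregation, summed over a state's counties, supplies cell bounds
for the state-level fit, so the two-step hierarchy (national→states, then
states→counties) never paints itself into a corner that the county-level
data forbid. Interval propagation is not complete for joint feasibility in
general, but across several hundred randomized synthetic tables in the test
suite it leaves no residual inconsistency.

## Exact integerization

Fitted cells are real numbers; censuses count animals. Rows with published
totals are integerized by bounded largest remainder over their seeded cells
(row sums exact by construction). Column sums are then repaired by
controlled rounding: single units move between columns along chains of
within-row transfers (found by breadth-first search), so row sums are
preserved while every column lands exactly on its subtotal; rows with
censored totals absorb any net difference. The result reaggregates exactly
at every level — at the state-to-national scale the package is within the
±1-animal rounding that motivated the 0.5-animal tolerance.

# Distribution model

Farm occurrence is modelled by logistic regression on ten landscape
covariates: distances (m) to open areas, cropland, roads, forest,
high-intensity urban areas, wetlands and barren land; slope (degrees); mean
annual temperature (°C); and annual precipitation (mm). The pipeline is:

* **Collinearity screening** (`screenCollinearity()`): pairwise Spearman
  correlations; of any pair with |r| ≥ 0.7 exactly one member is kept,
  decided by a caller-supplied preference order (e.g. roads over developed
  areas, slope over ruggedness — the covariates more widely available as
  spatial data).
* **Form choice** (`chooseForm()`): each covariate enters linearly or as a
  squared term, whichever single-covariate model has the lower AIC; ties go
  to linear. "Quadratic" means the squared term *only*, matching the
  built-in equation, which contains `x²` terms without paired linear terms.
* **All-subsets ranking** (`allSubsets()`): every subset of the global
  model (capped at 15 covariates, i.e. 2^15 fits) ranked by ΔAIC. Fits
  whose coefficients diverge to non-finite values are skipped with a
  message; fits that merely hit the iteration cap with finite coefficients
  (complete separation pushes estimates to the boundary) are kept and
  flagged, since their predictions remain usable and separable data should
  yield perfect discrimination, not an empty candidate set.
* **Model averaging** (`modelAverage()`): Akaike weights
  `w_i ∝ exp(-Δ_i/2)` over all models with ΔAIC ≤ 2. We use full
  (shrinkage) averaging — a term absent from a model contributes zero —
  because it is the conservative default when the selection itself is
  data-driven; the intercept is averaged with the same weights. With the
  window at 0 the single best model passes through unchanged.

`builtinSwineModel()` ships the published national swine equation (four
linear terms, six quadratic terms, intercept −0.0563) so a national
probability surface can be built without refitting.

Predictive performance is estimated by 5-fold cross-validation
(`kfoldAuc()`): the *entire* pipeline is refit on each 80% training split
and the 20% holdout scored with the rank-statistic AUC (Mann–Whitney, ties
averaged; cross-checked against an independent ROC implementation in the
tests). Variable importance (`variableImportance()`) is permutation-based —
the AUC drop when one covariate is shuffled in the holdout — chosen as a
standard, reproducible statistic; its absolute scale is not comparable to
other importance measures, only its ranking.

# Simulation model

## Populations

Within each bin, per-farm populations start as i.i.d. U(a, b) draws — the
null distribution given only the bin bounds — and are raked to the bin's
aggregate subtotal by one-dimensional proportional fitting. Values pushed
outside the bin are clamped to the violated bound and nudged 10% of the way
toward the *feasible mean* `subtotal/n`. The feasible mean, rather than
the bin midpoint, anchors the nudge because the unbounded bin's cap-based
midpoint sits roughly half a county total away from any realistic farm
size; nudging toward it throws clamped values orders of magnitude off and
the fit oscillates between all-clamped states. The feasible mean always
lies inside `[a, b]` for a feasible subtotal and degrades gracefully to the
bound itself in the extreme cases (subtotal = n·a or n·b). Iteration stops
within 0.5 animals of the subtotal (cap 2000 passes); bounded
largest-remainder integerization then makes each bin sum — and hence the
unit total — exact for every seed.

Each bin's subtotal is enforced separately. The aggregate data always
provide complete per-bin populations after imputation, and per-bin
enforcement guarantees both the bin sums and the grand total while also
making the published national distribution a deterministic check: 63,246
farms in, the printed bin subtotals and the printed 66,026,785 total out,
regardless of seed. For the unbounded bin the per-farm population cap is
the bin subtotal minus the minima of the other farms in the bin (no single
farm can exceed it), which degenerates to the remaining unknown population
when the bin holds one farm.

## Locations

The occurrence surface is a 100 m raster of inverse-logit predictions with
a boolean mask (urban areas, water, public lands) marking pixels where no
farm may sit. Farms do not always occupy the highest-probability pixels,
so placement targets are drawn from the empirical distribution of predicted
probabilities at *known presence locations* (`presenceProbabilityPool()`).
For each farm: draw a target, find available county pixels whose
probability lies within δ of it, choose uniformly among them. δ starts at
0.01 — fine enough to track the pool, coarse enough to find candidates on
a dense surface — and doubles until candidates exist. Placement proceeds
from the largest size class to the smallest; a placed ≥ 1000-head farm
blocks a 25-pixel (5×5) neighborhood, intermediate classes block 9 pixels
(3×3), and the smallest class blocks only its own pixel. The windows are
centered squares; a window reading of the pixel counts is the natural
one on a square grid. If a county exhausts its available pixels the
neighborhood exclusions are relaxed (masked and occupied pixels stay off
limits); if even that fails the unplaced farms are reported by error rather
than silently dropped. Farms are confined to their own county's pixels —
the aggregate data are county-level, and cross-county placement would break
reaggregation — while exclusion windows extend across county borders on
the shared raster.

Coordinates are pixel centers in decimal degrees; the synthetic landscape
uses an identity-like geotransform with 0.001° (~100 m) cells anchored at
(−100, 35). Every source of randomness streams from a single run seed via
a stable per-county hash (`deriveSeed()`), so county outputs are
independent of processing order and runs are bit-for-bit reproducible.

# Synthetic data: what it does and does not emulate

`makeCensus()` draws per-county farm counts from Poisson distributions
whose bin means follow the national 2012 shape (two-thirds of farms in the
smallest bin, most animals in the largest) scaled to ~20 farms per county,
draws within-bin farm sizes uniformly (the unbounded bin uniformly on
1000–20,000 head), and aggregates upward so the truth hierarchy is exactly
consistent. Disclosure rules then censor the observed copy: bin cells
backed by one or two farms, population totals of counties with fewer than
16 farms, and complementary-suppression partners (when a lone censored
value could be recovered from published siblings, the smallest sibling is
censored too). The 16-farm threshold was fixed analytically from the
Poisson county-size distribution so that roughly 19% of county totals are
censored — the documented share of redacted county totals in the 2012
swine census — with bin-level censoring correspondingly widespread.

`makeLandscape()` builds the ten covariates as seeded low-frequency cosine
mixtures `Σ_k a_k cos(2π(u_k r/R + v_k c/C) + φ_k)`, min–max normalized and
scaled to ranges on which the built-in swine equation produces realistic
occurrence probabilities; the mask censors the top decile of an extra
field; counties tile the grid as rectangles. `samplePA()` allocates points
to counties proportionally to farm counts (the weighted design), labels
them Bernoulli(true probability) and continues sampling until the target
prevalence (default 0.14) is hit exactly.

These generators reproduce the *structure* the pipeline depends on —
paired distributions, hierarchical sums, NASS-style suppression, smooth
covariates, presence/absence sampling — but not the texture of real data:
real landscapes have discontinuities and spatial autocorrelation patterns
cosine mixtures lack, real suppression follows richer rules, and real farm
sizes are not uniform within bins. Passing tests therefore demonstrate
algorithmic correctness under the stated study conditions, not predictive
validity on the real census, whose restricted extract the published
verification figures (county-to-state reaggregation APD near 3%,
substitution APD below 0.01%, cross-validated AUC 0.78) require.

# Numerical choices and degenerate inputs

* Marginal tolerance 0.5 animals; IPF cap 2000 iterations; both
  overridable.
* Zero-farm bins are pinned at zero whatever their redaction state.
* A one-farm bin is forced to its subtotal; an empty county yields an
  empty draft set; a fully masked county errors with the farm list.
* Ties in form choice go to linear; ties in AIC ranking keep the fitting
  order stable.
* The substitution analysis scores *re-imputed cells* against the values
  they replaced. Recovered totals are pinned exactly by the published
  hierarchy whenever they are not censored themselves, so a total-level
  statistic is structurally zero under cell redaction; the cell-level
  statistic is the informative one, and its stability across redaction
  patterns (within twice the Monte-Carlo standard error) is the property
  verified.
* Problem sizes in the test suite were chosen to exercise every code path
  at comfortable desk scale: 6×8-county synthetic censuses (≈1,000 farms
  per table), the full 63,246-farm national record, 50 replicates of
  n = 10,000 presence/absence samples for coverage, and 10,000 placements
  on a 400×400 (160,000-pixel) landscape.

# Known limitations

* The two-step hierarchy with interval-refined bounds resolves the
  cross-level feasibility cases we have generated, but interval
  consistency does not *prove* joint feasibility; a pathological table
  could still leave a flagged, non-converged block (reported in the
  convergence log, never silently absorbed).
* Only one variable (population) is imputed; cross-classified
  microsimulation over several variables (age or production-type
  structure) is out of scope.
* Placement knows nothing about parcel boundaries, zoning or roads beyond
  what the probability surface encodes.
* The importance statistic and the δ-ladder pixel-selection rule are
  reasonable, documented choices where the underlying field practice is
  unstandardized; alternatives (drop-column importance, kernel-weighted
  pixel choice) would be drop-in replacements.
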