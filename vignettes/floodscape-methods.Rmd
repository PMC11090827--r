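---
title: "Methods: turnover mapping and habitat-specialization tests"
author: "floodscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: turnover mapping and habitat-specialization tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`floodscape` analyses how strongly the tree flora of seasonally flooded
Amazonian forests (*várzea*, *igapó*) is differentiated from the
surrounding upland *terra firme*, and which individual species drive that
differentiation. This vignette is the package's own account of the
methods: the models and their assumptions, the parameters that matter,
the numerical choices, what the synthetic landscape does and does not
emulate, and the known limitations.

## From plots to compositional grids

The raw input is a georeferenced plot-inventory table: plot coordinates,
a habitat label (`TF`, `VA`, `IG`), plot area (ha) and long-format stem
counts per species. Counts are standardized to stems/ha so plots of
different area are comparable; this conserves total stems exactly
(`density × area` reproduces the counts).

Cell communities on the 1° lattice are built per habitat in two modes:

* **Interpolated** (`buildGridInterpolated`): the density of species *s*
  at a cell is the inverse-distance-weighted mean over the habitat's
  plots within a 3° search radius of the cell centroid, with weights
  `d^−2` and *zeros contributed by plots lacking the species*. Including
  the zeros matters: it is what makes a species predicted absent wherever
  it has no nearby record, and it makes every cell value a convex
  combination of observed plot densities (a tested invariant). The 3°
  radius and power 2 are the field-standard settings for basin-scale
  abundance interpolation and are configurable.
* **Pooled** (`buildGridPooled`): the unweighted mean over the plots that
  fall inside the cell. This uses far less data but removes the spatial
  dependence that interpolation builds into neighbouring cells, so it
  serves as the spatially independent cross-check.

Distances are Euclidean in degrees from plot to cell centroid (the
operative unit of the radius); a plot within 1e−9° of a centroid is
treated as at 1e−9°, which keeps the dominant-weight limit without a
division by zero. Cell membership uses half-open intervals
`[west, east) × [south, north)`, so boundary plots are assigned
deterministically.

Cells enter the turnover analysis only where both habitat grids are
covered and each exceeds **100 species** (strict inequality): in tropical
forests species accumulate fast, so failing to reach 100 signals
undersampling. Pooled grids must additionally hold at least 2 plots per
habitat in the cell; interpolated grids ignore the plot minimum because
their support is the whole search window.

## Turnover by standardized subsampling

Turnover between a floodplain cell and the analogous terra firme cell is
the mean over 1,000 paired subsamples of the Simpson dissimilarity

> β = 1 − a / (a + min(b, c)),

computed on the presence/absence species sets of two independent 500-stem
multinomial draws (selection probability ∝ cell density). Each draw is
the size of a standard ~1 ha inventory, which standardizes sampling
effort; the `min(b, c)` construction removes sensitivity to the richness
asymmetry expected between floodplain and terra firme; and using presence
sets makes the measure robust to hyperdominant species.

Two numerical notes. First, β from finite subsamples has a
*noise floor*: even identical density vectors give β > 0 because two
500-stem draws from a rich community miss different rare species. The
floor grows with pool richness and evenness (≈ 0.4 for draws from a
~1,000-species lognormal community) and is measurable by resampling a
cell against itself — the null-landscape tests compare against exactly
that self-pair oracle rather than against zero. Interpreting mapped β
therefore always means comparing cells to each other, not to an absolute
zero. Second, every cell uses an RNG substream derived from the map seed
and the cell index, so maps are bit-reproducible and independent of
evaluation order or parallel scheduling.

## The flood covariate

Flood magnitude is summarized from monthly land-water-thickness anomaly
series (cm): for each calendar year in 2002–2017 take the within-year
range (max − min of the monthly values), then average the yearly ranges.
The statistic is invariant to each cell's anomaly baseline and linear in
the seasonal amplitude (tested properties). Calendar years are used
rather than hydrological years — the simplest reading of a "yearly
range" — and a year counts only if ≥ 10 of its 12 months are present,
since gravimetric series have gaps and a sparsely sampled year biases the
range downward. Environmental rasters are brought onto the lattice by
bilinear interpolation at cell centroids (exact on planes, a tested
property); coarse fields are projected to finer maps (e.g. 0.05°) the
same way.

## Lower bounds: quantile regression

Flooding bounds turnover from below rather than predicting its mean: the
strongest floods force high turnover, while weakly flooded cells may
still be differentiated by unmeasured factors. The package therefore fits
the τ = 0.1 conditional quantile line by minimizing the check loss
Σ ρ_τ(y − a − bx), ρ_τ(u) = u(τ − 1{u<0}).

The optimizer is iteratively reweighted least squares with a decreasing
smoothing floor, followed by an exact polish: the optimum of the
check-loss linear program interpolates two data points, so the candidate
pairs among the smallest-residual points are enumerated and the best
exact line is taken. The result is verified in the tests against
exhaustive pair enumeration at small n (agreement to 1e−10) and satisfies
the textbook properties (loss ≤ the OLS line's loss; a fraction ≈ τ of
points strictly below the fit). The achieved loss is stored in the fit
object so solution equivalence is checkable. Degenerate inputs error
early: fewer than 3 points, or a constant predictor.

Slope inference uses a pairs bootstrap (B = 1,000 by default): percentile
95% CI, `t = slope / bootstrap s.e.`, and a two-sided normal p. A
bootstrap was chosen because it is assumption-light and directly testable
by simulation; rank-inversion intervals would need the full LP machinery
for little benefit at these sample sizes. Bootstrap refits use the IRLS
stage only — vertex exactness matters for the point estimate and the
optimality invariant, not for resampling noise.

Residual diagnostics: Moran's I under row-standardized k = 8
nearest-neighbour weights (kNN accommodates the irregular valid-cell
mask), with a permutation p (999 permutations, one-sided for positive
autocorrelation by default). User-supplied weight matrices are accepted,
which is also how the tests cross-check the statistic against an
independent implementation and a brute-force double loop. A rainfall
interaction is probed by a nested-model F test (`y ~ flood * rain` vs
`y ~ flood + rain`) with coefficient-wise variance inflation factors on
the full model; an aliased design errors rather than silently dropping
terms.

## Habitat association and classification

Species occurring in more than 20 plots are scored against four candidate
habitat patterns: {TF}, {VA}, {IG} and {VA ∪ IG}. Mixed terra firme
combinations are deliberately not candidates — a species spread across,
say, TF ∪ VA has no habitat *preference* in the sense sought here and
falls to the generalist class.

The statistic is a group-equalized point-biserial correlation: the
Pearson correlation between the species' abundance vector and the binary
membership vector, with each plot weighted `(N/K)/n_k` so that each
habitat contributes equally regardless of how many plots sampled it.
With equal habitat sizes the weights collapse to 1. The weighted form is
deterministic and exact, and is validated against the equivalent
construction by integer plot replication (agreement to 1e−9). Unlike
indicator-value statistics, absences outside the target habitat lower the
correlation, which is the property that lets the same statistic separate
specialists from generalists.

Because species ranges are smaller than the analysis window, permutations
are restricted to the plots lying in cells whose 3° IDW interpolation
predicts positive abundance for the species — outside that range an
absence carries no information about habitat preference. Within the
restricted subset, habitat labels are permuted (equivalently, the
abundance vector is permuted against fixed labels and weights, which is
what the implementation vectorizes); habitat frequencies, and hence the
equalizing weights, are preserved.

One inferential subtlety is resolved deliberately: the tested candidate
is itself *selected* as the maximum of four correlations. Testing that
selected candidate against permutations of its own statistic alone
inflates the false-positive rate (observed ≈ 8% at α = 0.05 in null
simulations). The permutation null therefore re-maximizes over the
candidate set in every permutation — a max-statistic test that is exactly
sized for the global null of no species–habitat linkage, as the
calibration suite verifies. p-values have floor 1/(n_perm + 1); no
multiplicity correction is applied across species — instead the summary
reports the expected number of false-positive specialists
(`round(α × significant)`) and an adjusted specialist percentage, the
field's reporting convention for this analysis.

Classification: the best candidate with p < α labels the species a
*várzea*, *igapó*, both-floodplain or terra firme specialist; otherwise
it is a generalist; species failing the occurrence filter (or whose
restricted subset spans fewer than two habitats) are `not_tested`. The
tested classes partition the tested species (a tested invariant).

## Specialist profiles

Cross-referencing a floodplain grid with the classified species gives
each cell's share of summed density (relative abundance) and of species
count (relative richness) belonging to floodplain specialists (subtypes
pooled), generalists and terra firme spillover; unclassified species are
excluded from the denominators. Shares are regressed on cell turnover by
OLS. Because the three shares sum to 1 in every cell, the three fitted
lines' predictions sum to 1 at any turnover value — a tested consistency
property.

A scale caveat found while validating: *richness* shares respond to the
habitat-affinity gradient only at the assemblage scale of pooled cells.
Interpolated cells union occurrences over every in-radius plot, which
saturates presence for all but the rarest species and flattens richness
shares; abundance shares are unaffected. The recovery tests therefore
assert abundance-share slopes on interpolated grids (the default for
profiles) and richness-share signs on pooled grids.

## The synthetic landscape

The generator emulates the statistical structure the pipeline assumes: a
1° window (default 16 × 6 cells) sampled by 2 plots per habitat per cell
(576 plots of ~550 stems, negative-binomial size 25, all 1 ha — within
the 10²–10³-plot, 500–600-stem regime of basin-scale networks, with
balanced habitat sampling for test efficiency); a unimodal flood wave
(80 cm LWT peak at the window centre, 6° e-folding decay) whose monthly
series is sinusoidal with whole-month phase lags, so the 12 monthly
samples straddle the extremes and the yearly range recovers the surface
exactly; a west–east rainfall gradient (3,200 → 1,800 mm/yr); and a
1,000-species pool with lognormal(0, 1.2) base abundances, uniform range
centres with 8° abundance decay and a 14° hard cutoff (so true absences
exist), and classes drawn at fractions 0.092/0.068/0.020/0.42/0.40 for
*várzea*/*igapó*/both/terra firme/generalist — 18% floodplain
specialists split 51/38/11, 42% terra firme, 40% generalist.

Two design choices were forced by the fixed-stem (compositional) sampling
model and deserve emphasis:

* **Symmetric affinity.** A specialist's odds are shifted √m up in its
  preferred habitat(s) and √m down elsewhere, so its preferred-habitat
  density exceeds its density elsewhere by exactly the configured
  multiplier m (default 12). With flood scaling on,
  `m_eff = 1 + (m − 1) · flood/flood_peak`, so specialist dominance — and
  hence turnover — grows toward the flood peak, producing the triangular
  turnover–flooding cloud whose τ = 0.1 floor the regression module must
  recover.
* **Class-mass balancing.** Specialist base abundances are rescaled so
  every habitat carries the same total preferred mass. Without this, the
  habitat with more specialist mass (terra firme, at 42%) depresses the
  *relative* densities of everything else there, handing true generalists
  a spurious floodplain association that no correct test could undo —
  the labels would simply not be recoverable from the data the generator
  writes. With balancing, a generalist's expected relative density is
  flat across habitats and the null calibration holds.

Each generator stage draws from its own stream derived from the master
seed by a fixed offset, so pools, plots and downstream maps are
seed-for-seed reproducible even as other configuration fields change.

What the generator does **not** emulate: river-network geometry and the
contiguity of floodplain habitat; range centres correlated with habitat
or flooding (ranges are uniform, so richness gradients are weak);
environmental noise in the flood series; plot-area variation; taxonomic
error and morphospecies; succession, soil chemistry and any
habitat-by-environment interaction beyond the flood scaling. Passing
recovery tests therefore demonstrates that the estimators recover the
constructed signal through the full pipeline — not that real inventories
satisfy the generator's assumptions.

## Problem sizes and runtime choices

The test suite and acceptance script run the study conditions at sizes
chosen to keep a full desk-scale run in minutes: the acceptance pipeline
uses the default 96-cell landscape with the full 500-stem × 1,000-rep
turnover protocol and B = 1,000 bootstrap, but 199 permutations per
species for the ~900 tested species; null-calibration suites use 199
permutations over ≥ 500 species and 150–300 Monte Carlo trials; the
lower-bound recovery uses n = 2,000 cells of the triangular cloud. The
defaults in the package (999 permutations, 1,000 reps) are the analysis
settings; the scaled-down counts appear only where a simulation loops
over many replicates.

## Limitations

Distances are Euclidean in degrees (no geodesic correction; fine at the
basin's latitudes, increasingly wrong poleward). The IDW distance is
plot-to-centroid; plot-to-nearest-cell-point would enlarge supports
slightly. The weighted-Pearson form of the group-equalized correlation is
a declared interpretation of group-based equalization, validated against
its own replication oracle rather than an external reference
implementation. Quantile-fit inference is bootstrap-based and the map's β
values are themselves Monte Carlo means, so their noise enters the
regression as measurement error on y — at 1,000 reps this is ≈ 0.005 s.d.
per cell, negligible against the cloud's spread. The turnover noise floor
means absolute β levels depend on pool richness and evenness; comparisons
should stay within a study design.
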