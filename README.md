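# floodscape

Amazonian floodplain forests (*várzea* along white-water rivers, *igapó*
along black- and clear-water rivers) hold a tree flora that partly
overlaps with, and partly replaces, the flora of the surrounding
never-flooded *terra firme*. `floodscape` implements, as a tested and
reusable pipeline, a spatially explicit analysis of that replacement: it
maps species turnover between floodplain and terra firme communities on a
1° lattice, models how the *lower bound* of turnover rises with regional
flood magnitude, and classifies individual species as floodplain
specialists, terra firme specialists or habitat generalists. It is aimed
at community ecologists and biodiversity informaticians working with
plot-inventory networks and gridded hydrological covariates.

Because basin-scale inventory data (and gravimetry-derived flood surfaces)
are typically available only on request, the package ships a
synthetic-landscape generator with known ground truth — class labels,
flood surface, expected turnover — so that every stage of the pipeline has
a recovery test at desk scale.

## The statistics at the core

* **Turnover.** For a floodplain/terra firme pair of cell assemblages,
  species turnover is Simpson dissimilarity
  `β = 1 − a / (a + min(b, c))`, with `a` shared species and `b`, `c` the
  species unique to either sample; `min(b, c)` makes β insensitive to
  richness differences, isolating true replacement. Cell assemblages are
  compared by repeatedly drawing 500 stems from each habitat with
  probability proportional to interpolated species densities and averaging
  β over 1,000 such paired subsamples.
* **Compositional grids.** Per-habitat cell communities are built either
  by inverse-distance-weighted interpolation (`w_i = d_i^−2` within a 3°
  search radius, zeros included so species are predicted absent where they
  have no nearby records) or by pooling the plots inside each cell
  (spatially independent, but data-hungry). Cells need > 100 species per
  habitat (and, for pooled grids, ≥ 2 plots per habitat) to be analysed.
* **Flood magnitude.** The mean annual range of monthly land-water
  thickness (cm), averaged over 2002–2017, summarizes the seasonal flood
  wave at each cell.
* **Lower bounds.** Quantile regression at τ = 0.1 estimates the floor of
  turnover conditional on flooding, minimizing the check loss
  `Σ ρ_τ(y − a − bx)`, with a pairs bootstrap for the slope CI and t;
  Moran's I (kNN row-standardized weights, permutation p) diagnoses
  residual spatial autocorrelation, and nested F tests probe a rainfall
  interaction.
* **Habitat association.** Each sufficiently sampled species (> 20
  occurrences) is scored by the group-equalized point-biserial correlation
  `r_g` between its abundances and membership of a candidate habitat or
  floodplain combination ({TF}, {VA}, {IG}, {VA ∪ IG}), with plots
  weighted `(N/K)/n_k` to equalize sampling effort across habitats. The
  best candidate is tested by a max-statistic permutation null restricted
  to the plots within the species' interpolated range.

## Worked example

```r
library(floodscape)

cfg  <- landscapeConfig(lonBounds = c(-68, -60), latBounds = c(-8, -4),
                        nSpecies = 500, seed = 7)
land <- simulateLandscape(cfg)
land$inventory
#> PlotInventory: 500 species x 192 plots (TF:64, VA:64, IG:64)
#>   densities standardized to stems/ha

flood <- floodMagnitude(land$floodWave$series, cfg$spec)
gVA   <- buildGridInterpolated(land$inventory, "VA", cfg$spec)
gTF   <- buildGridInterpolated(land$inventory, "TF", cfg$spec)
mask  <- applyCellFilters(gVA, gTF, minRichness = 100)
tm    <- turnoverMap(gVA, gTF, mask, nStems = 500, nReps = 1000, seed = 7)
tm
#> TurnoverMap: 32 valid cells of 32; beta in [0.423, 0.523]; 500 stems x 1000 reps

fit <- fitLowerBound(gridValues(tm), gridValues(flood), tau = 0.1,
                     nBoot = 1000, seed = 7)
fit
#> QuantileFit (tau = 0.10): slope 0.001195 [0.0002905, 0.001632], t = 3.28, n = 32

at <- classifyAll(land$inventory, cfg$spec, nPerm = 199, seed = 7)
at
#> AssociationTable: 411 species tested (alpha = 0.05, 199 perms)
#>   floodplain_specialist_VA   floodplain_specialist_IG
#>                         55                         23
#> floodplain_specialist_both     terra_firme_specialist
#>                         10                        154
#>                 generalist                 not_tested
#>                        169                          0
```

Read: turnover between *várzea* and terra firme sits around β ≈ 0.42–0.52
on this landscape; its τ = 0.1 floor rises by ≈ 0.0012 per cm of land
water thickness (bootstrap t = 3.28 over 32 cells), i.e. the most
flood-exposed cells cannot have low turnover; and of 411 testable species,
88 come out floodplain-associated, 154 terra firme-associated and 169
generalist at α = 0.05.

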