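centroidPlotFixture <- function() {
  # one TF plot exactly on the centroid of cell 1 of a 2x1 grid
  spec <- makeGridSpec(c(-62, -60), c(-5, -4))
  plots <- data.frame(plot_id = "P1", lon = -61.5, lat = -4.5,
                      habitat = "TF", area_ha = 1)
  stems <- data.frame(plot_id = "P1", species_id = c("a", "b"),
                      stems = c(30, 5))
  list(spec = spec, inv = standardizeDensities(tinyInventory(plots, stems)))
}

test_that("IDW at a coincident plot reproduces the plot vector", {
  fx <- centroidPlotFixture()
  g <- buildGridInterpolated(fx$inv, "TF", fx$spec)
  expect_equal(as.numeric(densities(g)[, 1]), c(30, 5))
  expect_true(SummarizedExperiment::colData(g)$covered[1])
})

test_that("IDW weights match the hand-computed convex combination", {
  # species at 30 stems/ha one degree away, 0 stems/ha two degrees away:
  # (1 * 30 + 0.25 * 0) / 1.25 = 24
  spec <- makeGridSpec(c(-63, -62), c(-5, -4))  # centroid (-62.5, -4.5)
  plots <- data.frame(
    plot_id = c("P1", "P2"), lon = c(-62.5, -62.5), lat = c(-3.5, -2.5),
    habitat = "VA", area_ha = 1
  )
  stems <- data.frame(plot_id = c("P1", "P2"),
                      species_id = c("x", "y"), stems = c(30, 10))
  inv <- standardizeDensities(tinyInventory(plots, stems))
  g <- buildGridInterpolated(inv, "VA", spec, radius = 3, power = 2)
  expect_equal(densities(g)["x", 1], 24)
  expect_equal(densities(g)["y", 1], (0 + 0.25 * 10) / 1.25)
})

test_that("plots beyond the search radius contribute to no cell", {
  spec <- makeGridSpec(c(-63, -62), c(-5, -4))
  plots <- data.frame(
    plot_id = c("P1", "P2"), lon = c(-62.5, -62.5), lat = c(-4.5, -1.0),
    habitat = "VA", area_ha = 1
  )  # P2 is 3.5 degrees from the only centroid
  stems <- data.frame(plot_id = c("P1", "P2"),
                      species_id = c("near", "far"), stems = c(9, 9))
  inv <- standardizeDensities(tinyInventory(plots, stems))
  g <- buildGridInterpolated(inv, "VA", spec, radius = 3)
  expect_equal(densities(g)["far", 1], 0)
  expect_equal(densities(g)["near", 1], 9)
  expect_error(buildGridInterpolated(inv, "VA", spec, radius = -1),
               "radius")
})

test_that("pooling averages plots inside a cell, half-open on boundaries", {
  spec <- makeGridSpec(c(-62, -60), c(-5, -4))
  plots <- data.frame(
    plot_id = c("P1", "P2", "P3"),
    lon = c(-61.3, -61.7, -61.0),  # P3 exactly on the shared edge
    lat = c(-4.5, -4.5, -4.5),
    habitat = "TF", area_ha = 1
  )
  stems <- data.frame(plot_id = c("P1", "P2", "P3"),
                      species_id = "s", stems = c(10, 30, 99))
  inv <- standardizeDensities(tinyInventory(plots, stems))
  g <- buildGridPooled(inv, "TF", spec)
  expect_equal(densities(g)["s", 1], 20)  # mean of 10 and 30
  # half-open rule: the boundary plot belongs to the eastern cell
  expect_equal(densities(g)["s", 2], 99)
  expect_equal(SummarizedExperiment::colData(g)$nPlots, c(2L, 1L))
})

test_that("IDW cell values are convex combinations of plot densities", {
  cfg <- landscapeConfig(lonBounds = c(-64, -61), latBounds = c(-6, -4),
                         nSpecies = 50, stemsMean = 150, seed = 21L)
  inv <- standardizeDensities(samplePlots(makeSpeciesPool(cfg)))
  g <- buildGridInterpolated(inv, "IG", cfg$spec)
  d <- densities(inv)[, plotHabitat(inv) == "IG"]
  gd <- densities(g)
  for (s in sample(rownames(inv), 10)) {
    expect_true(all(gd[s, ] >= min(d[s, ]) - 1e-9))
    expect_true(all(gd[s, ] <= max(d[s, ]) + 1e-9))
  }
})

test_that("pooled and interpolated grids agree for centroid-only plots", {
  fx <- centroidPlotFixture()
  gi <- buildGridInterpolated(fx$inv, "TF", fx$spec, radius = 0.5)
  gp <- buildGridPooled(fx$inv, "TF", fx$spec)
  expect_equal(as.matrix(densities(gi)), as.matrix(densities(gp)))
})

test_that("cell filters apply strict richness and pooled plot minimums", {
  cfg <- landscapeConfig(lonBounds = c(-64, -61), latBounds = c(-6, -4),
                         nSpecies = 400, stemsMean = 400,
                         plotsPerHabitatCell = 2, seed = 13L)
  inv <- standardizeDensities(samplePlots(makeSpeciesPool(cfg)))
  gV <- buildGridInterpolated(inv, "VA", cfg$spec)
  gT <- buildGridInterpolated(inv, "TF", cfg$spec)
  thr <- as.integer(stats::median(cellRichness(gV)))
  mask <- applyCellFilters(gV, gT, minRichness = thr)
  brute <- SummarizedExperiment::colData(gV)$covered &
    SummarizedExperiment::colData(gT)$covered &
    cellRichness(gV) > thr & cellRichness(gT) > thr
  expect_equal(mask, unname(brute))
  # a cell at exactly the threshold is excluded (strict inequality)
  at <- which(cellRichness(gV) == thr)
  if (length(at)) expect_false(any(mask[at]))

  # pooled mode additionally requires the plot minimum; interpolated not
  pV <- buildGridPooled(inv, "VA", cfg$spec)
  pT <- buildGridPooled(inv, "TF", cfg$spec)
  m2 <- applyCellFilters(pV, pT, minRichness = 0, minPlotsPerHabitat = 3)
  expect_true(all(SummarizedExperiment::colData(pV)$nPlots[m2] >= 3))
  expect_false(any(m2))  # config places only 2 plots per habitat per cell
  m3 <- applyCellFilters(gV, gT, minRichness = 0, minPlotsPerHabitat = 99)
  expect_true(any(m3))   # ignored for interpolated grids
})

test_that("bilinear resampling is exact on planes and masks outside", {
  x <- seq(-71, -55, by = 0.5); y <- seq(-10, -1, by = 0.5)
  plane <- outer(y, x, function(la, lo) 2 + 3 * lo + 5 * la)
  spec <- makeGridSpec(c(-70, -60), c(-9, -3))
  eg <- resampleEnv(list(x = x, y = y, z = plane), spec)
  cc <- cellCentroids(spec)
  expect_equal(gridValues(eg), 2 + 3 * cc$lon + 5 * cc$lat)

  const <- resampleEnv(list(x = x, y = y, z = plane * 0 + 7), spec)
  expect_true(all(gridValues(const) == 7))

  west <- makeGridSpec(c(-80, -70), c(-9, -3))
  masked <- resampleEnv(list(x = x, y = y, z = plane), west)
  expect_true(sum(is.na(gridValues(masked))) > 0)
})

test_that("fine projection hits 0.05 degrees and the centroid nodes", {
  spec <- makeGridSpec(c(-66, -60), c(-7, -4))
  set.seed(1)
  v <- runif(nCells(spec))
  fine <- projectToFine(v, fineFactor = 20, spec = spec)
  expect_equal(diff(fine$x)[1], 0.05)

  const <- projectToFine(rep(3, nCells(spec)), fineFactor = 20, spec = spec)
  expect_true(all(abs(const$z - 3) < 1e-12))

  # fineFactor 5 puts fine pixels exactly on the coarse centroids
  f5 <- projectToFine(v, fineFactor = 5, spec = spec)
  cc <- cellCentroids(spec)
  ix <- match(round(cc$lon, 10), round(f5$x, 10))
  iy <- match(round(cc$lat, 10), round(f5$y, 10))
  expect_equal(f5$z[cbind(iy, ix)], v, tolerance = 1e-10)
})
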