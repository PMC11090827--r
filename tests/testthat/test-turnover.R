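test_that("Simpson dissimilarity evaluates its defining formula", {
  expect_equal(simpsonDissimilarity(letters[1:12], letters[1:12]), 0)
  expect_equal(simpsonDissimilarity(letters[1:7], LETTERS[1:9]), 1)
  # a = 5, b = 5, c = 15 -> 1 - 5/10
  A <- c(paste0("s", 1:5), paste0("a", 1:5))
  B <- c(paste0("s", 1:5), paste0("b", 1:15))
  expect_equal(simpsonDissimilarity(A, B), 0.5)
  expect_error(simpsonDissimilarity(character(0), character(0)))
})

test_that("Simpson dissimilarity is symmetric and richness-insensitive", {
  set.seed(42)
  pool <- paste0("sp", 1:60)
  for (i in 1:200) {
    A <- sample(pool, sample(1:40, 1))
    B <- sample(pool, sample(1:40, 1))
    a <- length(intersect(A, B))
    if (a + min(length(A), length(B)) - a == 0) next
    expect_equal(simpsonDissimilarity(A, B), bruteSimpson(A, B))
    expect_equal(simpsonDissimilarity(A, B), simpsonDissimilarity(B, A))
  }
  # padding the richer side with unique species never changes beta
  A <- paste0("x", 1:10); B <- c(paste0("x", 1:4), paste0("y", 1:20))
  b0 <- simpsonDissimilarity(A, B)
  expect_equal(simpsonDissimilarity(A, c(B, paste0("z", 1:30))), b0)
})

test_that("subsampling is multinomial in the cell densities", {
  one <- c(only = 12)
  set.seed(1)
  draw <- subsampleAssembly(one, 500)
  expect_equal(unname(draw), 500L)
  expect_error(subsampleAssembly(one, 0), "nStems")
  expect_error(subsampleAssembly(c(a = 0, b = 0)), "positive")

  # two species at 90:10 -> focal count near 450 of 500
  set.seed(7)
  reps <- replicate(200, subsampleAssembly(c(a = 90, b = 10), 500)["a"])
  se <- sqrt(500 * 0.9 * 0.1)  # binomial sd of one draw
  expect_lt(abs(mean(reps) - 450), 3 * se / sqrt(200))
})

test_that("cell turnover hits the exact degenerate endpoints", {
  set.seed(1)
  expect_equal(cellTurnover(c(s = 10), c(s = 99), nReps = 50), 0)
  expect_equal(
    cellTurnover(c(a = 5, b = 5), c(x = 3, y = 7), nReps = 50), 1
  )
  expect_error(cellTurnover(c(a = 0), c(b = 1), nReps = 10), "positive")
})

test_that("cell turnover is a consistent Monte Carlo estimate", {
  # rare unique species so individual subsample pairs genuinely vary
  flood <- c(X = 95, Y = 5); tf <- c(X = 95, Z = 5)
  nStems <- 30
  set.seed(101); m1 <- cellTurnover(flood, tf, nStems, nReps = 1000)
  set.seed(202); m2 <- cellTurnover(flood, tf, nStems, nReps = 1000)
  # MC standard error estimated from a large independent run
  set.seed(303)
  big <- replicate(50, cellTurnover(flood, tf, nStems, nReps = 2000))
  seMean <- sd(big) * sqrt(2000 / 1000)
  expect_gt(seMean, 0)
  expect_lt(abs(m1 - m2), 3 * sqrt(2) * seMean)

  # s.d. of the cell mean scales as 1/sqrt(nReps)
  set.seed(404)
  s1 <- sd(replicate(40, cellTurnover(flood, tf, nStems, nReps = 100)))
  s2 <- sd(replicate(40, cellTurnover(flood, tf, nStems, nReps = 400)))
  expect_lt(s2 / s1, 0.8)  # expect about 0.5
})

test_that("turnover maps respect masks, seeds and ground truth", {
  fx <- scaledAffinityLandscape()
  inv <- fx$land$inventory
  gV <- buildGridInterpolated(inv, "VA", fx$cfg$spec)
  gT <- buildGridInterpolated(inv, "TF", fx$cfg$spec)
  mask <- applyCellFilters(gV, gT, minRichness = 80)
  tm <- turnoverMap(gV, gT, mask, nReps = 100, seed = 9L)
  expect_true(all(is.na(gridValues(tm)[!mask])))
  b <- gridValues(tm)[mask]
  expect_true(all(b >= 0 & b <= 1))

  tm2 <- turnoverMap(gV, gT, mask, nReps = 100, seed = 9L)
  expect_identical(gridValues(tm), gridValues(tm2))  # bit-identical

  # affinity scaling: turnover higher at the flood peak than the margins
  flood <- gridValues(fx$land$floodWave$magnitude)
  hi <- flood >= quantile(flood[mask], 0.8) & mask
  lo <- flood <= quantile(flood[mask], 0.2) & mask
  expect_gt(mean(gridValues(tm)[hi]), mean(gridValues(tm)[lo]))

  expect_warning(
    turnoverMap(gV, gT, rep(FALSE, nCells(fx$cfg$spec)), nReps = 10),
    "no cells"
  )
})

test_that("a null landscape yields near-zero turnover everywhere", {
  cfg <- landscapeConfig(lonBounds = c(-64, -61), latBounds = c(-6, -4),
                         nSpecies = 300, affinity = 1, stemsMean = 400,
                         plotsPerHabitatCell = 3, seed = 31L)
  inv <- standardizeDensities(samplePlots(makeSpeciesPool(cfg)))
  gV <- buildGridInterpolated(inv, "VA", cfg$spec)
  gT <- buildGridInterpolated(inv, "TF", cfg$spec)
  mask <- applyCellFilters(gV, gT, minRichness = 50)
  tm <- turnoverMap(gV, gT, mask, nReps = 100, seed = 3L)
  b <- gridValues(tm)[mask]
  expect_true(all(is.finite(b)))
  # shared pools: beta should sit near the finite-sampling noise floor,
  # measured by resampling a cell against itself; the cross-habitat value
  # also carries plot-sampling differences between the two grids, so it
  # sits slightly above the self-pair floor
  dV <- densities(gV)
  for (cell in sample(which(mask), 3)) {
    f <- setNames(dV[, cell], rownames(gV))
    set.seed(cell)
    floor <- cellTurnover(f, f, nReps = 200)
    expect_gt(gridValues(tm)[cell], floor - 0.03)
    expect_lt(gridValues(tm)[cell], floor + 0.12)
  }
  expect_lt(max(b), 0.35)
})
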