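occFixture <- function(nPlots = 60, occ = 25, seed = 1) {
  set.seed(seed)
  plots <- data.frame(
    plot_id = sprintf("P%03d", 1:nPlots),
    lon = runif(nPlots, -65.9, -60.1), lat = runif(nPlots, -5.9, -4.1),
    habitat = rep(c("TF", "VA", "IG"), length.out = nPlots),
    area_ha = 1
  )
  stems <- rbind(
    data.frame(plot_id = plots$plot_id[1:occ], species_id = "focal",
               stems = 5),
    data.frame(plot_id = plots$plot_id, species_id = "bg", stems = 3)
  )
  standardizeDensities(tinyInventory(plots, stems))
}

test_that("the occurrence filter is strict at 20 plots", {
  expect_false("focal" %in% occurrenceFilter(occFixture(occ = 20)))
  expect_true("focal" %in% occurrenceFilter(occFixture(occ = 21)))
  empty <- occFixture()[integer(0), ]
  expect_length(occurrenceFilter(empty), 0)
})

test_that("range restriction keeps in-range plots and all occurrences", {
  spec <- makeGridSpec(c(-66, -60), c(-6, -4))
  inv <- occFixture(occ = 30)
  everywhere <- rangeRestrict("bg", inv, spec)
  expect_setequal(everywhere, colnames(inv))
  sub <- rangeRestrict("focal", inv, spec)
  present <- colnames(inv)[
    SummarizedExperiment::assay(inv, "stems")["focal", ] > 0]
  expect_true(all(present %in% sub))
})

test_that("range restriction matches a brute-force IDW oracle", {
  # species confined to the west of a wide, sparse window
  spec <- makeGridSpec(c(-75, -60), c(-6, -4))
  plots <- data.frame(
    plot_id = sprintf("P%02d", 1:8),
    lon = c(-74.5, -74.2, -73.8, -68.5, -63.5, -62.5, -61.5, -60.5),
    lat = rep(c(-5.5, -4.5), 4),
    habitat = rep(c("TF", "VA"), 4), area_ha = 1
  )
  stems <- rbind(
    data.frame(plot_id = c("P01", "P02"), species_id = "west", stems = 4),
    data.frame(plot_id = plots$plot_id, species_id = "bg", stems = 2)
  )
  inv <- standardizeDensities(tinyInventory(plots, stems))
  sub <- rangeRestrict("west", inv, spec, radius = 3, power = 2)

  # oracle: full IDW interpolation of the species over all plots
  cc <- cellCentroids(spec)
  pred <- sapply(seq_len(nrow(cc)), function(ci) {
    d <- sqrt((plots$lon - cc$lon[ci])^2 + (plots$lat - cc$lat[ci])^2)
    keep <- d <= 3
    if (!any(keep)) return(0)
    x <- densities(inv)["west", keep]
    w <- pmax(d[keep], 1e-9)^-2
    sum(w * x) / sum(w)
  })
  posCells <- which(pred > 0)
  oracle <- plots$plot_id[cellIndex(spec, plots$lon, plots$lat) %in% posCells]
  expect_setequal(sub, oracle)
  expect_false("P08" %in% sub)  # far side lies outside 3 deg of any record
})

test_that("group equalization reduces to and extends point-biserial r", {
  # equal habitat sizes: plain point-biserial correlation
  hab <- rep(c("TF", "VA"), each = 10)
  m <- as.numeric(hab == "VA")
  set.seed(2)
  x <- rlnorm(20)
  expect_equal(groupEqualizedCor(x, m, hab), cor(x, m))
  expect_equal(groupEqualizedCor(5 + 2 * x, m, hab),
               groupEqualizedCor(x, m, hab))  # affine invariance
  xp <- m * 3.7  # abundance proportional to membership
  expect_equal(groupEqualizedCor(xp, m, hab), 1)
  expect_error(groupEqualizedCor(rep(1, 20), m, hab), "variance")

  # unequal sizes: weights (N/K)/n_k equal integer plot replication
  hab2 <- c(rep("TF", 12), rep("VA", 6), rep("IG", 4))
  m2 <- as.numeric(hab2 == "VA")
  set.seed(3)
  x2 <- rlnorm(22) * (1 + 2 * m2)
  rg <- groupEqualizedCor(x2, m2, hab2)
  reps <- c(TF = 1, VA = 2, IG = 3)  # lcm(12,6,4)/n_k
  idx <- rep(seq_along(x2), reps[hab2])
  expect_equal(rg, cor(x2[idx], m2[idx]), tolerance = 1e-9)
})

test_that("bestAssociation recovers a constructed varzea specialist", {
  fx <- strongAffinityLandscape()
  inv <- fx$land$inventory
  truth <- fx$land$truth$species
  tested <- occurrenceFilter(inv)
  va <- intersect(truth$species_id[truth$class == "VA"], tested)
  res <- bestAssociation(va[1], inv, fx$cfg$spec, nPerm = 199, seed = 4L)
  expect_equal(res$class, "floodplain_specialist_VA")
  expect_lt(res$p, 0.05)
  expect_gt(res$rg, 0)

  expect_error(
    bestAssociation(va[1], inv, fx$cfg$spec, nPerm = 0), "nPerm"
  )
})

test_that("classification partitions tested species and is reproducible", {
  fx <- strongAffinityLandscape()
  inv <- fx$land$inventory
  at <- classifyAll(inv, fx$cfg$spec, nPerm = 49, seed = 2L)
  res <- at@results
  expect_equal(nrow(res), length(occurrenceFilter(inv)))
  s <- at@summary
  expect_equal(
    s$nTested + as.integer(s$counts[["not_tested"]]), nrow(res)
  )
  expect_equal(
    sum(s$counts[c("floodplain_specialist_VA", "floodplain_specialist_IG",
                   "floodplain_specialist_both", "terra_firme_specialist",
                   "generalist")]),
    s$nTested
  )
  at2 <- classifyAll(inv, fx$cfg$spec, nPerm = 49, seed = 2L)
  expect_identical(at@results, at2@results)
})

test_that("summary arithmetic reproduces the headline bookkeeping", {
  # 301 significant floodplain specialists of 1,666 tested, 700 terra
  # firme specialists, 665 generalists
  res <- data.frame(class = c(
    rep("floodplain_specialist_VA", 154),
    rep("floodplain_specialist_IG", 115),
    rep("floodplain_specialist_both", 32),
    rep("terra_firme_specialist", 700),
    rep("generalist", 665)
  ))
  s <- summarizeClassification(res, alpha = 0.05)
  expect_equal(s$nTested, 1666L)
  expect_equal(s$nFloodplainSpecialists, 301L)
  expect_equal(s$pctFloodplainSpecialists, 18)
  expect_equal(s$expectedFalsePositives, 15)
  expect_equal(s$adjustedPctFloodplainSpecialists, 17)
  expect_equal(s$pctTerraFirmeSpecialists, 42)
  expect_equal(s$pctGeneralists, 40)

  none <- summarizeClassification(
    data.frame(class = rep("generalist", 50)), 0.05)
  expect_equal(none$pctFloodplainSpecialists, 0)
  expect_equal(none$expectedFalsePositives, 0)
})
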