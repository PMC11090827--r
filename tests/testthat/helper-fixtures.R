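# Fixtures are built in code; the larger synthetic landscapes are
# memoized so several test files can share one realization.

.fixtureCache <- new.env(parent = emptyenv())

memoFixture <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# Small inventory from long-format data frames.
tinyInventory <- function(plots, stems) {
  sp <- sort(unique(stems$species_id))
  m <- Matrix::sparseMatrix(
    i = match(stems$species_id, sp),
    j = match(stems$plot_id, plots$plot_id),
    x = stems$stems,
    dims = c(length(sp), nrow(plots)),
    dimnames = list(sp, plots$plot_id)
  )
  PlotInventory(m, data.frame(
    lon = plots$lon, lat = plots$lat, habitat = plots$habitat,
    areaHa = plots$area_ha, row.names = plots$plot_id
  ))
}

threePlotFixture <- function() {
  plots <- data.frame(
    plot_id = c("P1", "P2", "P3"),
    lon = c(-65.5, -64.5, -63.5), lat = c(-5.5, -5.5, -4.5),
    habitat = c("VA", "IG", "TF"), area_ha = c(1, 0.5, 2)
  )
  stems <- data.frame(
    plot_id = c("P1", "P1", "P2", "P3", "P3", "P3"),
    species_id = c("sp1", "sp2", "sp1", "sp2", "sp3", "sp4"),
    stems = c(25, 10, 25, 8, 12, 40)
  )
  list(plots = plots, stems = stems, inv = tinyInventory(plots, stems))
}

# A modest landscape with strong, spatially uniform affinity: used by the
# habitat-association and profile recovery tests.
strongAffinityLandscape <- function() {
  memoFixture("strong", {
    cfg <- landscapeConfig(
      lonBounds = c(-68, -60), latBounds = c(-8, -4), nSpecies = 500,
      affinity = 12, floodScaling = FALSE, plotsPerHabitatCell = 2,
      stemsMean = 450, seed = 11L
    )
    list(cfg = cfg, land = simulateLandscape(cfg))
  })
}

# Affinity-scaled landscape: turnover grows toward the flood peak.
scaledAffinityLandscape <- function() {
  memoFixture("scaled", {
    cfg <- landscapeConfig(
      lonBounds = c(-70, -58), latBounds = c(-8, -3), nSpecies = 600,
      affinity = 15, floodScaling = TRUE, plotsPerHabitatCell = 2,
      stemsMean = 450, seed = 23L
    )
    list(cfg = cfg, land = simulateLandscape(cfg))
  })
}

# Pooled 3-class truth/estimate labels.
pooledClass <- function(cls) {
  ifelse(cls %in% c("floodplain_specialist_VA", "floodplain_specialist_IG",
                    "floodplain_specialist_both", "VA", "IG", "both"), "FP",
  ifelse(cls %in% c("terra_firme_specialist", "TF"), "TF",
  ifelse(cls %in% c("generalist", "GEN"), "GEN", NA_character_)))
}

# Brute-force Simpson dissimilarity straight from set arithmetic.
bruteSimpson <- function(A, B) {
  A <- unique(A); B <- unique(B)
  a <- sum(A %in% B)
  1 - a / (a + min(length(A) - a, length(B) - a))
}
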