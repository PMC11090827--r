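## Synthetic landscape generator.
##
## Emulates the statistical structure of a basin-wide plot network: three
## habitats (TF, VA, IG) sampled on a 1-degree lattice, a unimodal seasonal
## flood wave, and a species pool with known floodplain / terra firme /
## generalist classes whose habitat affinity can scale with local flood
## magnitude. Every downstream stage has a recovery test against this
## known ground truth.

#' Configuration for the synthetic landscape
#'
#' Defaults describe the study conditions the generator emulates: a
#' regional 1-degree window sampled by a few hundred ~1 ha plots of
#' 500-600 stems, a flood wave peaking at 80 cm land water thickness in
#' the window centre, and a 1,000-species pool of which 18\% are
#' floodplain specialists (split 51/38/11 between varzea-only, igapo-only
#' and both), 42\% terra firme specialists and 40\% generalists.
#'
#' @param lonBounds,latBounds lattice window in degrees.
#' @param cellSize cell edge in degrees.
#' @param nSpecies species-pool size.
#' @param classFractions named fractions over \code{VA}, \code{IG},
#'   \code{both}, \code{TF}, \code{GEN}; must sum to 1.
#' @param affinity odds multiplier for a specialist's expected density in
#'   its preferred habitat(s) relative to elsewhere.
#' @param floodScaling logical; if TRUE the effective affinity grows
#'   linearly with local flood magnitude (1 at zero flooding, full
#'   \code{affinity} at the flood peak), producing the triangular
#'   turnover-flood pattern. If FALSE affinity is uniform in space.
#' @param floodPeak peak annual flood magnitude (cm land water thickness).
#' @param peakLon,peakLat flood-wave peak location; default window centre.
#' @param floodDecay spatial e-folding length of the flood wave (degrees).
#' @param plotsPerHabitatCell inventory plots per habitat per cell.
#' @param stemsMean,stemsDispersion negative-binomial mean and size for
#'   the stem total of a plot.
#' @param rangeDecay e-folding length of a species' abundance with
#'   distance from its range centre (degrees).
#' @param rangeCutoff hard range limit (degrees); expected density is zero
#'   beyond it, so species have true absences.
#' @param rainRange annual-rainfall extremes (mm/yr); rainfall declines
#'   linearly west to east, wettest at the north-west corner.
#' @param seed master seed; each generator stage derives its own stream
#'   from it by a fixed offset.
#' @return a validated list of class \code{"landscapeConfig"}.
#' @export
landscapeConfig <- function(lonBounds = c(-72, -56), latBounds = c(-9, -3),
                            cellSize = 1, nSpecies = 1000,
                            classFractions = c(VA = 0.092, IG = 0.068,
                                               both = 0.020, TF = 0.42,
                                               GEN = 0.40),
                            affinity = 12, floodScaling = TRUE,
                            floodPeak = 80, peakLon = NULL, peakLat = NULL,
                            floodDecay = 6, plotsPerHabitatCell = 2,
                            stemsMean = 550, stemsDispersion = 25,
                            rangeDecay = 8, rangeCutoff = 14,
                            rainRange = c(1800, 3200), seed = 1L) {
  if (is.null(peakLon)) peakLon <- mean(lonBounds)
  if (is.null(peakLat)) peakLat <- mean(latBounds)
  stopifnot(
    abs(sum(classFractions) - 1) < 1e-8,
    all(classFractions >= 0),
    all(c("VA", "IG", "both", "TF", "GEN") %in% names(classFractions)),
    affinity > 0, floodPeak >= 0, floodDecay > 0, rangeDecay > 0,
    rangeCutoff > 0, stemsMean > 0, stemsDispersion > 0,
    plotsPerHabitatCell >= 1
  )
  cfg <- list(
    spec = makeGridSpec(lonBounds, latBounds, cellSize),
    nSpecies = as.integer(nSpecies), classFractions = classFractions,
    affinity = affinity, floodScaling = isTRUE(floodScaling),
    floodPeak = floodPeak, peakLon = peakLon, peakLat = peakLat,
    floodDecay = floodDecay,
    plotsPerHabitatCell = as.integer(plotsPerHabitatCell),
    stemsMean = stemsMean, stemsDispersion = stemsDispersion,
    rangeDecay = rangeDecay, rangeCutoff = rangeCutoff,
    rainRange = rainRange, seed = as.integer(seed)
  )
  class(cfg) <- "landscapeConfig"
  cfg
}

## Stage streams are derived from the master seed by fixed offsets so a
## stage is reproducible even when unrelated config fields change.
stageSeed <- function(seed, stage) {
  offsets <- c(pool = 101L, plots = 202L, turnover = 303L)
  as.integer((as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max)
}

#' Generate the seasonal flood wave
#'
#' Builds the per-cell flood-magnitude surface (peak magnitude decaying
#' exponentially with distance from the peak location, hence unimodal) and
#' a monthly land-water-thickness anomaly series over 2002-2017 whose
#' yearly range equals the surface. The seasonal cycle is sinusoidal with
#' a whole-month phase lag increasing away from the headwaters, so the 12
#' monthly samples always straddle the extremes and the series is
#' deterministic.
#'
#' @param config a \code{\link{landscapeConfig}}.
#' @param years calendar years to generate.
#' @return list with \code{magnitude} (an \linkS4class{EnvGrid}, cm LWT)
#'   and \code{series} (long data.frame \code{cell, year, month, lwt_cm}).
#' @export
makeFloodWave <- function(config, years = 2002:2017) {
  spec <- config$spec
  cc <- cellCentroids(spec)
  d <- sqrt((cc$lon - config$peakLon)^2 + (cc$lat - config$peakLat)^2)
  mag <- config$floodPeak * exp(-d / config$floodDecay)
  lag <- floor((cc$lon - spec@lonMin) / 4) %% 12L  # ~1 month lag per 4 deg
  months <- 1:12
  grid <- expand.grid(month = months, year = years, cell = cc$cell)
  phase <- 2 * pi * (grid$month - 1 - lag[grid$cell]) / 12
  lwt <- (mag[grid$cell] / 2) * sin(phase)
  series <- data.frame(
    cell = grid$cell, year = grid$year, month = grid$month, lwt_cm = lwt
  )
  list(
    magnitude = EnvGrid(mag, spec, "flood magnitude, cm LWT"),
    series = series
  )
}

#' Generate the annual-rainfall surface
#'
#' Linear west-to-east decline between the configured extremes, a crude
#' stand-in for the basin's rainfall gradient; used by the rainfall
#' interaction test.
#'
#' @param config a \code{\link{landscapeConfig}}.
#' @return an \linkS4class{EnvGrid} (mm/yr).
#' @export
makeRainfall <- function(config) {
  spec <- config$spec
  cc <- cellCentroids(spec)
  f <- (cc$lon - spec@lonMin) / (spec@lonMax - spec@lonMin)
  rain <- config$rainRange[2] - f * (config$rainRange[2] - config$rainRange[1])
  EnvGrid(rain, spec, "annual rainfall, mm/yr")
}

#' Generate the species pool and its ground truth
#'
#' Each species receives a class (multinomial draw from the configured
#' fractions), a log-normal base abundance and a uniform range centre.
#'
#' @param config a \code{\link{landscapeConfig}}.
#' @param seed stream seed; defaults to the pool stage of the master seed.
#' @return list of class \code{"speciesPool"} with \code{species} (a
#'   data.frame: \code{species_id, class, base, lon, lat}) and the
#'   \code{config}.
#' @export
makeSpeciesPool <- function(config, seed = stageSeed(config$seed, "pool")) {
  set.seed(seed)
  n <- config$nSpecies
  cls <- sample(names(config$classFractions), n, replace = TRUE,
                prob = config$classFractions)
  spec <- config$spec
  base <- rlnorm(n, meanlog = 0, sdlog = 1.2)
  base <- balanceClassMasses(base, cls)
  pool <- list(
    species = data.frame(
      species_id = sprintf("S%04d", seq_len(n)),
      class = cls,
      base = base,
      lon = runif(n, spec@lonMin, spec@lonMax),
      lat = runif(n, spec@latMin, spec@latMax),
      stringsAsFactors = FALSE
    ),
    config = config
  )
  class(pool) <- "speciesPool"
  pool
}

## Rescale specialist base abundances so the total mass preferring each
## habitat is identical. Because every plot samples a fixed stem total,
## relative densities are compositional: if one habitat carried more
## boosted specialist mass than another, non-specialists would have
## systematically lower relative densities there and generalists would
## acquire a spurious habitat association. Equalizing the preferred mass
## (with the 'both' class contributing to both floodplain habitats) keeps
## the generalist share flat in expectation across habitats, so the
## configured class labels are recoverable by the association tests.
balanceClassMasses <- function(base, cls) {
  m <- function(k) sum(base[cls == k])
  mTF <- m("TF"); mVA <- m("VA"); mIG <- m("IG"); mB <- m("both")
  target <- mean(c(mTF, mVA + mB, mIG + mB))
  if (target <= 0) return(base)
  q <- if (mB > 0) mB / ((mVA + mIG) / 2 + mB) else 0
  scale <- c(
    TF = if (mTF > 0) target / mTF else 1,
    VA = if (mVA > 0) target * (1 - q) / mVA else 1,
    IG = if (mIG > 0) target * (1 - q) / mIG else 1,
    both = if (mB > 0) target * q / mB else 1,
    GEN = 1
  )
  base * scale[cls]
}

## Expected relative density of every species at one cell for one habitat.
## affinity multiplier: 1 + (affinity - 1) * flood/floodPeak when scaling
## is on, so specialist dominance grows toward the flood peak.
expectedRelDensity <- function(pool, lon, lat, habitat, floodMag) {
  cfg <- pool$config
  sp <- pool$species
  d <- sqrt((sp$lon - lon)^2 + (sp$lat - lat)^2)
  w <- sp$base * exp(-d / cfg$rangeDecay)
  w[d > cfg$rangeCutoff] <- 0
  mEff <- if (cfg$floodScaling && cfg$floodPeak > 0) {
    1 + (cfg$affinity - 1) * floodMag / cfg$floodPeak
  } else {
    cfg$affinity
  }
  preferred <- switch(habitat,
    TF = sp$class == "TF",
    VA = sp$class %in% c("VA", "both"),
    IG = sp$class %in% c("IG", "both")
  )
  specialist <- sp$class != "GEN"
  ## symmetric odds shift: sqrt(m) up in the preferred habitat(s), sqrt(m)
  ## down elsewhere, so a specialist's preferred-habitat density exceeds
  ## its density elsewhere by exactly mEff; generalists are unaffected
  w[preferred] <- w[preferred] * sqrt(mEff)
  w[specialist & !preferred] <- w[specialist & !preferred] / sqrt(mEff)
  if (sum(w) == 0) w else w / sum(w)
}

#' Sample the plot network from a species pool
#'
#' Places \code{plotsPerHabitatCell} plots of each habitat uniformly inside
#' every cell, draws each plot's stem total from a negative binomial and
#' its species counts from a multinomial over the local expected relative
#' densities of its habitat. All plots are 1 ha.
#'
#' @param pool a \code{\link{makeSpeciesPool}} result.
#' @param seed stream seed; defaults to the plots stage of the master seed.
#' @return a \linkS4class{PlotInventory}.
#' @export
samplePlots <- function(pool, seed = stageSeed(pool$config$seed, "plots")) {
  cfg <- pool$config
  set.seed(seed)
  spec <- cfg$spec
  cc <- cellCentroids(spec)
  flood <- makeFloodWave(cfg)$magnitude@values
  half <- spec@cellSize / 2
  nPerCell <- cfg$plotsPerHabitatCell
  rows <- list()
  plotMeta <- list()
  pid <- 0L
  for (cell in cc$cell) {
    for (hab in HABITATS) {
      p <- expectedRelDensity(pool, cc$lon[cell], cc$lat[cell], hab,
                              flood[cell])
      for (k in seq_len(nPerCell)) {
        pid <- pid + 1L
        stems <- max(1L, rnbinom(1, mu = cfg$stemsMean,
                                 size = cfg$stemsDispersion))
        cnt <- as.vector(rmultinom(1, stems, p))
        nz <- which(cnt > 0)
        rows[[pid]] <- data.frame(plot = pid, sp = nz, n = cnt[nz])
        plotMeta[[pid]] <- data.frame(
          plot_id = sprintf("P%05d", pid),
          lon = runif(1, cc$lon[cell] - half, cc$lon[cell] + half),
          lat = runif(1, cc$lat[cell] - half, cc$lat[cell] + half),
          habitat = hab, areaHa = 1
        )
      }
    }
  }
  long <- do.call(rbind, rows)
  meta <- do.call(rbind, plotMeta)
  mat <- Matrix::sparseMatrix(
    i = long$sp, j = long$plot, x = as.numeric(long$n),
    dims = c(cfg$nSpecies, pid),
    dimnames = list(pool$species$species_id, meta$plot_id)
  )
  PlotInventory(mat, meta)
}

#' Generate a complete synthetic landscape
#'
#' Runs the flood-wave, rainfall, species-pool and plot-sampling stages and
#' assembles the ground truth: the true class of every species, the true
#' flood magnitude of every cell, and the expected lower-bound turnover of
#' every cell (computed from presence probabilities of the expected
#' varzea/terra firme assemblages under the standard 500-stem draw).
#'
#' @param config a \code{\link{landscapeConfig}}.
#' @param nStems stem draw used for the expected-turnover calculation.
#' @return list with \code{inventory} (density-standardized
#'   \linkS4class{PlotInventory}), \code{pool}, \code{floodWave},
#'   \code{rainfall} and \code{truth} (list: \code{species}, \code{cells}).
#' @export
simulateLandscape <- function(config = landscapeConfig(), nStems = 500) {
  wave <- makeFloodWave(config)
  rain <- makeRainfall(config)
  pool <- makeSpeciesPool(config)
  inv <- standardizeDensities(samplePlots(pool))
  cc <- cellCentroids(config$spec)
  expBeta <- vapply(cc$cell, function(cell) {
    pVA <- expectedRelDensity(pool, cc$lon[cell], cc$lat[cell], "VA",
                              wave$magnitude@values[cell])
    pTF <- expectedRelDensity(pool, cc$lon[cell], cc$lat[cell], "TF",
                              wave$magnitude@values[cell])
    presVA <- 1 - (1 - pVA)^nStems
    presTF <- 1 - (1 - pTF)^nStems
    a <- sum(presVA * presTF)
    b <- sum(presVA * (1 - presTF))
    cQ <- sum((1 - presVA) * presTF)
    1 - a / (a + min(b, cQ))
  }, numeric(1))
  list(
    inventory = inv, pool = pool, floodWave = wave, rainfall = rain,
    truth = list(
      species = pool$species[c("species_id", "class")],
      cells = data.frame(
        cell = cc$cell, floodMagnitude = wave$magnitude@values,
        expectedTurnover = expBeta
      )
    )
  )
}
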