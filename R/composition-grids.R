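## Per-habitat compositional grids on the 1-degree lattice.
##
## Two constructions mirror the two analysis tracks: inverse-distance-
## weighted interpolation within a 3-degree search radius (power 2), and
## plain pooling of plots inside each cell. Distances are Euclidean in
## degrees from plot to cell centroid.

newCompositionGrid <- function(dens, spec, habitat, mode, nPlots,
                               radius = NA_real_, power = NA_real_) {
  cc <- cellCentroids(spec)
  dens <- Matrix::drop0(dens)
  richness <- Matrix::colSums(dens > 0)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(density = dens),
    colData = S4Vectors::DataFrame(
      lon = cc$lon, lat = cc$lat, nPlots = as.integer(nPlots),
      richness = as.integer(richness), covered = nPlots > 0,
      row.names = paste0("cell", cc$cell)
    )
  )
  S4Vectors::metadata(se) <- list(
    gridSpec = spec, habitat = habitat, mode = mode,
    radius = radius, power = power
  )
  methods::new("CompositionGrid", se)
}

habitatDensities <- function(inv, habitat) {
  idx <- which(plotHabitat(inv) == habitat)
  if (length(idx) == 0)
    stop("no plots of habitat ", habitat, " in the inventory")
  list(
    dens = densities(inv)[, idx, drop = FALSE],
    lon = SummarizedExperiment::colData(inv)$lon[idx],
    lat = SummarizedExperiment::colData(inv)$lat[idx]
  )
}

#' Build a composition grid by inverse-distance weighting
#'
#' For every cell and species, the interpolated density is the IDW mean
#' \eqn{\sum w_i x_i / \sum w_i} over the habitat's plots within
#' \code{radius} degrees of the cell centroid, with \eqn{w_i = d_i^{-p}}.
#' Plots without a record of the species contribute zeros, so a species is
#' predicted absent wherever it has no in-radius occurrence. Cells with no
#' plot in radius are uncovered (masked). A plot closer than 1e-9 degrees
#' to the centroid is treated as at 1e-9 degrees, preserving the
#' dominant-weight limit without dividing by zero.
#'
#' @param inv a density-standardized \linkS4class{PlotInventory}.
#' @param habitat one of \code{"TF"}, \code{"VA"}, \code{"IG"}.
#' @param spec the target \linkS4class{GridSpec}.
#' @param radius search radius in degrees (default 3).
#' @param power IDW exponent (default 2).
#' @return a \linkS4class{CompositionGrid} (mode \code{"interpolated"}).
#' @export
buildGridInterpolated <- function(inv, habitat, spec, radius = 3, power = 2) {
  if (radius <= 0 || power <= 0) stop("radius and power must be > 0")
  h <- habitatDensities(inv, habitat)
  cc <- cellCentroids(spec)
  ## weight matrix: plots x cells, zero outside the search radius
  d2 <- outer(h$lon, cc$lon, "-")^2 + outer(h$lat, cc$lat, "-")^2
  d <- sqrt(d2)
  inR <- d <= radius
  d[d < 1e-9] <- 1e-9
  w <- ifelse(inR, d^(-power), 0)
  tot <- colSums(w)
  nPlots <- colSums(inR)
  wn <- sweep(w, 2, ifelse(tot > 0, tot, 1), "/")
  grid <- h$dens %*% Matrix::Matrix(wn, sparse = TRUE)
  newCompositionGrid(grid, spec, habitat, "interpolated", nPlots,
                     radius = radius, power = power)
}

#' Build a composition grid by pooling plots within cells
#'
#' Each cell's density vector is the unweighted mean over the habitat's
#' plots whose coordinates fall inside the cell (half-open membership, see
#' \code{\link{cellIndex}}); the supporting-plot count is recorded. No
#' spatial interpolation is involved, so cells are spatially independent.
#'
#' @inheritParams buildGridInterpolated
#' @return a \linkS4class{CompositionGrid} (mode \code{"pooled"}).
#' @export
buildGridPooled <- function(inv, habitat, spec) {
  h <- habitatDensities(inv, habitat)
  cells <- cellIndex(spec, h$lon, h$lat)
  nc <- nCells(spec)
  keep <- !is.na(cells)
  nPlots <- tabulate(cells[keep], nbins = nc)
  memb <- Matrix::sparseMatrix(
    i = which(keep), j = cells[keep], x = 1,
    dims = c(length(cells), nc)
  )
  memb <- memb %*% Matrix::Diagonal(x = ifelse(nPlots > 0, 1 / nPlots, 0))
  grid <- h$dens %*% memb
  newCompositionGrid(grid, spec, habitat, "pooled", nPlots)
}

#' Validity mask for turnover cells
#'
#' A cell is analysable only where both the floodplain and the terra firme
#' grid are covered and each accumulates strictly more than
#' \code{minRichness} species; for pooled grids each habitat must in
#' addition be supported by at least \code{minPlotsPerHabitat} plots
#' inside the cell. Interpolated grids ignore the plot-count minimum.
#'
#' @param gridF,gridTF floodplain and terra firme
#'   \linkS4class{CompositionGrid}s sharing a \linkS4class{GridSpec} and
#'   mode.
#' @param minRichness strict richness threshold (default 100).
#' @param minPlotsPerHabitat pooled-mode plot minimum (default 2).
#' @return logical vector over cells.
#' @export
applyCellFilters <- function(gridF, gridTF, minRichness = 100,
                             minPlotsPerHabitat = 2) {
  if (!sameGrid(gridSpec(gridF), gridSpec(gridTF)))
    stop("grids do not share a GridSpec")
  mode <- S4Vectors::metadata(gridF)$mode
  if (!identical(mode, S4Vectors::metadata(gridTF)$mode))
    stop("grids were built in different modes")
  cdF <- SummarizedExperiment::colData(gridF)
  cdT <- SummarizedExperiment::colData(gridTF)
  mask <- cdF$covered & cdT$covered &
    cdF$richness > minRichness & cdT$richness > minRichness
  if (mode == "pooled")
    mask <- mask & cdF$nPlots >= minPlotsPerHabitat &
      cdT$nPlots >= minPlotsPerHabitat
  unname(mask)
}

#' Bilinearly sample a raster at cell centroids
#'
#' @param raster list with \code{x} (ascending longitudes), \code{y}
#'   (ascending latitudes) and \code{z}, a \code{length(y)} by
#'   \code{length(x)} value matrix.
#' @param spec the target \linkS4class{GridSpec}.
#' @return an \linkS4class{EnvGrid}; centroids outside the raster extent
#'   are masked.
#' @export
resampleEnv <- function(raster, spec) {
  cc <- cellCentroids(spec)
  inside <- cc$lon >= min(raster$x) & cc$lon <= max(raster$x) &
    cc$lat >= min(raster$y) & cc$lat <= max(raster$y)
  vals <- rep(NA_real_, nrow(cc))
  if (any(inside)) {
    vals[inside] <- pracma::interp2(
      raster$x, raster$y, raster$z,
      cc$lon[inside], cc$lat[inside], method = "linear"
    )
  }
  EnvGrid(vals, spec, "resampled")
}

#' Bilinearly project a per-cell field to a finer raster
#'
#' Upsamples a coarse scalar field (e.g. a turnover map) by interpolating
#' between coarse cell centroids; a \code{fineFactor} of 20 turns 1-degree
#' cells into 0.05-degree pixels. Fine pixels are clamped to the centroid
#' hull at the margins and restricted to \code{mask} (coarse cells where
#' \code{mask} is FALSE propagate NA).
#'
#' @param field an \linkS4class{EnvGrid} or \linkS4class{TurnoverMap}, or
#'   a numeric vector over cells (then \code{spec} is required).
#' @param fineFactor integer subdivision of each cell edge.
#' @param mask optional logical over coarse cells.
#' @param spec \linkS4class{GridSpec} when \code{field} is numeric.
#' @return list raster (\code{x}, \code{y}, \code{z}) with \code{z} a
#'   \code{length(y)} by \code{length(x)} matrix.
#' @export
projectToFine <- function(field, fineFactor = 20, mask = NULL, spec = NULL) {
  if (is(field, "EnvGrid") || is(field, "TurnoverMap")) {
    spec <- gridSpec(field)
    vals <- gridValues(field)
  } else {
    stopifnot(!is.null(spec))
    vals <- as.numeric(field)
  }
  if (!is.null(mask)) vals[!mask] <- NA_real_
  cc <- cellCentroids(spec)
  xs <- sort(unique(cc$lon))
  ys <- sort(unique(cc$lat))
  z <- matrix(vals, nrow = spec@nx, ncol = spec@ny)  # lon fastest
  Z <- t(z)[match(ys, ys), match(xs, xs), drop = FALSE]
  fine <- spec@cellSize / fineFactor
  fx <- seq(spec@lonMin + fine / 2, spec@lonMax - fine / 2, by = fine)
  fy <- seq(spec@latMin + fine / 2, spec@latMax - fine / 2, by = fine)
  cx <- pmin(pmax(fx, min(xs)), max(xs))
  cy <- pmin(pmax(fy, min(ys)), max(ys))
  pts <- expand.grid(x = cx, y = cy)
  vz <- pracma::interp2(xs, ys, Z, pts$x, pts$y, method = "linear")
  list(x = fx, y = fy, z = matrix(vz, nrow = length(fy), ncol = length(fx),
                                  byrow = TRUE))
}
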