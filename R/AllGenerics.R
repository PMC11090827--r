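#' @import methods
#' @importFrom stats cor lm pf pt quantile rbinom rlnorm rmultinom rnbinom
#'   runif sd var anova coef complete.cases resid predict
#' @importFrom utils read.csv write.csv head
NULL

#' Number of cells in a grid
#'
#' @param x a \linkS4class{GridSpec} or an object carrying one.
#' @return integer cell count.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' Cell centroid coordinates
#'
#' @param x a \linkS4class{GridSpec} or an object carrying one.
#' @return a data.frame with columns \code{cell}, \code{lon}, \code{lat}.
#' @export
setGeneric("cellCentroids", function(x) standardGeneric("cellCentroids"))

#' Extract the grid specification
#'
#' @param x an object built on a \linkS4class{GridSpec} lattice.
#' @return the \linkS4class{GridSpec}.
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' Per-plot or per-cell species densities (stems/ha)
#'
#' @param x a \linkS4class{PlotInventory} (after
#'   \code{\link{standardizeDensities}}) or a \linkS4class{CompositionGrid}.
#' @return a sparse species-by-column \code{dgCMatrix}.
#' @export
setGeneric("densities", function(x) standardGeneric("densities"))

#' Per-cell species richness of a composition grid
#'
#' Richness is the number of species with strictly positive density in the
#' cell's (interpolated or pooled) assemblage.
#'
#' @param x a \linkS4class{CompositionGrid}.
#' @return integer vector, one entry per cell.
#' @export
setGeneric("cellRichness", function(x) standardGeneric("cellRichness"))

#' Masked per-cell scalar values
#'
#' @param x an \linkS4class{EnvGrid} or \linkS4class{TurnoverMap}.
#' @return numeric vector over cells; \code{NA} where masked.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
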