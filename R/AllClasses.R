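#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom Matrix sparseMatrix colSums rowSums t Diagonal drop0
NULL

HABITATS <- c("TF", "VA", "IG")

#' Georeferenced plot inventories with species stem counts
#'
#' A \code{PlotInventory} is a \linkS4class{SummarizedExperiment} whose
#' columns are inventory plots and rows are species. The \code{"stems"}
#' assay holds raw stem counts (sparse, non-negative integers); after
#' \code{\link{standardizeDensities}} a \code{"density"} assay holds
#' stems/ha. Column data carry \code{lon}, \code{lat} (degrees),
#' \code{habitat} (factor with levels TF, VA, IG for terra firme,
#' \emph{varzea} and \emph{igapo}) and \code{areaHa} (plot area, ha).
#'
#' @aliases PlotInventory-class
#' @export
setClass("PlotInventory", contains = "SummarizedExperiment")

setValidity("PlotInventory", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  need <- c("lon", "lat", "habitat", "areaHa")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("missing plot columns:", paste(miss, collapse = ", ")))
  if (!"stems" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "a 'stems' assay is required")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "plot ids (colnames) must be unique and non-NULL")
  if (any(!is.finite(cd$lon)) || any(!is.finite(cd$lat)))
    msg <- c(msg, "plot coordinates must be finite")
  if (any(cd$areaHa <= 0)) msg <- c(msg, "areaHa must be > 0")
  if (!all(levels(cd$habitat) %in% HABITATS))
    msg <- c(msg, "habitat levels must be among TF, VA, IG")
  if ("stems" %in% SummarizedExperiment::assayNames(object)) {
    st <- SummarizedExperiment::assay(object, "stems")
    if (any(st@x < 0)) msg <- c(msg, "stem counts must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PlotInventory
#'
#' @param stems species-by-plot matrix of stem counts (coerced to sparse).
#' @param plotData data.frame or DataFrame with one row per plot and columns
#'   \code{lon}, \code{lat}, \code{habitat}, \code{areaHa}; row names (or a
#'   \code{plot_id} column) give plot ids.
#' @return a \linkS4class{PlotInventory}.
#' @export
PlotInventory <- function(stems, plotData) {
  plotData <- as.data.frame(plotData)
  if ("plot_id" %in% colnames(plotData)) {
    rownames(plotData) <- plotData$plot_id
    plotData$plot_id <- NULL
  }
  stems <- methods::as(methods::as(methods::as(
    stems, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(colnames(stems))) colnames(stems) <- rownames(plotData)
  plotData$habitat <- factor(as.character(plotData$habitat), levels = HABITATS)
  if (anyNA(plotData$habitat)) stop("unknown habitat code in plotData")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(stems = stems),
    colData = S4Vectors::DataFrame(plotData[colnames(stems), , drop = FALSE])
  )
  methods::new("PlotInventory", se)
}

#' Per-habitat composition grid
#'
#' A \code{CompositionGrid} is a \linkS4class{SummarizedExperiment} whose
#' columns are lattice cells and rows are species; the \code{"density"}
#' assay holds interpolated or pooled stems/ha. Column data carry cell
#' centroids, the supporting-plot count \code{nPlots}, \code{richness} and
#' a \code{covered} flag (FALSE where no plot informs the cell). Metadata
#' store the \linkS4class{GridSpec}, the habitat and the construction mode
#' (\code{"interpolated"} or \code{"pooled"}).
#'
#' @aliases CompositionGrid-class
#' @export
setClass("CompositionGrid", contains = "SummarizedExperiment")

setValidity("CompositionGrid", function(object) {
  md <- S4Vectors::metadata(object)
  msg <- character()
  if (!is(md$gridSpec, "GridSpec")) msg <- c(msg, "metadata$gridSpec missing")
  if (!md$mode %in% c("interpolated", "pooled"))
    msg <- c(msg, "mode must be 'interpolated' or 'pooled'")
  if (!"density" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "a 'density' assay is required")
  else if (any(SummarizedExperiment::assay(object, "density")@x < -1e-12))
    msg <- c(msg, "densities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Masked per-cell environmental scalar
#'
#' Holds one scalar per lattice cell (flood magnitude in cm land water
#' thickness, or annual rainfall in mm/yr), \code{NA} where masked.
#'
#' @slot values numeric per-cell values.
#' @slot spec the \linkS4class{GridSpec}.
#' @slot label units/short description.
#' @aliases EnvGrid
#' @export
setClass("EnvGrid",
  representation(values = "numeric", spec = "GridSpec", label = "character")
)

setValidity("EnvGrid", function(object) {
  if (length(object@values) != nCells(object@spec))
    "values length must equal the cell count" else TRUE
})

EnvGrid <- function(values, spec, label = "") {
  new("EnvGrid", values = as.numeric(values), spec = spec, label = label)
}

#' Per-cell species-turnover map
#'
#' Mean Simpson dissimilarity between a floodplain and the terra firme
#' composition grid, estimated by repeated fixed-stem subsampling; cells
#' failing the validity filters are \code{NA}.
#'
#' @slot beta numeric per-cell mean dissimilarity in [0, 1]; NA = masked.
#' @slot spec the \linkS4class{GridSpec}.
#' @slot nStems,nReps subsampling parameters.
#' @slot seed integer seed the map was generated under.
#' @aliases TurnoverMap
#' @export
setClass("TurnoverMap",
  representation(
    beta = "numeric", spec = "GridSpec",
    nStems = "integer", nReps = "integer", seed = "integer"
  )
)

setValidity("TurnoverMap", function(object) {
  msg <- character()
  if (length(object@beta) != nCells(object@spec))
    msg <- c(msg, "beta length must equal the cell count")
  b <- object@beta[!is.na(object@beta)]
  if (length(b) && (min(b) < -1e-12 || max(b) > 1 + 1e-12))
    msg <- c(msg, "beta must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Lower-bound quantile-regression fit
#'
#' Check-loss-minimizing line of turnover on flood magnitude at quantile
#' level \code{tau}, with pairs-bootstrap slope confidence interval.
#'
#' @slot tau quantile level.
#' @slot coefficients named numeric (intercept, slope).
#' @slot ciLower,ciUpper percentile-bootstrap 95\% bounds for the slope.
#' @slot se bootstrap standard error of the slope.
#' @slot tStat slope / bootstrap s.e.
#' @slot p two-sided normal-approximation p-value for the slope.
#' @slot n number of cells fitted.
#' @slot residuals,fitted per-observation vectors.
#' @slot loss achieved check loss (so solution equivalence is checkable).
#' @slot bootSlopes bootstrap replicate slopes.
#' @aliases QuantileFit
#' @export
setClass("QuantileFit",
  representation(
    tau = "numeric", coefficients = "numeric",
    ciLower = "numeric", ciUpper = "numeric", se = "numeric",
    tStat = "numeric", p = "numeric", n = "integer",
    residuals = "numeric", fitted = "numeric", loss = "numeric",
    bootSlopes = "numeric"
  )
)

#' Moran's I diagnostic
#'
#' @slot I observed Moran's I under row-standardized weights.
#' @slot expectedI null expectation -1/(n-1).
#' @slot p permutation p-value.
#' @slot k neighbours used when weights were built by kNN (NA otherwise).
#' @slot nPerm number of permutations.
#' @slot n number of locations.
#' @slot alternative "greater", "less" or "two.sided".
#' @aliases SpatialDiagnostic
#' @export
setClass("SpatialDiagnostic",
  representation(
    I = "numeric", expectedI = "numeric", p = "numeric",
    k = "integer", nPerm = "integer", n = "integer",
    alternative = "character"
  )
)

#' Species habitat-association results
#'
#' @slot results data.frame with one row per species: occurrences, the
#'   best candidate habitat/combination, the group-equalized correlation
#'   \code{rg}, permutation \code{p} and the class label.
#' @slot summary list with class counts, percentages, expected false
#'   positives at \code{alpha} and the adjusted specialist percentage.
#' @slot alpha significance threshold used.
#' @slot nPerm permutations per species.
#' @slot seed master seed.
#' @aliases AssociationTable
#' @export
setClass("AssociationTable",
  representation(
    results = "data.frame", summary = "list",
    alpha = "numeric", nPerm = "integer", seed = "integer"
  )
)

## ---- accessors / show ----

#' @rdname gridSpec
#' @export
setMethod("gridSpec", "CompositionGrid",
  function(x) S4Vectors::metadata(x)$gridSpec)
#' @rdname gridSpec
#' @export
setMethod("gridSpec", "EnvGrid", function(x) x@spec)
#' @rdname gridSpec
#' @export
setMethod("gridSpec", "TurnoverMap", function(x) x@spec)

#' @rdname densities
#' @export
setMethod("densities", "PlotInventory", function(x) {
  if (!"density" %in% SummarizedExperiment::assayNames(x))
    stop("no 'density' assay; run standardizeDensities() first")
  SummarizedExperiment::assay(x, "density")
})
#' @rdname densities
#' @export
setMethod("densities", "CompositionGrid",
  function(x) SummarizedExperiment::assay(x, "density"))

#' @rdname cellRichness
#' @export
setMethod("cellRichness", "CompositionGrid",
  function(x) SummarizedExperiment::colData(x)$richness)

#' @rdname gridValues
#' @export
setMethod("gridValues", "EnvGrid", function(x) x@values)
#' @rdname gridValues
#' @export
setMethod("gridValues", "TurnoverMap", function(x) x@beta)

#' Habitat of each plot
#' @param x a \linkS4class{PlotInventory}.
#' @return factor with levels TF, VA, IG.
#' @export
plotHabitat <- function(x) SummarizedExperiment::colData(x)$habitat

#' Plot counts per habitat
#' @param x a \linkS4class{PlotInventory}.
#' @return named integer vector over TF, VA, IG.
#' @export
habitatCounts <- function(x) table(plotHabitat(x))

setMethod("show", "PlotInventory", function(object) {
  cnt <- habitatCounts(object)
  cat(sprintf(
    "PlotInventory: %d species x %d plots (%s)\n",
    nrow(object), ncol(object),
    paste(names(cnt), as.integer(cnt), sep = ":", collapse = ", ")
  ))
  if ("density" %in% SummarizedExperiment::assayNames(object))
    cat("  densities standardized to stems/ha\n")
})

setMethod("show", "CompositionGrid", function(object) {
  md <- S4Vectors::metadata(object)
  cov <- sum(SummarizedExperiment::colData(object)$covered)
  cat(sprintf(
    "CompositionGrid (%s, %s): %d species, %d/%d covered cells\n",
    md$habitat, md$mode, nrow(object), cov, ncol(object)
  ))
})

setMethod("show", "EnvGrid", function(object) {
  v <- object@values
  cat(sprintf(
    "EnvGrid [%s]: %d cells (%d masked), range [%.3g, %.3g]\n",
    object@label, length(v), sum(is.na(v)),
    suppressWarnings(min(v, na.rm = TRUE)),
    suppressWarnings(max(v, na.rm = TRUE))
  ))
})

setMethod("show", "TurnoverMap", function(object) {
  v <- object@beta
  cat(sprintf(
    "TurnoverMap: %d valid cells of %d; beta in [%.3f, %.3f]; %d stems x %d reps\n",
    sum(!is.na(v)), length(v),
    suppressWarnings(min(v, na.rm = TRUE)),
    suppressWarnings(max(v, na.rm = TRUE)),
    object@nStems, object@nReps
  ))
})

setMethod("show", "QuantileFit", function(object) {
  co <- object@coefficients
  cat(sprintf(
    "QuantileFit (tau = %.2f): slope %.4g [%.4g, %.4g], t = %.2f, n = %d\n",
    object@tau, co["slope"], object@ciLower, object@ciUpper,
    object@tStat, object@n
  ))
})

setMethod("show", "SpatialDiagnostic", function(object) {
  cat(sprintf(
    "Moran's I = %.4f (E[I] = %.4f), p = %.4g (%s, %d perms, n = %d)\n",
    object@I, object@expectedI, object@p, object@alternative,
    object@nPerm, object@n
  ))
})

setMethod("show", "AssociationTable", function(object) {
  s <- object@summary
  cat(sprintf(
    "AssociationTable: %d species tested (alpha = %g, %d perms)\n",
    s$nTested, object@alpha, object@nPerm
  ))
  print(s$counts)
})
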