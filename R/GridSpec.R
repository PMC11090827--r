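#' Regular longitude/latitude lattice
#'
#' A \code{GridSpec} describes the analysis lattice: an axis-aligned
#' longitude/latitude window tiled by square cells (1 degree by default).
#' Cells are indexed column-major from the south-west corner, longitude
#' varying fastest; the centroid of cell \code{(i, j)} sits at
#' \code{bounds + (i + 0.5, j + 0.5) * cellSize}. Cell membership uses
#' half-open intervals \code{[west, east) x [south, north)} so boundary
#' plots are assigned deterministically.
#'
#' @slot lonMin,lonMax,latMin,latMax numeric window bounds in degrees.
#' @slot cellSize numeric cell edge in degrees.
#' @slot nx,ny integer cell counts along longitude and latitude.
#'
#' @aliases GridSpec
#' @export
setClass("GridSpec",
  representation(
    lonMin = "numeric", lonMax = "numeric",
    latMin = "numeric", latMax = "numeric",
    cellSize = "numeric", nx = "integer", ny = "integer"
  )
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (object@cellSize <= 0) msg <- c(msg, "cellSize must be > 0")
  if (object@lonMax <= object@lonMin) msg <- c(msg, "lonMax must exceed lonMin")
  if (object@latMax <= object@latMin) msg <- c(msg, "latMax must exceed latMin")
  if (length(msg) == 0) {
    if (abs(object@lonMin + object@nx * object@cellSize - object@lonMax) > 1e-8 ||
        abs(object@latMin + object@ny * object@cellSize - object@latMax) > 1e-8)
      msg <- c(msg, "bounds are not an integer number of cells")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a grid specification
#'
#' @param lonBounds,latBounds length-2 numeric windows in degrees; each span
#'   must be an integer multiple of \code{cellSize}.
#' @param cellSize cell edge in degrees (default 1).
#' @return a \linkS4class{GridSpec}.
#' @examples
#' spec <- makeGridSpec(c(-70, -60), c(-8, -2))
#' nCells(spec)
#' @export
makeGridSpec <- function(lonBounds, latBounds, cellSize = 1) {
  stopifnot(length(lonBounds) == 2, length(latBounds) == 2)
  nx <- round((lonBounds[2] - lonBounds[1]) / cellSize)
  ny <- round((latBounds[2] - latBounds[1]) / cellSize)
  new("GridSpec",
    lonMin = lonBounds[1], lonMax = lonBounds[2],
    latMin = latBounds[1], latMax = latBounds[2],
    cellSize = cellSize, nx = as.integer(nx), ny = as.integer(ny)
  )
}

#' @rdname nCells
#' @export
setMethod("nCells", "GridSpec", function(x) x@nx * x@ny)

#' @rdname cellCentroids
#' @export
setMethod("cellCentroids", "GridSpec", function(x) {
  ix <- rep(seq_len(x@nx) - 1L, times = x@ny)
  iy <- rep(seq_len(x@ny) - 1L, each = x@nx)
  data.frame(
    cell = seq_len(x@nx * x@ny),
    lon = x@lonMin + (ix + 0.5) * x@cellSize,
    lat = x@latMin + (iy + 0.5) * x@cellSize
  )
})

#' Map coordinates to cell indices
#'
#' Uses the half-open membership rule \code{[west, east) x [south, north)}.
#' Points outside the window map to \code{NA}.
#'
#' @param spec a \linkS4class{GridSpec}.
#' @param lon,lat numeric coordinate vectors (degrees).
#' @return integer cell indices (1-based, column-major), \code{NA} outside.
#' @export
cellIndex <- function(spec, lon, lat) {
  ix <- floor((lon - spec@lonMin) / spec@cellSize)
  iy <- floor((lat - spec@latMin) / spec@cellSize)
  out <- as.integer(iy * spec@nx + ix + 1)
  bad <- ix < 0 | ix >= spec@nx | iy < 0 | iy >= spec@ny |
    !is.finite(lon) | !is.finite(lat)
  out[bad] <- NA_integer_
  out
}

setMethod("show", "GridSpec", function(object) {
  cat(sprintf(
    "GridSpec: %d x %d cells of %g deg, lon [%g, %g], lat [%g, %g]\n",
    object@nx, object@ny, object@cellSize,
    object@lonMin, object@lonMax, object@latMin, object@latMax
  ))
})

sameGrid <- function(a, b) {
  isTRUE(all.equal(
    c(a@lonMin, a@lonMax, a@latMin, a@latMax, a@cellSize),
    c(b@lonMin, b@lonMax, b@latMin, b@latMax, b@cellSize)
  ))
}
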