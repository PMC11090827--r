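## Species turnover between floodplain and terra firme grids:
## Simpson dissimilarity of repeated fixed-stem subsamples.

#' Simpson dissimilarity of two species sets
#'
#' \eqn{\beta = 1 - a / (a + \min(b, c))} where \eqn{a} is the number of
#' shared species and \eqn{b}, \eqn{c} the numbers unique to each set.
#' Taking the smaller unique count makes the index insensitive to richness
#' differences between the samples, isolating species replacement.
#'
#' @param setA,setB character vectors of species (duplicates ignored).
#' @return dissimilarity in [0, 1].
#' @examples
#' simpsonDissimilarity(c("x", "y"), c("x", "z"))  # a=1, b=1, c=1 -> 0.5
#' @export
simpsonDissimilarity <- function(setA, setB) {
  setA <- unique(setA)
  setB <- unique(setB)
  a <- length(intersect(setA, setB))
  b <- length(setA) - a
  cc <- length(setB) - a
  if (a + min(b, cc) == 0)
    stop("undefined dissimilarity: no shared or unique species on the ",
         "smaller side (are both sets empty?)")
  1 - a / (a + min(b, cc))
}

#' Draw a standardized assembly from a cell's composition
#'
#' Multinomial draw of \code{nStems} stems with replacement, selection
#' probability proportional to each species' cell density; the sampled
#' assembly is comparable to a standard ~1 ha inventory plot.
#'
#' @param cellDensities named non-negative numeric vector (stems/ha).
#' @param nStems stems to draw (default 500).
#' @return named integer vector of drawn stem counts (all species).
#' @export
subsampleAssembly <- function(cellDensities, nStems = 500) {
  if (nStems < 1) stop("nStems must be >= 1")
  tot <- sum(cellDensities)
  if (!(tot > 0)) stop("cell has no positive densities to sample from")
  cnt <- as.vector(rmultinom(1, nStems, cellDensities / tot))
  names(cnt) <- names(cellDensities)
  cnt
}

#' Mean Simpson dissimilarity of paired subsamples for one cell
#'
#' Draws \code{nReps} independent pairs of \code{nStems}-stem assemblies
#' from the floodplain and terra firme cell compositions and averages the
#' Simpson dissimilarity of the pairs' presence/absence species sets. The
#' two draws of a pair are independent.
#'
#' @param floodCell,tfCell named non-negative density vectors over a
#'   common species universe (names are matched by position if identical,
#'   else by union of names).
#' @param nStems stems per draw (default 500).
#' @param nReps subsample pairs (default 1000).
#' @return mean dissimilarity in [0, 1].
#' @export
cellTurnover <- function(floodCell, tfCell, nStems = 500, nReps = 1000) {
  if (!identical(names(floodCell), names(tfCell))) {
    sp <- union(names(floodCell), names(tfCell))
    fc <- tc <- setNames(numeric(length(sp)), sp)
    fc[names(floodCell)] <- floodCell
    tc[names(tfCell)] <- tfCell
    floodCell <- fc
    tfCell <- tc
  }
  if (!(sum(floodCell) > 0 && sum(tfCell) > 0))
    stop("both cells must have positive total density")
  ## restrict to the joint support; species absent from both never enter
  keep <- floodCell > 0 | tfCell > 0
  pF <- floodCell[keep] / sum(floodCell[keep])
  pT <- tfCell[keep] / sum(tfCell[keep])
  drawF <- rmultinom(nReps, nStems, pF) > 0
  drawT <- rmultinom(nReps, nStems, pT) > 0
  a <- colSums(drawF & drawT)
  b <- colSums(drawF & !drawT)
  cQ <- colSums(!drawF & drawT)
  mean(1 - a / (a + pmin(b, cQ)))
}

#' Map species turnover over all valid cells
#'
#' Applies \code{\link{cellTurnover}} at every cell passing the validity
#' mask (see \code{\link{applyCellFilters}}). Each cell draws from its own
#' RNG substream derived from \code{seed} and the cell index, so the map
#' is reproducible and independent of evaluation order.
#'
#' @param gridF,gridTF floodplain and terra firme
#'   \linkS4class{CompositionGrid}s on a shared lattice.
#' @param mask logical validity mask over cells; defaults to
#'   \code{applyCellFilters(gridF, gridTF)}.
#' @param nStems,nReps subsampling parameters (defaults 500 and 1000).
#' @param seed integer map seed.
#' @return a \linkS4class{TurnoverMap}.
#' @export
turnoverMap <- function(gridF, gridTF, mask = NULL, nStems = 500,
                        nReps = 1000, seed = 1L) {
  if (!sameGrid(gridSpec(gridF), gridSpec(gridTF)))
    stop("grids do not share a GridSpec")
  if (is.null(mask)) mask <- applyCellFilters(gridF, gridTF)
  spec <- gridSpec(gridF)
  beta <- rep(NA_real_, nCells(spec))
  valid <- which(mask)
  if (length(valid) == 0) {
    warning("no cells pass the validity filters; returning an empty map")
  }
  dF <- densities(gridF)
  dT <- densities(gridTF)
  for (cell in valid) {
    ## per-cell substream: value depends only on (seed, cell)
    set.seed(as.integer((as.double(seed) * 7919 + cell) %%
                          .Machine$integer.max))
    f <- dF[, cell]
    t_ <- dT[, cell]
    names(f) <- names(t_) <- rownames(gridF)
    beta[cell] <- cellTurnover(f, t_, nStems = nStems, nReps = nReps)
  }
  new("TurnoverMap",
    beta = beta, spec = spec, nStems = as.integer(nStems),
    nReps = as.integer(nReps), seed = as.integer(seed)
  )
}
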