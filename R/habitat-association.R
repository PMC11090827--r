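## Habitat-association tests: group-equalized point-biserial correlation
## with range-restricted permutations, and the specialist classification.

FP_CLASSES <- c("floodplain_specialist_VA", "floodplain_specialist_IG",
                "floodplain_specialist_both")
ALL_CLASSES <- c(FP_CLASSES, "terra_firme_specialist", "generalist",
                 "not_tested")

candidateSets <- function() {
  list(TF = "TF", VA = "VA", IG = "IG", `VA+IG` = c("VA", "IG"))
}

classOfCandidate <- function(candidate) {
  switch(candidate,
    TF = "terra_firme_specialist",
    VA = "floodplain_specialist_VA",
    IG = "floodplain_specialist_IG",
    `VA+IG` = "floodplain_specialist_both"
  )
}

#' Species tested for habitat association
#'
#' Only species occurring (stems > 0) in strictly more than \code{minOcc}
#' plots are assessed, ensuring sufficient sampling.
#'
#' @param inv a \linkS4class{PlotInventory}.
#' @param minOcc strict occurrence threshold (default 20, i.e. at least
#'   21 plots).
#' @return character vector of species ids.
#' @export
occurrenceFilter <- function(inv, minOcc = 20) {
  st <- SummarizedExperiment::assay(inv, "stems")
  occ <- Matrix::rowSums(st > 0)
  rownames(inv)[occ > minOcc]
}

## In-radius indicator between cells and plots (cells x plots, logical).
inRadiusMatrix <- function(inv, spec, radius) {
  cd <- SummarizedExperiment::colData(inv)
  cc <- cellCentroids(spec)
  d2 <- outer(cc$lon, cd$lon, "-")^2 + outer(cc$lat, cd$lat, "-")^2
  d2 <= radius^2
}

#' Restrict a species' test to plots within its interpolated range
#'
#' Most species' ranges are smaller than the study window, so habitat
#' labels are permuted only over plots lying in grid cells whose
#' inverse-distance-weighted interpolation predicts a positive abundance
#' for the species. Because the IDW search radius bounds the weights'
#' support, a cell predicts > 0 exactly when at least one in-radius plot
#' (of any habitat) contains the species.
#'
#' @param speciesId one species id.
#' @param inv a \linkS4class{PlotInventory}.
#' @param spec the \linkS4class{GridSpec} defining the cells.
#' @param radius,power IDW parameters (defaults 3 and 2; \code{power}
#'   does not change the support).
#' @return character vector of plot ids (always contains every plot where
#'   the species is present, provided the plot lies on the grid).
#' @export
rangeRestrict <- function(speciesId, inv, spec, radius = 3, power = 2) {
  st <- SummarizedExperiment::assay(inv, "stems")
  present <- st[speciesId, ] > 0
  if (!any(present)) stop("species has no occurrences")
  inR <- inRadiusMatrix(inv, spec, radius)
  posCells <- which(inR[, present, drop = FALSE] %*%
                      rep(1, sum(present)) > 0)
  cd <- SummarizedExperiment::colData(inv)
  plotCell <- cellIndex(spec, cd$lon, cd$lat)
  colnames(inv)[!is.na(plotCell) & plotCell %in% posCells]
}

#' Group-equalized point-biserial correlation
#'
#' Pearson correlation between a species' abundance vector and the binary
#' habitat-membership vector, with each plot weighted \eqn{(N/K)/n_k}
#' (\eqn{n_k} its habitat's plot count, \eqn{K} the number of habitats,
#' \eqn{N} the total plots) so unequal sampling effort among habitats is
#' equalized. With equal habitat sizes the weights collapse to 1 and the
#' statistic is the ordinary point-biserial correlation. Absences outside
#' the target habitat enter the correlation, unlike indicator-value
#' statistics.
#'
#' @param abund per-plot abundance (stems/ha).
#' @param membership per-plot logical/0-1 indicator of the candidate
#'   habitat or combination.
#' @param habitat per-plot habitat factor (defines the groups equalized).
#' @return correlation in [-1, 1].
#' @export
groupEqualizedCor <- function(abund, membership, habitat) {
  membership <- as.numeric(membership)
  if (sum(membership >= 1) < 2 || sum(membership < 1) < 2)
    stop("need at least 2 plots inside and outside the candidate group")
  habitat <- droplevels(factor(habitat))
  nk <- table(habitat)
  K <- length(nk)
  N <- length(abund)
  w <- (N / K) / as.numeric(nk[habitat])
  wCor(abund, membership, w)
}

wCor <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0)
    stop("zero variance in abundance or membership vector")
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

## Correlations of permuted abundance against several fixed membership
## columns. Permuting habitat labels (carrying membership and the
## equalizing weights together) is equivalent to permuting the abundance
## vector, which vectorizes; returns an nPerm x ncol(M) matrix.
permCors <- function(x, M, w, nPerm) {
  n <- length(x)
  P <- vapply(seq_len(nPerm), function(b) sample.int(n), integer(n))
  X <- matrix(x[P], nrow = n)
  sw <- sum(w)
  my <- colSums(w * M) / sw
  vy <- colSums(w * M^2) - sw * my^2
  mx <- colSums(w * X) / sw
  vx <- colSums(w * X^2) - sw * mx^2
  cov <- crossprod(w * M, X) - outer(sw * my, mx)  # C x nPerm
  out <- t(cov / sqrt(vy)) / outer(sqrt(vx), rep(1, ncol(M)))
  out[vx <= 0, ] <- NA_real_
  out
}

#' Best habitat association of one species
#'
#' Computes the group-equalized correlation for each candidate habitat or
#' floodplain combination (\code{TF}, \code{VA}, \code{IG},
#' \code{VA+IG}) on the species' range-restricted plot subset and tests
#' the highest-correlation candidate by permuting habitat labels across
#' the restricted plots (one-sided; habitat frequencies and hence the
#' equalizing weights are preserved). Because the candidate is itself
#' selected as the maximum, the permutation null re-maximizes over the
#' candidates in every permutation; this max-statistic construction keeps
#' the test exactly sized for the global null of no habitat linkage.
#' Mixed terra firme combinations are not candidates; such patterns fall
#' to the generalist class.
#'
#' @param speciesId species to test (should have passed
#'   \code{\link{occurrenceFilter}}).
#' @param inv a density-standardized \linkS4class{PlotInventory}.
#' @param spec \linkS4class{GridSpec} for range restriction.
#' @param nPerm permutations (default 999); p has floor 1/(nPerm + 1).
#' @param seed RNG seed for the permutations.
#' @param alpha significance level for the class label (default 0.05).
#' @param radius IDW search radius for range restriction.
#' @return one-row data.frame: \code{species_id, n_occurrences, n_plots,
#'   candidate, rg, p, class}.
#' @export
bestAssociation <- function(speciesId, inv, spec, nPerm = 999, seed = 1L,
                            alpha = 0.05, radius = 3) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  row <- function(candidate, rg, p, cls, nPlots, nOcc) data.frame(
    species_id = speciesId, n_occurrences = nOcc, n_plots = nPlots,
    candidate = candidate, rg = rg, p = p, class = cls,
    stringsAsFactors = FALSE
  )
  st <- SummarizedExperiment::assay(inv, "stems")
  nOcc <- sum(st[speciesId, ] > 0)
  plots <- rangeRestrict(speciesId, inv, spec, radius = radius)
  x <- densities(inv)[speciesId, plots]
  hab <- droplevels(factor(plotHabitat(inv)[match(plots, colnames(inv))]))
  if (length(levels(hab)) < 2)
    return(row(NA_character_, NA_real_, NA_real_, "not_tested",
               length(plots), nOcc))
  nk <- table(hab)
  K <- length(nk)
  N <- length(x)
  w <- (N / K) / as.numeric(nk[hab])
  cands <- candidateSets()
  M <- vapply(cands, function(cs) as.numeric(hab %in% cs),
              numeric(length(hab)))
  usable <- colSums(M) >= 2 & colSums(1 - M) >= 2
  rgs <- rep(NA_real_, length(cands))
  names(rgs) <- names(cands)
  for (ci in which(usable))
    rgs[ci] <- tryCatch(wCor(x, M[, ci], w), error = function(e) NA_real_)
  if (all(is.na(rgs)))
    return(row(NA_character_, NA_real_, NA_real_, "not_tested",
               length(plots), nOcc))
  bestIdx <- which.max(rgs)
  candidate <- names(rgs)[bestIdx]
  set.seed(as.integer(seed))
  pc <- permCors(x, M[, !is.na(rgs), drop = FALSE], w, nPerm)
  permMax <- apply(pc, 1, max, na.rm = TRUE)
  p <- (1 + sum(permMax >= rgs[bestIdx])) / (1 + nPerm)
  cls <- if (p < alpha) classOfCandidate(candidate) else "generalist"
  row(candidate, unname(rgs[bestIdx]), p, cls, length(x), nOcc)
}

#' Classify every sufficiently sampled species
#'
#' Runs \code{\link{bestAssociation}} for each species passing the
#' occurrence filter. Each species draws from its own RNG substream
#' derived from \code{seed}, so results do not depend on evaluation
#' order. The summary reports class counts, nearest-integer percentages,
#' the expected number of false-positive floodplain specialists at
#' \code{alpha} and the adjusted specialist percentage
#' \code{round(100 * (significant - expected FP) / tested)}. No
#' multiplicity correction is applied; the expected-false-positive count
#' is reported instead.
#'
#' @param inv a density-standardized \linkS4class{PlotInventory}.
#' @param spec \linkS4class{GridSpec} for range restriction.
#' @param minOcc strict occurrence threshold (default 20).
#' @param alpha significance level (default 0.05).
#' @param nPerm permutations per species (default 999).
#' @param seed master seed.
#' @param radius IDW search radius for range restriction.
#' @return an \linkS4class{AssociationTable}.
#' @export
classifyAll <- function(inv, spec, minOcc = 20, alpha = 0.05, nPerm = 999,
                        seed = 1L, radius = 3) {
  tested <- occurrenceFilter(inv, minOcc)
  rows <- lapply(tested, function(sp) {
    spSeed <- as.integer((as.double(seed) * 131071 +
                            match(sp, rownames(inv))) %%
                           .Machine$integer.max)
    bestAssociation(sp, inv, spec, nPerm = nPerm, seed = spSeed,
                    alpha = alpha, radius = radius)
  })
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species_id = character(), n_occurrences = integer(),
               n_plots = integer(), candidate = character(),
               rg = numeric(), p = numeric(), class = character())
  new("AssociationTable",
    results = results,
    summary = summarizeClassification(results, alpha),
    alpha = alpha, nPerm = as.integer(nPerm), seed = as.integer(seed)
  )
}

#' Summarize a classification table
#'
#' @param results data.frame as returned by \code{\link{bestAssociation}}
#'   (row-bound).
#' @param alpha significance level used.
#' @return list with counts, percentages, expected false positives and
#'   the adjusted floodplain-specialist percentage.
#' @export
summarizeClassification <- function(results, alpha = 0.05) {
  counts <- table(factor(results$class, levels = ALL_CLASSES))
  nTested <- sum(counts[setdiff(ALL_CLASSES, "not_tested")])
  nFP <- sum(counts[FP_CLASSES])
  expectedFP <- round(alpha * nFP)
  pct <- function(n) if (nTested > 0) round(100 * n / nTested) else 0
  list(
    counts = counts,
    nTested = as.integer(nTested),
    nFloodplainSpecialists = as.integer(nFP),
    pctFloodplainSpecialists = pct(nFP),
    pctTerraFirmeSpecialists = pct(counts[["terra_firme_specialist"]]),
    pctGeneralists = pct(counts[["generalist"]]),
    expectedFalsePositives = expectedFP,
    adjustedPctFloodplainSpecialists = pct(nFP - expectedFP)
  )
}
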