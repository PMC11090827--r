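## Cell-wise class profiles: relative abundance and richness of
## floodplain specialists, generalists and terra firme spillover in
## floodplain grids, and their least-squares relationships with turnover.

#' Per-cell class shares of abundance and richness
#'
#' Cross-references a floodplain composition grid with the classified
#' species and computes, for every covered cell, the share of summed
#' density (relative abundance) and of species count (relative richness)
#' belonging to floodplain specialists (subtypes pooled), generalists and
#' terra firme specialists. Species absent from the tested list are
#' excluded from the denominators; cells with no classified species are
#' dropped.
#'
#' @param grid a floodplain \linkS4class{CompositionGrid}.
#' @param classes an \linkS4class{AssociationTable} or its results
#'   data.frame.
#' @return data.frame with \code{cell} and columns
#'   \code{abundance_/richness_} x \code{floodplain/generalist/terra_firme};
#'   each trio sums to 1.
#' @export
cellClassProportions <- function(grid, classes) {
  if (is(classes, "AssociationTable")) classes <- classes@results
  cls <- classes[classes$class != "not_tested", c("species_id", "class")]
  cls$group <- ifelse(cls$class %in% FP_CLASSES, "floodplain",
               ifelse(cls$class == "terra_firme_specialist", "terra_firme",
                      "generalist"))
  common <- intersect(rownames(grid), cls$species_id)
  if (length(common) == 0) stop("no classified species occur in the grid")
  dens <- densities(grid)[common, , drop = FALSE]
  grp <- cls$group[match(common, cls$species_id)]
  groups <- c("floodplain", "generalist", "terra_firme")
  ind <- Matrix::sparseMatrix(
    i = match(grp, groups), j = seq_along(common), x = 1,
    dims = c(3, length(common))
  )
  ab <- as.matrix(ind %*% dens)                 # 3 x cells summed density
  ri <- as.matrix(ind %*% (dens > 0))           # 3 x cells species counts
  totAb <- colSums(ab)
  totRi <- colSums(ri)
  keep <- which(totAb > 0 & totRi > 0)
  out <- data.frame(cell = keep)
  for (g in seq_along(groups)) {
    out[[paste0("abundance_", groups[g])]] <- ab[g, keep] / totAb[keep]
    out[[paste0("richness_", groups[g])]] <- ri[g, keep] / totRi[keep]
  }
  out
}

#' Least-squares fits of class shares on turnover
#'
#' Ordinary least squares of each class share (abundance and richness)
#' against the cell turnover values, reporting slope, intercept,
#' \eqn{r^2} and p. Because the three shares sum to 1 in every cell, the
#' three fitted lines' predictions sum to 1 at any turnover value.
#'
#' @param profiles output of \code{\link{cellClassProportions}}.
#' @param turnover a \linkS4class{TurnoverMap} (or numeric vector over
#'   cells).
#' @param level confidence level of the pointwise band (default 0.95).
#' @return data.frame with one row per class and measure (\code{slope},
#'   \code{intercept}, \code{r2}, \code{p}, \code{n}); the fitted
#'   \code{lm} objects are in \code{attr(, "models")} and a band can be
#'   obtained with \code{predict(model, newdata, interval="confidence")}.
#' @export
regressProfiles <- function(profiles, turnover, level = 0.95) {
  beta <- if (is(turnover, "TurnoverMap")) gridValues(turnover)
          else as.numeric(turnover)
  b <- beta[profiles$cell]
  ok <- is.finite(b)
  if (sum(ok) < 3) stop("need at least 3 cells with valid turnover")
  if (var(b[ok]) == 0) stop("turnover has zero variance over the cells")
  shareCols <- setdiff(colnames(profiles), "cell")
  models <- list()
  rows <- lapply(shareCols, function(cn) {
    d <- data.frame(share = profiles[[cn]][ok], beta = b[ok])
    fit <- lm(share ~ beta, data = d)
    models[[cn]] <<- fit
    s <- summary(fit)
    measureClass <- strsplit(cn, "_")[[1]]
    data.frame(
      measure = measureClass[1],
      class = paste(measureClass[-1], collapse = "_"),
      slope = coef(fit)[["beta"]], intercept = coef(fit)[["(Intercept)"]],
      r2 = s$r.squared,
      p = if (nrow(s$coefficients) > 1) s$coefficients["beta", 4] else NA,
      n = sum(ok), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "models") <- models
  attr(out, "level") <- level
  out
}
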