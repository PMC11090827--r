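## Reading, validating and standardizing plot-inventory CSVs.
##
## plots.csv: plot_id, lon, lat, habitat (TF/VA/IG), area_ha
## stems.csv: plot_id, species_id, stems (non-negative integers)

#' Read plot and stem CSVs into a PlotInventory
#'
#' Validates both tables: required columns, unique plot ids, known habitat
#' codes, positive areas, non-negative integer stem counts, and referential
#' integrity (every stems row must cite a declared plot). Violations raise
#' an error naming the offending rows.
#'
#' @param plotsPath CSV with columns \code{plot_id, lon, lat, habitat,
#'   area_ha}.
#' @param stemsPath CSV with columns \code{plot_id, species_id, stems}.
#' @return a \linkS4class{PlotInventory}.
#' @seealso \code{\link{writeInventories}} for the inverse.
#' @export
readInventories <- function(plotsPath, stemsPath) {
  plots <- read.csv(plotsPath, stringsAsFactors = FALSE)
  stems <- read.csv(stemsPath, stringsAsFactors = FALSE)

  need <- c("plot_id", "lon", "lat", "habitat", "area_ha")
  miss <- setdiff(need, colnames(plots))
  if (length(miss))
    stop("plots table is missing columns: ", paste(miss, collapse = ", "))
  need <- c("plot_id", "species_id", "stems")
  miss <- setdiff(need, colnames(stems))
  if (length(miss))
    stop("stems table is missing columns: ", paste(miss, collapse = ", "))

  dup <- which(duplicated(plots$plot_id))
  if (length(dup))
    stop("duplicate plot_id in plots rows: ", paste(dup, collapse = ", "))
  bad <- which(!plots$habitat %in% HABITATS)
  if (length(bad))
    stop("unknown habitat code in plots rows: ", paste(bad, collapse = ", "))
  bad <- which(!(plots$area_ha > 0))
  if (length(bad))
    stop("non-positive area_ha in plots rows: ", paste(bad, collapse = ", "))

  orphan <- which(!stems$plot_id %in% plots$plot_id)
  if (length(orphan))
    stop("stems rows reference undeclared plots: rows ",
         paste(head(orphan, 10), collapse = ", "),
         " (plot ", paste(unique(stems$plot_id[orphan])[1], sep = ""), ")")
  bad <- which(!(stems$stems >= 0) | stems$stems != round(stems$stems))
  if (length(bad))
    stop("stem counts must be non-negative integers: rows ",
         paste(head(bad, 10), collapse = ", "))
  dup <- which(duplicated(stems[c("plot_id", "species_id")]))
  if (length(dup))
    stop("duplicate (plot_id, species_id) in stems rows: ",
         paste(head(dup, 10), collapse = ", "))

  speciesIds <- sort(unique(stems$species_id))
  mat <- Matrix::sparseMatrix(
    i = match(stems$species_id, speciesIds),
    j = match(stems$plot_id, plots$plot_id),
    x = as.numeric(stems$stems),
    dims = c(length(speciesIds), nrow(plots)),
    dimnames = list(speciesIds, plots$plot_id)
  )
  pd <- data.frame(
    lon = plots$lon, lat = plots$lat, habitat = plots$habitat,
    areaHa = plots$area_ha, row.names = plots$plot_id
  )
  inv <- PlotInventory(mat, pd)
  empty <- Matrix::colSums(SummarizedExperiment::assay(inv, "stems")) == 0
  if (any(empty)) {
    S4Vectors::metadata(inv)$emptyPlots <- colnames(inv)[empty]
    warning(sum(empty), " plot(s) have no recorded stems; ",
            "retained but flagged in metadata(x)$emptyPlots")
  }
  inv
}

#' Write a PlotInventory back to the two-CSV dialect
#'
#' @param x a \linkS4class{PlotInventory}.
#' @param plotsPath,stemsPath output CSV paths.
#' @return invisibly, the two paths.
#' @export
writeInventories <- function(x, plotsPath, stemsPath) {
  cd <- SummarizedExperiment::colData(x)
  plots <- data.frame(
    plot_id = colnames(x), lon = cd$lon, lat = cd$lat,
    habitat = as.character(cd$habitat), area_ha = cd$areaHa
  )
  st <- methods::as(SummarizedExperiment::assay(x, "stems"), "TsparseMatrix")
  stems <- data.frame(
    plot_id = colnames(x)[st@j + 1L],
    species_id = rownames(x)[st@i + 1L],
    stems = as.integer(st@x)
  )
  stems <- stems[order(stems$plot_id, stems$species_id), ]
  write.csv(plots, plotsPath, row.names = FALSE)
  write.csv(stems, stemsPath, row.names = FALSE)
  invisible(c(plotsPath, stemsPath))
}

#' Standardize stem counts to densities (stems/ha)
#'
#' Divides each plot's stem counts by its area so plots of different sizes
#' are comparable; adds a \code{"density"} assay. Total stems are conserved:
#' density times area reproduces the counts exactly.
#'
#' @param x a \linkS4class{PlotInventory}.
#' @return the inventory with a \code{"density"} assay.
#' @export
standardizeDensities <- function(x) {
  area <- SummarizedExperiment::colData(x)$areaHa
  if (any(area <= 0)) stop("all plot areas must be > 0")
  st <- SummarizedExperiment::assay(x, "stems")
  SummarizedExperiment::assay(x, "density", withDimnames = FALSE) <-
    st %*% Matrix::Diagonal(x = 1 / area)
  x
}

#' Long-format density table
#'
#' @param x a density-standardized \linkS4class{PlotInventory}.
#' @return data.frame with \code{plot_id}, \code{species_id}, \code{density}.
#' @export
densityTable <- function(x) {
  d <- methods::as(densities(x), "TsparseMatrix")
  out <- data.frame(
    plot_id = colnames(x)[d@j + 1L],
    species_id = rownames(x)[d@i + 1L],
    density = d@x
  )
  out[order(out$plot_id, out$species_id), ]
}

#' Drop records not identified to species level
#'
#' Morphospecies or otherwise unresolved names are flagged by the caller;
#' the flagged rows are removed and the retained fractions of names and
#' stems recorded in \code{metadata(x)$retention}.
#'
#' @param x a \linkS4class{PlotInventory}.
#' @param morphospeciesFlags character vector of species ids to drop, or a
#'   named logical vector over species (TRUE = drop).
#' @return the filtered inventory.
#' @export
filterSpeciesLevel <- function(x, morphospeciesFlags) {
  if (is.logical(morphospeciesFlags)) {
    flagged <- names(morphospeciesFlags)[morphospeciesFlags]
  } else {
    flagged <- as.character(morphospeciesFlags)
  }
  st <- SummarizedExperiment::assay(x, "stems")
  keep <- !rownames(x) %in% flagged
  totalStems <- sum(st)
  out <- x[keep, ]
  keptStems <- sum(SummarizedExperiment::assay(out, "stems"))
  S4Vectors::metadata(out)$retention <- c(
    species = if (nrow(x)) sum(keep) / nrow(x) else 1,
    stems = if (totalStems > 0) keptStems / totalStems else 1
  )
  if (sum(keep) == 0)
    warning("all species were flagged; the collection is empty")
  out
}
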