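## Flood-magnitude covariate from monthly land-water-thickness series.

#' Mean annual flood magnitude from a monthly LWT series
#'
#' For every cell, computes the range (max - min) of the monthly
#' land-water-thickness anomalies within each calendar year of the
#' analysis period and averages those yearly ranges. Years with fewer
#' than \code{minMonths} of the 12 months present are skipped; cells with
#' no usable year are masked. The result is invariant to a per-cell
#' constant offset (the anomaly baseline) and scales linearly with the
#' seasonal amplitude.
#'
#' @param series long data.frame with columns \code{cell}, \code{year},
#'   \code{month}, \code{lwt_cm}; non-finite values are treated as missing.
#' @param spec the \linkS4class{GridSpec} the cells index into.
#' @param period length-2 integer vector of calendar years, inclusive
#'   (default \code{c(2002, 2017)}).
#' @param minMonths minimum months per year for the year to count
#'   (default 10; gravimetric series have gaps).
#' @return an \linkS4class{EnvGrid} (cm land water thickness).
#' @export
floodMagnitude <- function(series, spec, period = c(2002, 2017),
                           minMonths = 10) {
  need <- c("cell", "year", "month", "lwt_cm")
  miss <- setdiff(need, colnames(series))
  if (length(miss))
    stop("series is missing columns: ", paste(miss, collapse = ", "))
  s <- series[series$year >= period[1] & series$year <= period[2] &
                is.finite(series$lwt_cm), , drop = FALSE]
  vals <- rep(NA_real_, nCells(spec))
  if (nrow(s)) {
    key <- interaction(s$cell, s$year, drop = TRUE)
    nm <- tapply(s$lwt_cm, key, length)
    rng <- tapply(s$lwt_cm, key, function(v) max(v) - min(v))
    cellOf <- tapply(s$cell, key, `[`, 1)
    ok <- nm >= minMonths
    if (any(ok)) {
      means <- tapply(rng[ok], cellOf[ok], mean)
      vals[as.integer(names(means))] <- as.numeric(means)
    }
  }
  EnvGrid(vals, spec, "flood magnitude, cm LWT")
}
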