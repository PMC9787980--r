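#' Reduce underway tracks to daily quarter-degree grid-cell means
#'
#' Dense underway records oversample small areas where the ship lingered;
#' averaging into daily 0.25 x 0.25 degree cells removes that weighting
#' bias before flux calculation. Bin edges are half-open
#' `[k*0.25, (k+1)*0.25)` anchored at 0 degrees; the day boundary is UTC
#' midnight (integer day-of-year). Missing values are dropped per variable,
#' so a record with no salinity still contributes to the pCO2 mean;
#' `n_obs` counts all records falling in the cell.
#'
#' @param records A data frame of surface records with columns `time`
#'   (decimal day-of-year), `lat`, `lon`, `sst`, `sss`, `pco2`.
#' @return A tibble with one row per occupied cell: `day`, `lat_bin`,
#'   `lon_bin` (bin indices), `lat`, `lon` (cell centres), `mean_sst`,
#'   `mean_sss`, `mean_pco2`, `n_obs`.
#' @export
#' @examples
#' rec <- tibble::tibble(time = 180.2, lat = c(68.1, 68.2), lon = -168.9,
#'                       sst = 5, sss = 31, pco2 = c(200, 300))
#' grid_daily(rec)
grid_daily <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    return(tibble::tibble(day = integer(), lat_bin = integer(),
                          lon_bin = integer(), lat = numeric(),
                          lon = numeric(), mean_sst = numeric(),
                          mean_sss = numeric(), mean_pco2 = numeric(),
                          n_obs = integer()))
  }
  stopifnot(all(is.finite(records$lat)), all(is.finite(records$lon)),
            all(is.finite(records$time)))
  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  records |>
    dplyr::mutate(
      day = as.integer(floor(.data$time)),
      lat_bin = as.integer(floor(.data$lat / 0.25)),
      lon_bin = as.integer(floor(.data$lon / 0.25))
    ) |>
    dplyr::summarise(
      lat = (.data$lat_bin[1] + 0.5) * 0.25,
      lon = (.data$lon_bin[1] + 0.5) * 0.25,
      mean_sst = mean_or_na(.data$sst),
      mean_sss = mean_or_na(.data$sss),
      mean_pco2 = mean_or_na(.data$pco2),
      n_obs = dplyr::n(),
      .by = c("day", "lat_bin", "lon_bin")
    )
}
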