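#' Great-circle distance between zip-code centroids, in miles
#'
#' Haversine distance on a sphere of radius 3958.8 miles, the convention
#' for patient-to-facility distances computed between zip-code centroids.
#' Vectorized with recycling.
#'
#' @param lat1,lon1 Origin coordinates in decimal degrees.
#' @param lat2,lon2 Destination coordinates in decimal degrees.
#' @return Numeric vector of distances in statute miles.
#' @examples
#' zip_distance(40, -75, 40, -74)  # ~53 miles along the 40th parallel
#' @export
zip_distance <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE) ||
      any(abs(c(lon1, lon2)) > 180, na.rm = TRUE))
    stop_config("coordinates out of range: |lat| <= 90, |lon| <= 180 required")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 3958.8)
}

#' Medical-care consumer price index lookup (annual averages)
#'
#' Used to express costs in 2020 US dollars.  Values are the US city
#' average medical-care CPI series; the conversion factor for a discharge
#' year is \code{cpi[2020] / cpi[year]}.  Override with your own table for
#' other base years or updated series.
#'
#' @format Named numeric vector, names are calendar years.
#' @export
cpi_medical_care <- c(`2016` = 463.67, `2017` = 475.32, `2018` = 484.71,
                      `2019` = 498.43, `2020` = 518.87)

#' CPI conversion factor to 2020 dollars
#'
#' @param year Integer vector of discharge years.
#' @param cpi Named CPI table; defaults to the bundled medical-care series.
#' @param base_year Target year of the conversion.
#' @return Numeric vector of multiplicative factors.  Years missing from the
#'   table get factor 1 with a warning.
#' @export
cpi_factor <- function(year, cpi = cpi_medical_care, base_year = 2020) {
  if (!as.character(base_year) %in% names(cpi))
    stop_config("base_year %s not in the CPI table", base_year)
  f <- cpi[[as.character(base_year)]] / cpi[as.character(year)]
  if (anyNA(f)) {
    warning("discharge year(s) outside the CPI table; factor 1 used")
    f[is.na(f)] <- 1
  }
  unname(f)
}

#' Standardize billed charges to cost in 2020 US dollars
#'
#' Cost = total charges x cost-to-charge ratio / wage index x CPI factor.
#' The wage-index adjustment is implemented as division, normalizing local
#' price levels to the national standard; pass \code{wage_index = 1} to
#' skip it or invert the ratio yourself for the opposite convention.
#'
#' @param total_charges Billed charges in USD (> 0).
#' @param cost_to_charge_ratio Facility cost-to-charge ratio (> 0).
#' @param wage_index Facility wage index (> 0).
#' @param cpi_factor Multiplicative CPI conversion to the base year (> 0);
#'   see [cpi_factor()].
#' @return Standardized cost in base-year USD.
#' @export
standardize_cost <- function(total_charges, cost_to_charge_ratio,
                             wage_index = 1, cpi_factor = 1) {
  if (any(total_charges <= 0 | cost_to_charge_ratio <= 0 |
          wage_index <= 0 | cpi_factor <= 0, na.rm = TRUE))
    stop_config("all cost inputs must be strictly positive")
  total_charges * cost_to_charge_ratio / wage_index * cpi_factor
}
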