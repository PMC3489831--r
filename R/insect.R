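#' Parameters of the temperature/wind insect activity index
#'
#' Both indices peak (value 1) in warm calm weather — temperature at or
#' above 18 C with no wind — and fall to 0 in cold windy weather; the
#' species differ in their low-temperature and high-wind cut-offs: mosquito
#' activity is 0 at or below 6 C or at winds of 6 m/s and above, oestrid fly
#' activity at or below 13 C or winds of 9 m/s and above. A location is
#' classed as a high-harassment period when the index exceeds `threshold`
#' at either weather station in the preceding `lookback` hours. A lower
#' mosquito wind cut-off of 4 m/s (reported for the area around the study
#' lake) is available via `local_wind = TRUE`.
#'
#' @param species `"mosquito"` or `"fly"`.
#' @param local_wind use the local 4 m/s mosquito wind cut-off.
#' @return object of class `insect_params`.
#' @export
insect_params <- function(species = c("mosquito", "fly"),
                          local_wind = FALSE) {
  species <- match.arg(species)
  p <- list(
    species = species,
    temp_hi = 18,
    temp_lo = if (species == "mosquito") 6 else 13,
    wind_lo = 0,
    wind_hi = if (species == "mosquito") {
      if (local_wind) 4 else 6
    } else 9,
    threshold = 0.5,
    lookback = 12
  )
  stopifnot(p$temp_lo < p$temp_hi, p$wind_lo < p$wind_hi,
            p$threshold > 0, p$threshold < 1)
  structure(p, class = "insect_params")
}

#' Insect activity index from temperature and wind
#'
#' A separable bilinear ramp anchored at the index's corner conditions:
#' `index = clamp01((temp - temp_lo)/(temp_hi - temp_lo)) *
#' clamp01((wind_hi - wind)/(wind_hi - wind_lo))`. It equals 1 at
#' (temp >= temp_hi, wind <= wind_lo), 0 whenever temp <= temp_lo or
#' wind >= wind_hi, and interpolates in between according to how far the
#' observation is from the maximum temperature and minimum wind speed.
#' Non-decreasing in temperature and non-increasing in wind everywhere.
#'
#' @param temp_c air temperature (C), vectorized.
#' @param wind_ms wind speed (m/s), vectorized.
#' @param params an [insect_params()].
#' @return index values in \[0, 1\].
#' @export
activity_index <- function(temp_c, wind_ms, params = insect_params()) {
  clamp01 <- function(z) pmin(pmax(z, 0), 1)
  t_score <- clamp01((temp_c - params$temp_lo) /
                       (params$temp_hi - params$temp_lo))
  w_score <- clamp01((params$wind_hi - wind_ms) /
                       (params$wind_hi - params$wind_lo))
  t_score * w_score
}

#' Classify the period preceding a fix as high or low insect harassment
#'
#' A fix is `"high"` when any weather record from any station in the
#' half-open window `(t - lookback, t]` has an activity index strictly
#' greater than `params$threshold`; `"low"` otherwise; `"unknown"` when the
#' window holds no weather records (such fixes are excluded downstream).
#'
#' @param fix_times POSIXct vector of fix timestamps.
#' @param weather a `weather_series` data.frame (station_id, timestamp,
#'   temp_c, wind_ms).
#' @param params an [insect_params()].
#' @return character vector in `{"high", "low", "unknown"}`.
#' @export
classify_insect_period <- function(fix_times, weather,
                                   params = insect_params()) {
  idx <- activity_index(weather$temp_c, weather$wind_ms, params)
  wt <- as.numeric(weather$timestamp)
  o <- order(wt)
  wt <- wt[o]; idx <- idx[o]
  # cumulative count of high-index records up to each weather time
  high_cum <- cumsum(idx > params$threshold)
  vapply(as.numeric(fix_times), function(t) {
    lo <- t - params$lookback * 3600
    i_hi <- findInterval(t, wt)            # records with time <= t
    i_lo <- findInterval(lo, wt)           # records with time <= t - lookback
    if (i_hi <= i_lo) return("unknown")    # no record in (lo, t]
    n_high <- high_cum[i_hi] - if (i_lo > 0) high_cum[i_lo] else 0
    if (n_high > 0) "high" else "low"
  }, character(1))
}
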