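#' Simulate hourly weather at two inland stations
#'
#' Generates hourly air temperature and wind speed for two weather stations
#' over `[start, end)` (half-open, so a 1-hour span yields one record per
#' station). Temperature follows a diurnal cycle plus AR(1) noise; wind is a
#' mixture of calm spells and gamma-distributed breezes. The parameters are
#' chosen so a mid-summer month visits all corner regions of the insect
#' activity index: warm-calm (index 1), cold-windy (mosquito index 0), and
#' cool with wind above the fly cut-off.
#'
#' @param config a [synthetic_config()] (seed source).
#' @param start,end POSIXct bounds (UTC); `end > start`.
#' @return data.frame `station_id`, `timestamp`, `temp_c`, `wind_ms`, one
#'   row per station-hour, of class `weather_series`.
#' @export
simulate_weather <- function(config, start, end) {
  stopifnot(inherits(config, "synthetic_config"), end > start)
  set.seed(config$seed + 1L)
  times <- seq(from = start, to = end, by = "3600 sec")
  times <- times[times < end]
  n <- length(times)
  hours <- as.numeric(format(times, "%H", tz = "UTC"))
  out <- lapply(c("station_a", "station_b"), function(st) {
    e <- stats::filter(stats::rnorm(n, 0, 3), 0.8, method = "recursive")
    temp <- 12 + 7 * sin(2 * pi * (hours - 9) / 24) + as.numeric(e)
    calm <- stats::runif(n) < 0.15
    wind <- ifelse(calm, stats::runif(n, 0, 0.8),
                   stats::rgamma(n, shape = 2, scale = 2.5))
    data.frame(station_id = st, timestamp = times,
               temp_c = temp, wind_ms = wind)
  })
  res <- do.call(rbind, out)
  class(res) <- c("weather_series", "data.frame")
  res
}
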