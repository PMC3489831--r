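#' Screen raw GPS fixes
#'
#' Removes records that degrade location accuracy: non-finite coordinates,
#' duplicate timestamps within an animal (first kept), 2D fixes, fixes with
#' positional dilution of precision strictly greater than `pdop_max`, and
#' fixes implying a movement speed above `max_speed_kmh` between consecutive
#' retained fixes (treated as erroneous points). Rows are sorted by animal
#' and time first.
#'
#' @param raw data.frame with columns `animal_id`, `timestamp` (POSIXct),
#'   `x`, `y`, `fix_dim` ("2D"/"3D"), `pdop`; extra columns pass through.
#' @param pdop_max PDOP cut-off; removal uses the strict rule `pdop > pdop_max`.
#' @param max_speed_kmh implied-speed cut-off for erroneous points (km/h).
#' @return list with `fixes` (screened data.frame) and `report` (counts by
#'   removal reason plus the overall removal fraction).
#' @export
screen_fixes <- function(raw, pdop_max = 10, max_speed_kmh = 50) {
  cols <- c("animal_id", "timestamp", "x", "y", "fix_dim", "pdop")
  if (nrow(raw) == 0) {
    report <- list(n_input = 0L, n_retained = 0L, removed = list(),
                   removal_fraction = 0)
    return(list(fixes = raw, report = report))
  }
  stopifnot(all(cols %in% names(raw)))
  n_input <- nrow(raw)
  d <- raw[order(raw$animal_id, raw$timestamp), , drop = FALSE]

  bad_coord <- !is.finite(d$x) | !is.finite(d$y)
  dup <- duplicated(d[, c("animal_id", "timestamp")])
  bad_2d <- d$fix_dim == "2D"
  bad_pdop <- d$pdop > pdop_max
  drop <- bad_coord | dup | bad_2d | bad_pdop
  d2 <- d[!drop, , drop = FALSE]

  # implied speed between consecutive surviving fixes per animal
  n_speed <- 0L
  if (nrow(d2) > 1) {
    keep <- rep(TRUE, nrow(d2))
    for (id in unique(d2$animal_id)) {
      i <- which(d2$animal_id == id)
      if (length(i) < 2) next
      last <- i[1]
      for (j in i[-1]) {
        dt_h <- as.numeric(difftime(d2$timestamp[j], d2$timestamp[last],
                                    units = "hours"))
        dist_km <- sqrt((d2$x[j] - d2$x[last])^2 +
                          (d2$y[j] - d2$y[last])^2) / 1000
        if (dt_h > 0 && dist_km / dt_h > max_speed_kmh) {
          keep[j] <- FALSE
        } else {
          last <- j
        }
      }
    }
    n_speed <- sum(!keep)
    d2 <- d2[keep, , drop = FALSE]
  }

  report <- list(
    n_input = n_input,
    n_retained = nrow(d2),
    removed = list(
      bad_coordinates = sum(bad_coord),
      duplicate_timestamp = sum(dup & !bad_coord),
      fix_2d = sum(bad_2d & !bad_coord & !dup),
      pdop = sum(bad_pdop & !bad_2d & !bad_coord & !dup),
      speed = n_speed
    ),
    removal_fraction = 1 - nrow(d2) / n_input
  )
  rownames(d2) <- NULL
  list(fixes = d2, report = report)
}

#' Drop sedentary fixes (movement <= `min_move` between relocations)
#'
#' Within each group (animal, or animal-season when a `season` column is
#' present), a fix is dropped when its displacement from the previously
#' retained fix is at most `min_move`; the previously retained fix — the
#' first location of the sedentary bout — always stays, and the bout ends
#' once a fix moves beyond `min_move` from it. The first fix of each group
#' is always retained. Applying the filter twice changes nothing.
#'
#' @param track screened fix data.frame (sorted or sortable by time).
#' @param min_move displacement threshold (m).
#' @param group_cols columns defining independent sequences.
#' @return filtered data.frame.
#' @export
filter_sedentary <- function(track, min_move = 25,
                             group_cols = intersect(c("animal_id", "season"),
                                                    names(track))) {
  if (nrow(track) <= 1) return(track)
  ord <- do.call(order, c(track[group_cols], list(track$timestamp)))
  d <- track[ord, , drop = FALSE]
  key <- do.call(paste, c(d[group_cols], sep = "\r"))
  keep <- rep(TRUE, nrow(d))
  for (k in unique(key)) {
    i <- which(key == k)
    if (length(i) < 2) next
    ref <- i[1]
    for (j in i[-1]) {
      disp <- sqrt((d$x[j] - d$x[ref])^2 + (d$y[j] - d$y[ref])^2)
      if (disp > min_move) ref <- j else keep[j] <- FALSE
    }
  }
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' The default biological season calendar
#'
#' Five summer periods defined by month-day windows (inclusive):
#' calving 1-15 Jun, post-calving 16-30 Jun, mosquito harassment 1-15 Jul,
#' oestrid fly harassment 16 Jul-7 Aug, late summer 8 Aug-15 Sep.
#'
#' @return data.frame `season`, `start` ("mm-dd"), `end` ("mm-dd").
#' @export
season_calendar <- function() {
  data.frame(
    season = c("calving", "post_calving", "mosquito", "oestrid_fly",
               "late_summer"),
    start = c("06-01", "06-16", "07-01", "07-16", "08-08"),
    end = c("06-15", "06-30", "07-15", "08-07", "09-15"),
    stringsAsFactors = FALSE
  )
}

validate_calendar <- function(cal) {
  stopifnot(all(c("season", "start", "end") %in% names(cal)))
  md <- function(s) as.integer(sub("-", "", s))
  s <- md(cal$start); e <- md(cal$end)
  stopifnot(all(s <= e))
  o <- order(s)
  if (any(s[o][-1] <= e[o][-nrow(cal)])) stop("season windows overlap")
  invisible(cal)
}

#' Label fixes with their biological season
#'
#' Uses the local date of the study area (a fixed UTC offset) against the
#' calendar's month-day windows; fixes outside every window are labelled
#' `"off_season"`.
#'
#' @param track fix data.frame with a POSIXct `timestamp`.
#' @param calendar a calendar as returned by [season_calendar()].
#' @param utc_offset_hours local-time offset applied before taking the date.
#' @return `track` with a `season` column added.
#' @export
assign_seasons <- function(track, calendar = season_calendar(),
                           utc_offset_hours = -8) {
  validate_calendar(calendar)
  local <- track$timestamp + utc_offset_hours * 3600
  md <- as.integer(format(local, "%m%d", tz = "UTC"))
  season <- rep("off_season", nrow(track))
  for (i in seq_len(nrow(calendar))) {
    s <- as.integer(sub("-", "", calendar$start[i]))
    e <- as.integer(sub("-", "", calendar$end[i]))
    season[md >= s & md <= e] <- calendar$season[i]
  }
  track$season <- season
  track
}

#' Flag animal-years that switched to another herd
#'
#' An animal-year is flagged (and excluded from analysis sets) when at least
#' one of its calving-season fixes falls inside the calving-area polygon of
#' another herd during a calving season after the animal's first.
#'
#' @param track fix data.frame with `animal_id`, `year`, `timestamp`, `x`,
#'   `y` (a `season` column is added if absent).
#' @param other_calving_polygons list of two-column matrices (x, y vertex
#'   rings) in the fixes' coordinate system; may be empty.
#' @return list with `fixes` (flagged animal-years removed, column
#'   `excluded_herd_switch` added first), `flags` (data.frame animal_id,
#'   year, excluded).
#' @export
flag_herd_switch <- function(track, other_calving_polygons = list()) {
  if (!"season" %in% names(track)) track <- assign_seasons(track)
  if (!"year" %in% names(track)) {
    track$year <- as.integer(format(track$timestamp, "%Y", tz = "UTC"))
  }
  ay <- unique(track[, c("animal_id", "year")])
  ay$excluded <- FALSE
  if (length(other_calving_polygons) > 0) {
    calv <- track[track$season == "calving", , drop = FALSE]
    if (nrow(calv) > 0) {
      inside <- rep(FALSE, nrow(calv))
      for (poly in other_calving_polygons) {
        inside <- inside | mgcv::in.out(rbind(poly, poly[1, ]),
                                        cbind(calv$x, calv$y))
      }
      first_year <- tapply(track$year, track$animal_id, min)
      hit <- unique(calv[inside, c("animal_id", "year")])
      if (nrow(hit) > 0) {
        for (r in seq_len(nrow(hit))) {
          if (hit$year[r] > first_year[[hit$animal_id[r]]]) {
            ay$excluded[ay$animal_id == hit$animal_id[r] &
                          ay$year >= hit$year[r]] <- TRUE
          }
        }
      }
    }
  }
  track$excluded_herd_switch <- ay$excluded[
    match(paste(track$animal_id, track$year),
          paste(ay$animal_id, ay$year))]
  list(fixes = track[!track$excluded_herd_switch, , drop = FALSE],
       flags = ay)
}
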