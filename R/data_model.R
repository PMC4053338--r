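#' @keywords internal
"_PACKAGE"

## Closed vocabularies for the three study tables.  All validation funnels
## through these so error messages always list the allowed labels.
SPECIES_LEVELS <- c("wild_dog", "fox", "feral_cat")
BEHAVIOUR_LEVELS <- c("feeding", "investigating", "scent_marking", "moving_through")
SEASON_LEVELS <- c("winter", "spring")
DESIGN_DISTANCES <- c(0.05, 1, 2, 3, 4)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_rows <- function(bad, what, allowed = NULL) {
  msg <- sprintf("%s in row(s) %s", what, paste(which(bad), collapse = ", "))
  if (!is.null(allowed)) {
    msg <- paste0(msg, "; allowed: ", paste(allowed, collapse = ", "))
  }
  stop(msg, call. = FALSE)
}

#' Validate a table of carcass visit events
#'
#' An event is one visit by one species to one carcass, with a behaviour
#' label and a duration in seconds.  Columns: `carcass_id`, `species`,
#' `start_time` (POSIXct), `duration` (seconds, >= 0), `behaviour`,
#' `n_individuals` (>= 1).
#'
#' @param events data frame of events.
#' @return the validated data frame, invisibly unchanged.
#' @export
validate_events <- function(events) {
  need <- c("carcass_id", "species", "start_time", "duration", "behaviour",
            "n_individuals")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("events table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(events)) {
    bad <- !(events$species %in% SPECIES_LEVELS)
    if (any(bad)) stop_rows(bad, "unknown species", SPECIES_LEVELS)
    bad <- !(events$behaviour %in% BEHAVIOUR_LEVELS)
    if (any(bad)) stop_rows(bad, "unknown behaviour", BEHAVIOUR_LEVELS)
    bad <- !is.finite(events$duration) | events$duration < 0
    if (any(bad)) stop_rows(bad, "negative or non-finite duration")
    bad <- events$n_individuals < 1
    if (any(bad)) stop_rows(bad, "n_individuals < 1")
    if (!inherits(events$start_time, "POSIXct"))
      stop("start_time must be POSIXct", call. = FALSE)
  }
  invisible(events)
}

#' Validate a table of carcass sites
#'
#' Columns: `carcass_id`, `transect_id`, `distance_to_farm` (km, from the
#' design set 0.05/1/2/3/4), `season` (winter/spring), `deploy_date`,
#' `removal_date` (Date, may be NA), `censored` (logical; cameras stolen or
#' monitoring ended before the carcass was exhausted).
#'
#' @param sites data frame of sites.
#' @return the validated data frame, invisibly.
#' @export
validate_sites <- function(sites) {
  need <- c("carcass_id", "transect_id", "distance_to_farm", "season",
            "deploy_date", "removal_date", "censored")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("sites table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(sites)) {
    if (anyDuplicated(sites$carcass_id))
      stop("duplicate carcass_id in sites", call. = FALSE)
    bad <- !(sites$season %in% SEASON_LEVELS)
    if (any(bad)) stop_rows(bad, "unknown season", SEASON_LEVELS)
    bad <- !sapply(sites$distance_to_farm,
                   function(d) any(abs(d - DESIGN_DISTANCES) < 1e-9))
    if (any(bad)) stop_rows(bad, "distance_to_farm not in design set",
                            DESIGN_DISTANCES)
    ok <- is.na(sites$removal_date) | sites$removal_date >= sites$deploy_date
    if (any(!ok)) stop_rows(!ok, "removal_date before deploy_date")
  }
  invisible(sites)
}

#' Validate a table of biomass inspections
#'
#' Each row is one ~14-day inspection of one carcass, recording the
#' proportion of edible biomass remaining on the front and rear halves.
#'
#' @param inspections data frame with columns `carcass_id`, `date`,
#'   `front_half`, `rear_half` (proportions in \[0,1\]).
#' @return the validated data frame, invisibly.
#' @export
validate_inspections <- function(inspections) {
  need <- c("carcass_id", "date", "front_half", "rear_half")
  miss <- setdiff(need, names(inspections))
  if (length(miss)) stop("inspections table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  for (col in c("front_half", "rear_half")) {
    bad <- !is.finite(inspections[[col]]) | inspections[[col]] < 0 |
      inspections[[col]] > 1
    if (any(bad)) stop_rows(bad, paste(col, "outside [0,1]"))
  }
  invisible(inspections)
}

#' Read and write the three study tables as CSV
#'
#' CSV with a header naming the type's fields; timestamps ISO-8601 in UTC,
#' dates `YYYY-MM-DD`.  Reading validates; the read/write round trip is
#' lossless.
#'
#' @param path file path.
#' @name table_io
#' @return `read_*` return validated data frames; `write_*` return the path
#'   invisibly.
NULL

#' @rdname table_io
#' @export
read_events <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$start_time <- as.POSIXct(x$start_time, tz = "UTC",
                             format = "%Y-%m-%dT%H:%M:%S")
  if (nrow(x) && anyNA(x$start_time))
    stop("unparseable ISO-8601 start_time in ", path, call. = FALSE)
  validate_events(x)
  x
}

#' @rdname table_io
#' @param events,sites,inspections tables to write.
#' @export
write_events <- function(events, path) {
  validate_events(events)
  out <- events
  out$start_time <- format(events$start_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_sites <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$deploy_date <- as.Date(x$deploy_date)
  x$removal_date <- as.Date(x$removal_date)
  x$censored <- as.logical(x$censored)
  validate_sites(x)
  x
}

#' @rdname table_io
#' @export
write_sites <- function(sites, path) {
  validate_sites(sites)
  utils::write.csv(sites, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_inspections <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$date <- as.Date(x$date)
  validate_inspections(x)
  x
}

#' @rdname table_io
#' @export
write_inspections <- function(inspections, path) {
  validate_inspections(inspections)
  utils::write.csv(inspections, path, row.names = FALSE)
  invisible(path)
}

#' Mean edible biomass of the two carcass halves
#'
#' Biomass is recorded per half (front: head, front legs, ribs; rear: the
#' remainder) because the halves can decay at different rates; analyses use
#' the mean of the two.
#'
#' @param front,rear proportions in \[0,1\].
#' @return the arithmetic mean proportion.
#' @export
mean_halves <- function(front, rear) {
  if (any(!is.finite(front) | front < 0 | front > 1) ||
      any(!is.finite(rear) | rear < 0 | rear > 1))
    stop("half proportions must lie in [0,1]", call. = FALSE)
  (front + rear) / 2
}

#' Linearly interpolated daily edible biomass
#'
#' Edible biomass is measured only at ~14-day inspections; between
#' inspections it is assumed to decline linearly.  No extrapolation is
#' performed outside the inspected window.
#'
#' @param inspections inspections for one carcass.
#' @param day a `Date` (or vector of dates) at which to interpolate.
#' @return proportion(s) in \[0,1\]; exact at inspection dates.
#' @export
interpolate_daily_biomass <- function(inspections, day) {
  validate_inspections(inspections)
  if (length(unique(inspections$carcass_id)) > 1)
    stop("inspections must belong to a single carcass", call. = FALSE)
  o <- order(inspections$date)
  d <- as.numeric(inspections$date[o])
  b <- mean_halves(inspections$front_half[o], inspections$rear_half[o])
  x <- as.numeric(as.Date(day))
  if (any(x < d[1] | x > d[length(d)]))
    stop("day outside the inspected window [", as.Date(d[1], origin = "1970-01-01"),
         ", ", as.Date(d[length(d)], origin = "1970-01-01"),
         "]: no extrapolation", call. = FALSE)
  if (length(d) == 1) return(rep(b, length(x)))
  stats::approx(d, b, xout = x, ties = "ordered")$y
}

#' Daily presence/absence series for one carcass
#'
#' Collapses events to one row per monitored day with wild dog and fox
#' presence flags and the interpolated edible biomass.  A day runs from
#' `day_start_hour` to `day_start_hour` + 24 h; an event sets the flag on
#' every day its \[start, start + duration\] interval intersects.
#'
#' @param events events for this carcass (other carcasses' rows are ignored).
#' @param inspections inspections for this carcass, bracketing the monitored
#'   window.
#' @param site one-row site table for the carcass.
#' @param day_start_hour boundary of the 24-h period; 0 (calendar days,
#'   default) or 12 (midday-anchored, matching the diel activity clocks).
#' @return data frame with `carcass_id`, `day_index` (1 = first monitored
#'   day), `date`, `dog_present`, `fox_present` (0/1) and `biomass`.
#' @export
build_daily_series <- function(events, inspections, site, day_start_hour = 0) {
  validate_sites(site)
  stopifnot(nrow(site) == 1)
  events <- events[events$carcass_id == site$carcass_id, , drop = FALSE]
  validate_events(events)
  inspections <- inspections[inspections$carcass_id == site$carcass_id, ,
                             drop = FALSE]
  end_date <- site$removal_date
  if (is.na(end_date)) end_date <- max(inspections$date)
  n_days <- as.integer(end_date - site$deploy_date)
  if (n_days < 1) stop("monitored window shorter than one day", call. = FALSE)
  day0 <- as.POSIXct(paste(site$deploy_date, sprintf("%02d:00:00", day_start_hour)),
                     tz = "UTC")
  breaks <- day0 + (0:n_days) * 86400

  present <- function(sp) {
    flag <- integer(n_days)
    ev <- events[events$species == sp, , drop = FALSE]
    if (!nrow(ev)) return(flag)
    s <- as.numeric(ev$start_time)
    e <- s + ev$duration
    if (any(s < as.numeric(breaks[1]) | e > as.numeric(breaks[n_days + 1])))
      stop("event outside the monitored window for ", site$carcass_id,
           call. = FALSE)
    for (i in seq_len(nrow(ev))) {
      first <- findInterval(s[i], as.numeric(breaks))
      last <- findInterval(e[i], as.numeric(breaks), left.open = TRUE)
      flag[first:min(last, n_days)] <- 1L
    }
    flag
  }

  dates <- site$deploy_date + seq_len(n_days) - 1
  data.frame(
    carcass_id = site$carcass_id,
    day_index = seq_len(n_days),
    date = dates,
    dog_present = present("wild_dog"),
    fox_present = present("fox"),
    biomass = interpolate_daily_biomass(inspections, dates),
    stringsAsFactors = FALSE
  )
}
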