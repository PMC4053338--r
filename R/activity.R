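## Descriptive layer: carcass-use summaries, 24-h activity clocks (anchored
## at midday), feeding-bout statistics, BCa bootstrap intervals for total
## feeding time, and interspecific departure-arrival intervals.

#' Per-species carcass use summary
#'
#' Counts and percentages of carcasses visited (>= 1 event) and fed at
#' (>= 1 feeding event) by each species.
#'
#' @param events validated events table.
#' @param sites validated sites table (denominator = number of sites).
#' @return data frame: species, n_visited, n_fed, pct_visited, pct_fed.
#' @export
carcass_use_summary <- function(events, sites) {
  validate_events(events)
  validate_sites(sites)
  n <- nrow(sites)
  out <- lapply(SPECIES_LEVELS, function(sp) {
    ev <- events[events$species == sp, , drop = FALSE]
    visited <- unique(ev$carcass_id)
    fed <- unique(ev$carcass_id[ev$behaviour == "feeding"])
    data.frame(species = sp, n_visited = length(visited),
               n_fed = length(fed),
               pct_visited = 100 * length(visited) / n,
               pct_fed = 100 * length(fed) / n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' 24-hour activity clock
#'
#' Apportions event durations into time-of-day bins pro-rata by overlap and
#' averages over monitored days.  The 24-h cycle is anchored at midday
#' (12:00 to 12:00), the convention for diel activity at carcasses, so that
#' a single night's activity is not split across two cycles.
#'
#' @param events validated events table (already filtered to the carcasses
#'   of interest).
#' @param species species to summarise.
#' @param behaviour_filter optional behaviour subset (default: all).
#' @param bin_minutes bin width; must divide 1440.
#' @param monitored_days total carcass-days monitored (the averaging
#'   denominator).
#' @param anchor_hour start of the cycle (default 12).
#' @return data frame of class `activity_clock`: `bin_start_min` (minutes
#'   after the anchor), `minutes_per_day`.  Total minutes are conserved
#'   exactly: sum(minutes_per_day) * monitored_days equals the total event
#'   minutes.
#' @export
activity_clock <- function(events, species, behaviour_filter = NULL,
                           bin_minutes = 60, monitored_days = 1,
                           anchor_hour = 12) {
  stopifnot(1440 %% bin_minutes == 0, monitored_days > 0)
  validate_events(events)
  ev <- events[events$species == species, , drop = FALSE]
  if (!is.null(behaviour_filter))
    ev <- ev[ev$behaviour %in% behaviour_filter, , drop = FALSE]
  n_bins <- 1440 / bin_minutes
  tot <- numeric(n_bins)
  if (nrow(ev)) {
    lt <- as.POSIXlt(ev$start_time, tz = "UTC")
    ## minutes since the anchor, wrapped to [0, 1440)
    start_min <- (lt$hour * 60 + lt$min + lt$sec / 60 -
                    anchor_hour * 60) %% 1440
    dur_min <- ev$duration / 60
    for (i in seq_along(start_min)) {
      s <- start_min[i]
      remaining <- dur_min[i]
      while (remaining > 1e-12) {
        b <- floor(s / bin_minutes) + 1
        room <- b * bin_minutes - s
        take <- min(room, remaining)
        tot[b] <- tot[b] + take
        remaining <- remaining - take
        s <- (s + take) %% 1440
      }
    }
  }
  structure(data.frame(bin_start_min = seq(0, 1439, by = bin_minutes),
                       minutes_per_day = tot / monitored_days),
            class = c("activity_clock", "data.frame"),
            species = species, anchor_hour = anchor_hour,
            monitored_days = monitored_days)
}

#' Plot an activity clock as a polar diagram
#'
#' Simple base-graphics polar rendering; radial rings mark 5 and 10
#' minutes of mean daily activity.
#'
#' @param x an `activity_clock`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.activity_clock <- function(x, ...) {
  anchor <- attr(x, "anchor_hour")
  theta <- 2 * pi * (x$bin_start_min + diff(c(x$bin_start_min, 1440)) / 2) /
    1440
  r <- x$minutes_per_day
  graphics::plot(NULL, xlim = c(-12, 12), ylim = c(-12, 12), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", ...)
  for (ring in c(5, 10))
    graphics::lines(ring * sin(seq(0, 2 * pi, length.out = 200)),
                    ring * cos(seq(0, 2 * pi, length.out = 200)),
                    col = "grey70")
  graphics::polygon(r * sin(theta), r * cos(theta), col = "grey40",
                    border = NA)
  for (h in seq(0, 21, 3)) {
    a <- 2 * pi * ((h - anchor) %% 24) / 24
    graphics::text(11 * sin(a), 11 * cos(a), sprintf("%02d:00", h),
                   cex = 0.7)
  }
  invisible(x)
}

merge_visits <- function(ev, gap_min) {
  ## merge a species' events at one carcass into visits when separated by
  ## less than gap_min minutes
  o <- order(ev$start_time)
  s <- as.numeric(ev$start_time[o])
  e <- s + ev$duration[o]
  visit <- cumsum(c(1, as.integer(s[-1] - cummax(e[-length(e)]) >=
                                    gap_min * 60)))
  split(o, visit)
}

#' Bout statistics for one behaviour
#'
#' Events of one species are merged into visits (events closer than
#' `merge_gap` minutes at the same carcass belong to one visit); bout
#' durations are the per-event durations of the requested behaviour, and
#' the share is the fraction of visits containing at least one such bout.
#'
#' @param events validated events table.
#' @param species species to summarise.
#' @param behaviour behaviour of interest (default "feeding").
#' @param merge_gap visit-merging gap in minutes (default 5).
#' @return list with `n_bouts`, `mean_min`, `sd_min`, `share_of_visits`;
#'   all NA/0 fields (not an error) when no events match.
#' @export
bout_stats <- function(events, species, behaviour = "feeding",
                       merge_gap = 5) {
  validate_events(events)
  ev <- events[events$species == species, , drop = FALSE]
  if (!nrow(ev))
    return(list(n_bouts = 0L, mean_min = NA_real_, sd_min = NA_real_,
                share_of_visits = NA_real_))
  sel <- ev[ev$behaviour == behaviour, , drop = FALSE]
  visits <- unlist(lapply(split(seq_len(nrow(ev)), ev$carcass_id),
                          function(ix) {
    vis <- merge_visits(ev[ix, ], merge_gap)
    vapply(vis, function(v) any(ev$behaviour[ix][v] == behaviour), TRUE)
  }))
  dur <- sel$duration / 60
  list(n_bouts = nrow(sel),
       mean_min = if (nrow(sel)) mean(dur) else NA_real_,
       sd_min = if (nrow(sel) > 1) stats::sd(dur) else
         if (nrow(sel) == 1) 0 else NA_real_,
       share_of_visits = mean(visits))
}

#' BCa bootstrap confidence interval
#'
#' Bias-corrected and accelerated percentile interval for a statistic of a
#' sample; acceleration from the jackknife.  Degenerate (all-equal)
#' samples return a zero-width interval at the point estimate.
#'
#' @param values numeric sample (>= 2 values).
#' @param statistic function of a numeric vector (default mean).
#' @param n_boot bootstrap replicates (>= 1000 recommended).
#' @param level confidence level.
#' @param seed RNG seed; results are reproducible given the seed.
#' @return list with `estimate`, `lo`, `hi`.
#' @export
bca_bootstrap_ci <- function(values, statistic = mean, n_boot = 2000,
                             level = 0.95, seed = 1) {
  stopifnot(length(values) >= 2)
  est <- statistic(values)
  if (length(unique(values)) == 1)
    return(list(estimate = est, lo = est, hi = est))
  set.seed(seed)
  b <- boot::boot(values, function(d, i) statistic(d[i]), R = n_boot)
  ci <- boot::boot.ci(b, conf = level, type = "bca")
  list(estimate = est, lo = ci$bca[4], hi = ci$bca[5])
}

#' Interspecific departure-arrival intervals
#'
#' For every event, finds the most recent prior departure of a different
#' species at the same carcass and reports the gap in minutes between that
#' departure and this arrival.  Non-positive gaps indicate co-presence and
#' are flagged.
#'
#' @param events validated events table.
#' @return data frame sorted by gap: `carcass_id`, `from_species`,
#'   `to_species`, `gap_min`, `co_presence`.
#' @export
interspecies_intervals <- function(events) {
  validate_events(events)
  out <- list()
  for (cid in unique(events$carcass_id)) {
    ev <- events[events$carcass_id == cid, , drop = FALSE]
    ev <- ev[order(ev$start_time), , drop = FALSE]
    s <- as.numeric(ev$start_time)
    e <- s + ev$duration
    for (i in seq_len(nrow(ev))) {
      prior <- which(ev$species != ev$species[i] & s <= s[i])
      if (!length(prior)) next
      j <- prior[which.max(e[prior])]
      gap <- (s[i] - e[j]) / 60
      out[[length(out) + 1]] <- data.frame(
        carcass_id = cid, from_species = ev$species[j],
        to_species = ev$species[i], gap_min = gap,
        co_presence = gap <= 0, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(carcass_id = character(), from_species = character(),
                      to_species = character(), gap_min = numeric(),
                      co_presence = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$gap_min), ]
}
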