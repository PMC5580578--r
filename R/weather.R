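#' Detect qualifying wet-weather events in a rain series
#'
#' A wet-weather event begins when rainfall accumulates to at least
#' `min_depth` inches following an antecedent dry period of at least
#' `dry_days` consecutive dry days (a day is dry when its total depth is
#' below `dry_day_threshold`, i.e. at most trace rain).  Accumulation starts
#' at the first rainy day after a qualifying dry spell and carries across
#' consecutive records; trace-rain days neither break a dry spell nor add to
#' the accumulated depth; if a fresh `dry_days`-long dry spell intervenes
#' before the trigger depth is reached, the accumulation resets.  The event
#' start is the first record at which the cumulative depth reaches
#' `min_depth`, and its sampling window extends 72 h from that start.  A
#' subsequent event requires a new qualifying dry spell, so windows of one
#' gauge never overlap.  No antecedent dry credit is assumed before the first
#' record of a series.
#'
#' @param rain A validated rain series ([read_rain_series()]); may hold
#'   several gauges, daily or sub-daily records.
#' @param min_depth Event trigger depth, inches (default 0.10).
#' @param dry_days Required antecedent dry days (default 3).
#' @param dry_day_threshold Daily depth below which a day counts as dry,
#'   inches (default 0.01).
#' @return A tibble of events: `gauge_id`, `start`, `window_end`
#'   (= start + 72 h).
#' @export
detect_wet_events <- function(rain, min_depth = 0.10, dry_days = 3,
                              dry_day_threshold = 0.01) {
  rain <- validate_rain_series(rain)
  out <- lapply(split(rain, rain$gauge_id), function(g) {
    detect_wet_events_gauge(g, min_depth, dry_days, dry_day_threshold)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(gauge_id = character(),
                          start = as.POSIXct(character(), tz = "UTC"),
                          window_end = as.POSIXct(character(), tz = "UTC")))
  }
  res[order(res$gauge_id, res$start), ]
}

detect_wet_events_gauge <- function(g, min_depth, dry_days, dry_day_threshold) {
  g <- g[order(g$timestamp), ]
  day_chr <- as.character(as.Date(g$timestamp))
  # fill calendar gaps with zero-rain (dry) days
  all_days <- as.character(seq(as.Date(day_chr[1]),
                               as.Date(day_chr[length(day_chr)]), by = "day"))
  totals <- setNames(rep(0, length(all_days)), all_days)
  day_total <- tapply(g$depth_inches, day_chr, sum)
  totals[names(day_total)] <- day_total
  idx_by_day <- split(seq_len(nrow(g)), day_chr)

  starts <- as.POSIXct(character(), tz = "UTC")
  dry_run <- 0L
  accumulating <- FALSE
  cum <- 0
  for (d in all_days) {
    is_dry <- totals[[d]] < dry_day_threshold
    if (!accumulating && !is_dry && dry_run >= dry_days) {
      accumulating <- TRUE
      cum <- 0
    }
    if (accumulating) {
      idx <- idx_by_day[[d]]
      started <- FALSE
      if (!is_dry && length(idx) > 0) {   # trace days do not accumulate
        cs <- cum + cumsum(g$depth_inches[idx])
        hit <- which(cs >= min_depth)
        if (length(hit) > 0) {
          starts <- c(starts, g$timestamp[idx[hit[1]]])
          accumulating <- FALSE
          started <- TRUE
        }
        cum <- cs[length(cs)]
      }
      if (!started && is_dry && dry_run + 1L >= dry_days) {
        accumulating <- FALSE  # dry spell broke the accumulation
      }
    }
    dry_run <- if (is_dry) dry_run + 1L else 0L
  }
  tibble::tibble(
    gauge_id = g$gauge_id[1],
    start = starts,
    window_end = starts + 72 * 3600
  )
}

#' Classify a sample timestamp as wet-weather, dry-weather or excluded
#'
#' Wet: the timestamp falls inside an event window (start to start + 72 h).
#' Dry: outside every event window plus a further 72-h post-event buffer
#' (keeping storm tails out of dry-weather summaries) and within the
#' recreational season, 1 April to 31 October.  Anything else -- off-season
#' non-storm samples, or samples in the post-storm buffer -- is excluded.
#' Wet samples are accepted year-round.
#'
#' @param timestamp POSIXct sample collection time(s).
#' @param events Event table from [detect_wet_events()] for the sample's
#'   nearest gauge.
#' @param season_start,season_end Month-day bounds of the dry-weather season
#'   (defaults "04-01" and "10-31").
#' @param buffer_hours Dry-weather buffer after an event window, hours
#'   (default 72).
#' @return Character vector: `"WET"`, `"DRY"` or `"EXCLUDED"`.
#' @export
classify_sample_weather <- function(timestamp, events,
                                    season_start = "04-01",
                                    season_end = "10-31",
                                    buffer_hours = 72) {
  vapply(seq_along(timestamp), function(i) {
    t <- timestamp[i]
    if (nrow(events) > 0) {
      in_window <- t >= events$start & t <= events$window_end
      if (any(in_window)) return("WET")
      in_buffer <- t > events$window_end &
        t <= events$window_end + buffer_hours * 3600
      if (any(in_buffer)) return("EXCLUDED")
    }
    md <- format(t, "%m-%d")
    if (md >= season_start && md <= season_end) "DRY" else "EXCLUDED"
  }, character(1))
}

#' Assign wet/dry weather strata to sample metadata
#'
#' Detects events per gauge and classifies each sample against the events of
#' its own `gauge_id`.
#'
#' @param metadata Sample metadata ([read_sample_metadata()]).
#' @param rain Rain series covering every gauge in the metadata.
#' @inheritParams detect_wet_events
#' @inheritParams classify_sample_weather
#' @return The metadata with a `weather` column (`WET`/`DRY`/`EXCLUDED`).
#' @export
assign_weather <- function(metadata, rain, min_depth = 0.10, dry_days = 3,
                           dry_day_threshold = 0.01, buffer_hours = 72) {
  events <- detect_wet_events(rain, min_depth, dry_days, dry_day_threshold)
  metadata$weather <- vapply(seq_len(nrow(metadata)), function(i) {
    ev <- events[events$gauge_id == metadata$gauge_id[i], ]
    classify_sample_weather(metadata$timestamp[i], ev,
                            buffer_hours = buffer_hours)
  }, character(1))
  metadata
}
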