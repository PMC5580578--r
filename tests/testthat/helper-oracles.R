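# Independent oracles and small fixture builders shared across tests.

# a noise-free master curve with detection limits set
make_test_curve <- function(slope = -3.5, intercept = 37) {
  pts <- data.frame(
    log10_copies = rep(0:5, each = 3),
    cq = intercept + slope * rep(0:5, each = 3)
  )
  cv <- fit_master_curve(pts, "labT")
  derive_detection_limits(
    cv,
    cq_1copy = rep(intercept, 3),
    cq_10copy = rep(intercept + slope, 3)
  )
}

# grid-search maximizer of the presence/absence Poisson likelihood
grid_mpn <- function(n, k, grid = seq(1e-4, 10, by = 1e-4)) {
  loglik <- k * log(1 - exp(-grid)) - grid * (n - k)
  grid[which.max(loglik)]
}

# closed-form posterior mean of lambda under likelihood
# (1 - e^-l)^k e^(-l(n-k)) and uniform prior on [0, upper]:
# expand (1 - e^-l)^k binomially and integrate term by term
bayes_closed_form <- function(n, k, upper) {
  j <- 0:k
  a <- j + n - k
  coefs <- choose(k, j) * (-1)^j
  int0 <- ifelse(a == 0, upper, (1 - exp(-a * upper)) / a)
  int1 <- ifelse(a == 0, upper^2 / 2,
                 (1 - (1 + a * upper) * exp(-a * upper)) / a^2)
  sum(coefs * int1) / sum(coefs * int0)
}

# brute-force day-by-day wet-event finder: for each wet day with three dry
# days immediately before it, accumulate daily totals forward; an event
# starts on the first day cumulative depth reaches min_depth unless a
# three-day dry spell intervenes first
brute_force_events <- function(depths, dates, min_depth = 0.10,
                               dry_days = 3, dry_day_threshold = 0.01) {
  n <- length(depths)
  dry <- depths < dry_day_threshold
  starts <- as.Date(character())
  for (o in seq_len(n)) {
    if (dry[o]) next
    if (o <= dry_days) next                       # no antecedent credit
    if (!all(dry[(o - dry_days):(o - 1)])) next
    cum <- 0
    run <- 0
    for (s in o:n) {
      if (!dry[s]) {                              # trace days do not count
        cum <- cum + depths[s]
        if (cum >= min_depth) {
          starts <- c(starts, dates[s])
          break
        }
      }
      run <- if (dry[s]) run + 1 else 0
      if (run >= dry_days) break                  # dry spell aborted it
    }
  }
  starts
}

# independent classifier working directly off brute-force events
brute_force_classify <- function(ts, event_starts) {
  ev <- if (length(event_starts) == 0) {
    as.POSIXct(character(), tz = "UTC")
  } else {
    as.POSIXct(paste(event_starts, "00:00:00"), tz = "UTC")
  }
  vapply(seq_along(ts), function(i) {
    t <- ts[i]
    if (length(ev) > 0) {
      d <- as.numeric(difftime(t, ev, units = "hours"))
      if (any(d >= 0 & d <= 72)) return("WET")
      if (any(d > 72 & d <= 144)) return("EXCLUDED")
    }
    md <- format(t, "%m-%d")
    if (md >= "04-01" && md <= "10-31") "DRY" else "EXCLUDED"
  }, character(1))
}

# random daily rain series with trace days, seeded by the caller
random_rain_series <- function(n_days = 60, start = as.Date("2014-01-01")) {
  depths <- ifelse(
    runif(n_days) < 0.3,
    round(rexp(n_days, rate = 15), 3),  # mostly small, some over 0.10
    0
  )
  dates <- start + seq_len(n_days) - 1
  tibble::tibble(
    gauge_id = "g1",
    timestamp = as.POSIXct(paste(dates, "00:00:00"), tz = "UTC"),
    depth_inches = depths
  )
}

# a full fixture plate in the shared layout: 6 standards x 3, 2 NEC x 3,
# 1 NTC x 3, 22 samples x 3 = 93 occupied wells
fixture_plate <- function(plate_id = "p1", lab_id = "lab1",
                          slope = -3.5, intercept = 37, sample_cq = 30) {
  positions <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8))
  std_copies <- rep(10^(0:5), each = 3)
  sample_ids <- rep(sprintf("s%02d", 1:22), each = 3)
  tibble::tibble(
    plate_id = plate_id,
    lab_id = lab_id,
    well = positions[1:93],
    role = c(rep("STANDARD", 18), rep("NEC", 6), rep("NTC", 3),
             rep("SAMPLE", 66)),
    target = "HF183",
    sample_id = c(rep(NA_character_, 27), sample_ids),
    standard_copies = c(std_copies, rep(NA_real_, 75)),
    cq = c(intercept + slope * log10(std_copies), rep(NA_real_, 9),
           rep(sample_cq, 66))
  )
}
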