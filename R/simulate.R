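#' Construct a site-truth table for simulation
#'
#' Each site carries the true parameters the generator draws from: the
#' probability a sample contains the human marker (per stratum), the
#' lognormal concentration of the marker given contamination (copies per
#' 100 mL, parameterized on the log10 scale), a wet-weather concentration
#' multiplier, and the Enterococcus distribution with an optional coupling
#' to the marker signal (0 = independent, as when fecal indicator bacteria
#' come mostly from non-human sources).
#'
#' Unless given, the concentration scale is coupled to prevalence
#' (`log10_mean_conc = 1.8 + 2.2 * prevalence_dry`): sites with persistent
#' human fecal input tend to show higher concentrations as well, which is
#' what makes frequency- and concentration-based rankings agree.
#'
#' @param site_id Site identifiers.
#' @param prevalence_dry,prevalence_wet Per-sample contamination
#'   probabilities by stratum (wet defaults to
#'   `min(0.98, dry + 0.25)`, 1 stays 1: contamination expands in storms).
#' @param log10_mean_conc,log10_sd_conc Lognormal parameters of the marker
#'   concentration given contamination, log10 copies per 100 mL.
#' @param wet_multiplier Multiplier on the concentration in the wet stratum.
#' @param entero_log10_mean,entero_log10_sd Enterococcus lognormal
#'   parameters, log10 per 100 mL (dry stratum).
#' @param entero_wet_shift Added to `entero_log10_mean` in the wet stratum.
#' @param entero_coupling In `[0, 1]`; weight of the marker log-concentration
#'   anomaly added to the Enterococcus draw.
#' @param gauge_id Nearest rain gauge per site.
#' @return A tibble, one row per site.
#' @export
make_site_truth <- function(site_id,
                            prevalence_dry,
                            prevalence_wet = NULL,
                            log10_mean_conc = NULL,
                            log10_sd_conc = 0.5,
                            wet_multiplier = 3,
                            entero_log10_mean = 2.37,
                            entero_log10_sd = 1.0,
                            entero_wet_shift = 0.73,
                            entero_coupling = 0,
                            gauge_id = "G1") {
  n <- length(site_id)
  if (any(prevalence_dry < 0 | prevalence_dry > 1)) {
    abort("prevalences must be in [0, 1].")
  }
  if (is.null(prevalence_wet)) {
    prevalence_wet <- ifelse(prevalence_dry >= 1, 1,
                             pmin(0.98, prevalence_dry + 0.25))
  }
  if (is.null(log10_mean_conc)) {
    log10_mean_conc <- 1.8 + 2.2 * prevalence_dry
  }
  tibble::tibble(
    site_id = site_id,
    gauge_id = rep_len(gauge_id, n),
    prevalence_dry = rep_len(prevalence_dry, n),
    prevalence_wet = rep_len(prevalence_wet, n),
    log10_mean_conc = rep_len(log10_mean_conc, n),
    log10_sd_conc = rep_len(log10_sd_conc, n),
    wet_multiplier = rep_len(wet_multiplier, n),
    entero_log10_mean = rep_len(entero_log10_mean, n),
    entero_log10_sd = rep_len(entero_log10_sd, n),
    entero_wet_shift = rep_len(entero_wet_shift, n),
    entero_coupling = rep_len(entero_coupling, n)
  )
}

#' Configuration of a synthetic monitoring campaign
#'
#' @param site_truth Site-truth tibble ([make_site_truth()]).
#' @param samples_per_site_per_stratum Target sample count per site and
#'   stratum (default 50).
#' @param n_labs Number of laboratories; sites are assigned to labs
#'   round-robin.
#' @param lab_efficiency True per-lab amplification efficiencies (length
#'   `n_labs`); slopes are `-1 / log10(1 + E)`.
#' @param lab_intercept True per-lab intercepts, Cq at 1 copy/reaction.
#' @param cq_noise_sd Normal Cq measurement noise, cycles (default 0.3).
#' @param volumes A [volume_config()].
#' @param control_contamination_rate Probability an NTC/NEC reaction
#'   amplifies spuriously (Cq 37-40); default 0.002, of the order of the
#'   2-per-thousand rate seen in practice.
#' @param sketa22_mean,sketa22_sd Sample-processing control Cq distribution.
#' @param year Calendar year the campaign is laid out in.
#' @param storm_days Day-of-year storm dates (>= 14 days apart so every
#'   event has its antecedent dry spell); each storm deposits
#'   `storm_depth` inches in one day.
#' @param storm_depth Storm depth, inches.
#' @param seed Integer seed; a fixed seed makes the campaign byte-identical.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(site_truth,
                              samples_per_site_per_stratum = 50,
                              n_labs = 8,
                              lab_efficiency = seq(0.90, 0.98,
                                                   length.out = n_labs),
                              lab_intercept = seq(36.6, 37.4,
                                                  length.out = n_labs),
                              cq_noise_sd = 0.3,
                              volumes = volume_config(),
                              control_contamination_rate = 0.002,
                              sketa22_mean = 24, sketa22_sd = 0.3,
                              year = 2014,
                              storm_days = c(8, 22, 36, 50, 64, 78, 169,
                                             197, 309, 323, 337, 351),
                              storm_depth = 0.5,
                              seed = 1183) {
  stopifnot(is.data.frame(site_truth), nrow(site_truth) >= 1)
  if (length(lab_efficiency) != n_labs || length(lab_intercept) != n_labs) {
    abort("`lab_efficiency` and `lab_intercept` must have length `n_labs`.")
  }
  if (any(lab_efficiency <= 0)) abort("lab efficiencies must be positive.")
  if (samples_per_site_per_stratum < 1) abort("need at least 1 sample per stratum.")
  if (any(diff(sort(storm_days)) < 14)) {
    abort("storm days must be at least 14 days apart.")
  }
  structure(
    list(
      site_truth = tibble::as_tibble(site_truth),
      samples_per_site_per_stratum = samples_per_site_per_stratum,
      n_labs = n_labs,
      lab_id = sprintf("lab%02d", seq_len(n_labs)),
      lab_slope = -1 / log10(1 + lab_efficiency),
      lab_intercept = lab_intercept,
      lab_efficiency = lab_efficiency,
      cq_noise_sd = cq_noise_sd,
      volumes = volumes,
      control_contamination_rate = control_contamination_rate,
      sketa22_mean = sketa22_mean,
      sketa22_sd = sketa22_sd,
      year = year,
      storm_days = sort(storm_days),
      storm_depth = storm_depth,
      seed = seed
    ),
    class = "simulation_config"
  )
}

#' The default study-like scenario
#'
#' Twenty-two sites, fifty samples per site and stratum, eight laboratories.
#' Dry-weather prevalences span the full range: two sites at zero, fifteen
#' sites evenly spaced 0.10--0.34, four high sites (0.50--0.90) and one site
#' at 1 with a high concentration scale, reproducing the observed structure
#' of a mid-band of sites around 10--35% detection, a high band near
#' 50--100%, two sites never positive in dry weather and one always
#' positive.  Lab efficiencies are evenly spaced over 0.90--0.98.
#'
#' @param seed Integer seed (default 1183).
#' @param samples_per_site_per_stratum Default 50.
#' @return A `simulation_config`.
#' @export
default_study_like_scenario <- function(seed = 1183,
                                        samples_per_site_per_stratum = 50) {
  prevalence <- c(0, 0,
                  seq(0.10, 0.34, length.out = 15),
                  0.50, 0.65, 0.80, 0.90,
                  1.00)
  truth <- make_site_truth(
    site_id = sprintf("site%02d", seq_along(prevalence)),
    prevalence_dry = prevalence,
    entero_coupling = 0.2
  )
  simulation_config(
    truth,
    samples_per_site_per_stratum = samples_per_site_per_stratum,
    seed = seed
  )
}

#' Simulate a complete monitoring campaign
#'
#' Generates, under one seed: a daily rain series with planted storms; dry-
#' and wet-weather sample metadata (dry samples on in-season days clear of
#' any storm window, wet samples inside 72-h storm windows); and the qPCR
#' plates.  For each sample, contamination is Bernoulli(prevalence); given
#' contamination the concentration is lognormal (wet stratum scaled by the
#' wet multiplier); the expected copies per reaction are the concentration
#' divided by the volume conversion factor; each of the three replicate
#' reactions receives a Poisson copy number and amplifies exactly when at
#' least one copy is present, with
#' `Cq = intercept + slope * log10(copies) + Normal(0, cq_noise_sd)`.
#' Standards (10^0..10^5 copies, triplicate) amplify at their nominal copy
#' number: prepared dilution standards deliver their nominal template, which
#' is what makes >90% of 1-copy standards amplify in practice.  NTC/NEC
#' wells amplify only at the configured contamination rate.  Plates follow
#' the shared layout: 6 standards x 3 + 2 NEC x 3 + 1 NTC x 3 + up to 22
#' samples x 3 = up to 93 occupied wells.
#'
#' @param config A [simulation_config()].
#' @return A list: `plates` (well table), `metadata`, `rain`,
#'   `sample_truth`, `site_truth`, `config`.
#' @export
simulate_campaign <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_campaign_impl(config))
}

simulate_campaign_impl <- function(config) {
  truth <- config$site_truth
  n_sites <- nrow(truth)
  nss <- config$samples_per_site_per_stratum
  factor100 <- conversion_factor(config$volumes, 100)

  # --- rain: daily series per gauge, zeros except planted storms ----------
  days <- seq(as.Date(sprintf("%d-01-01", config$year)),
              as.Date(sprintf("%d-12-31", config$year)), by = "day")
  storm_dates <- days[config$storm_days]
  rain <- dplyr::bind_rows(lapply(unique(truth$gauge_id), function(g) {
    tibble::tibble(
      gauge_id = g,
      timestamp = as.POSIXct(paste(days, "00:00:00"), tz = "UTC"),
      depth_inches = ifelse(days %in% storm_dates, config$storm_depth, 0)
    )
  }))

  # candidate dry-sampling days: in season, > 6 days after any storm start
  season <- days[format(days, "%m-%d") >= "04-01" &
                 format(days, "%m-%d") <= "10-31"]
  near_storm <- unlist(lapply(storm_dates, function(s) as.character(s + 0:6)))
  dry_days_pool <- season[!as.character(season) %in% near_storm]

  # --- samples ------------------------------------------------------------
  lab_of_site <- config$lab_id[(seq_len(n_sites) - 1) %% config$n_labs + 1]
  meta_list <- vector("list", 2 * n_sites)
  truth_list <- vector("list", 2 * n_sites)
  idx <- 0
  for (i in seq_len(n_sites)) {
    for (stratum in c("DRY", "WET")) {
      idx <- idx + 1
      prev <- if (stratum == "DRY") truth$prevalence_dry[i] else
        truth$prevalence_wet[i]
      if (stratum == "DRY") {
        sdays <- sort(sample(dry_days_pool, nss, replace = nss > length(dry_days_pool)))
        ts <- as.POSIXct(paste(sdays, "08:00:00"), tz = "UTC")
      } else {
        ev <- sample(storm_dates, nss, replace = TRUE)
        offs_h <- runif(nss, 6, 66)
        ts <- sort(as.POSIXct(paste(ev, "00:00:00"), tz = "UTC") +
                     round(offs_h * 3600))
      }
      contaminated <- runif(nss) < prev
      lmean <- truth$log10_mean_conc[i] +
        if (stratum == "WET") log10(truth$wet_multiplier[i]) else 0
      conc <- ifelse(
        contaminated,
        10^rnorm(nss, lmean, truth$log10_sd_conc[i]),
        0
      )
      e_mean <- truth$entero_log10_mean[i] +
        if (stratum == "WET") truth$entero_wet_shift[i] else 0
      e_log10 <- rnorm(nss, e_mean, truth$entero_log10_sd[i]) +
        truth$entero_coupling[i] *
          ifelse(contaminated, log10(pmax(conc, 1)) - truth$log10_mean_conc[i],
                 -1)
      sample_id <- sprintf("%s-%s-%03d", truth$site_id[i],
                           tolower(stratum), seq_len(nss))
      meta_list[[idx]] <- tibble::tibble(
        sample_id = sample_id,
        site_id = truth$site_id[i],
        timestamp = ts,
        volume_filtered_ml = 100,
        enterococcus_per_100ml = round(10^e_log10, 1),
        gauge_id = truth$gauge_id[i],
        sketa22_cq = round(rnorm(nss, config$sketa22_mean,
                                 config$sketa22_sd), 2),
        lab_id = lab_of_site[i]
      )
      truth_list[[idx]] <- tibble::tibble(
        sample_id = sample_id,
        stratum = stratum,
        contaminated = contaminated,
        true_conc_per_100ml = conc,
        true_mean_copies_per_reaction = conc / factor100
      )
    }
  }
  metadata <- dplyr::bind_rows(meta_list)
  sample_truth <- dplyr::bind_rows(truth_list)

  # --- plates -------------------------------------------------------------
  plates <- dplyr::bind_rows(lapply(config$lab_id, function(lab) {
    ids <- metadata$sample_id[metadata$lab_id == lab]
    if (length(ids) == 0) return(NULL)
    chunks <- split(ids, ceiling(seq_along(ids) / 22))
    lab_i <- match(lab, config$lab_id)
    dplyr::bind_rows(lapply(seq_along(chunks), function(p) {
      simulate_plate(
        plate_id = sprintf("%s-p%03d", lab, p),
        lab_id = lab,
        sample_ids = chunks[[p]],
        mu = sample_truth$true_mean_copies_per_reaction[
          match(chunks[[p]], sample_truth$sample_id)],
        slope = config$lab_slope[lab_i],
        intercept = config$lab_intercept[lab_i],
        cq_noise_sd = config$cq_noise_sd,
        control_contamination_rate = config$control_contamination_rate
      )
    }))
  }))

  metadata$lab_id <- NULL
  list(
    plates = validate_plate_wells(plates),
    metadata = metadata,
    rain = rain,
    sample_truth = sample_truth,
    site_truth = truth,
    config = config
  )
}

# one 96-well plate: 18 standard + 6 NEC + 3 NTC + 3 * n_samples wells
simulate_plate <- function(plate_id, lab_id, sample_ids, mu,
                           slope, intercept, cq_noise_sd,
                           control_contamination_rate) {
  positions <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8))
  std_copies <- rep(10^(0:5), each = 3)
  n_s <- length(sample_ids)

  std_cq <- intercept + slope * log10(std_copies) +
    rnorm(length(std_copies), 0, cq_noise_sd)

  n_ctrl <- 9  # 2 NEC x 3 + 1 NTC x 3
  ctrl_amp <- runif(n_ctrl) < control_contamination_rate
  ctrl_cq <- ifelse(ctrl_amp, runif(n_ctrl, 37, 40), NA_real_)

  rep_mu <- rep(mu, each = 3)
  copies <- rpois(3 * n_s, rep_mu)
  samp_cq <- ifelse(
    copies >= 1,
    intercept + slope * log10(pmax(copies, 1)) +
      rnorm(3 * n_s, 0, cq_noise_sd),
    NA_real_
  )

  n_wells <- 18 + n_ctrl + 3 * n_s
  tibble::tibble(
    plate_id = plate_id,
    lab_id = lab_id,
    well = positions[seq_len(n_wells)],
    role = c(rep("STANDARD", 18), rep("NEC", 6), rep("NTC", 3),
             rep("SAMPLE", 3 * n_s)),
    target = "HF183",
    sample_id = c(rep(NA_character_, 18 + n_ctrl), rep(sample_ids, each = 3)),
    standard_copies = c(std_copies, rep(NA_real_, n_ctrl + 3 * n_s)),
    cq = round(c(std_cq, ctrl_cq, samp_cq), 3)
  )
}

#' Simulate pooled standard points for calibration studies
#'
#' @param n_plates Number of plates, each contributing one 6-point
#'   triplicate curve (10^0..10^5 copies/reaction).
#' @param slope,intercept True curve parameters.
#' @param cq_noise_sd Cq noise, cycles.
#' @return A tibble with `plate`, `log10_copies`, `cq`.
#' @export
simulate_standards <- function(n_plates, slope = -3.5, intercept = 37,
                               cq_noise_sd = 0.2) {
  lg <- rep(rep(0:5, each = 3), n_plates)
  tibble::tibble(
    plate = rep(seq_len(n_plates), each = 18),
    log10_copies = lg,
    cq = intercept + slope * lg + rnorm(length(lg), 0, cq_noise_sd)
  )
}

#' Write a simulated campaign to a directory
#'
#' Emits `plates.csv`, `metadata.csv`, `rain.csv`, the truth tables and a
#' `manifest.json` recording the configuration and seed.
#'
#' @param campaign A list from [simulate_campaign()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_plate_table(campaign$plates, file.path(dir, "plates.csv"))
  write_sample_metadata(campaign$metadata, file.path(dir, "metadata.csv"))
  readr::write_csv(campaign$rain, file.path(dir, "rain.csv"), progress = FALSE)
  readr::write_csv(campaign$site_truth, file.path(dir, "site_truth.csv"),
                   progress = FALSE)
  readr::write_csv(campaign$sample_truth, file.path(dir, "sample_truth.csv"),
                   progress = FALSE)
  cfg <- campaign$config
  manifest <- list(
    seed = cfg$seed,
    n_sites = nrow(cfg$site_truth),
    samples_per_site_per_stratum = cfg$samples_per_site_per_stratum,
    n_labs = cfg$n_labs,
    lab_efficiency = cfg$lab_efficiency,
    cq_noise_sd = cfg$cq_noise_sd,
    elution_volume_ul = cfg$volumes$elution_volume_ul,
    template_volume_ul = cfg$volumes$template_volume_ul
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
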