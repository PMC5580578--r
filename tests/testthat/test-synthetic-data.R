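test_that("zero prevalence and zero contamination give an all-negative campaign", {
  cfg <- simulation_config(
    make_site_truth(c("s1", "s2"), prevalence_dry = c(0, 0),
                    prevalence_wet = c(0, 0)),
    samples_per_site_per_stratum = 10, n_labs = 1,
    lab_efficiency = 0.95, lab_intercept = 37,
    control_contamination_rate = 0, seed = 3
  )
  camp <- simulate_campaign(cfg)
  sample_cq <- camp$plates$cq[camp$plates$role == "SAMPLE"]
  expect_true(all(is.na(sample_cq)))
  res <- run_campaign_analysis(camp$plates, camp$metadata, camp$rain,
                               min_n = 1)
  expect_true(all(res$summaries$freq_amp1 == 0))
})

test_that("the all-ND fraction at one mean copy per reaction is e^-3", {
  # mu = 1 copy/reaction for every sample: a replicate is ND with
  # probability e^-1, a sample all-ND with probability e^-3
  factor <- conversion_factor(volume_config(), 100)
  cfg <- simulation_config(
    make_site_truth("s1", prevalence_dry = 1, prevalence_wet = 1,
                    log10_mean_conc = log10(factor), log10_sd_conc = 0,
                    wet_multiplier = 1),
    samples_per_site_per_stratum = 1000, n_labs = 1,
    lab_efficiency = 0.95, lab_intercept = 37, seed = 13
  )
  camp <- simulate_campaign(cfg)
  wells <- camp$plates[camp$plates$role == "SAMPLE", ]
  all_nd <- tapply(is.na(wells$cq), wells$sample_id, all)
  p_hat <- mean(all_nd)          # 2000 samples across both strata
  p <- exp(-3)
  se <- sqrt(p * (1 - p) / length(all_nd))
  expect_lt(abs(p_hat - p), 3 * se)
})

test_that("the same seed reproduces byte-identical campaign files", {
  cfg <- simulation_config(
    make_site_truth(c("s1", "s2"), prevalence_dry = c(0.2, 0.9)),
    samples_per_site_per_stratum = 8, n_labs = 2,
    lab_efficiency = c(0.92, 0.96), lab_intercept = c(36.8, 37.2),
    seed = 17
  )
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_campaign(simulate_campaign(cfg), d1)
  write_campaign(simulate_campaign(cfg), d2)
  for (f in c("plates.csv", "metadata.csv", "rain.csv", "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # and a different seed does not
  cfg2 <- simulation_config(cfg$site_truth, samples_per_site_per_stratum = 8,
                            n_labs = 2, lab_efficiency = c(0.92, 0.96),
                            lab_intercept = c(36.8, 37.2), seed = 18)
  d3 <- withr::local_tempdir()
  write_campaign(simulate_campaign(cfg2), d3)
  expect_false(identical(readLines(file.path(d1, "plates.csv")),
                         readLines(file.path(d3, "plates.csv"))))
})

test_that("estimated site frequencies converge to the analytic detection probability", {
  factor <- conversion_factor(volume_config(), 100)
  prev <- c(0.25, 0.7)
  mu <- 2                         # fixed mean copies per reaction
  cfg <- simulation_config(
    make_site_truth(c("s1", "s2"), prevalence_dry = prev,
                    prevalence_wet = prev,
                    log10_mean_conc = log10(mu * factor), log10_sd_conc = 0,
                    wet_multiplier = 1),
    samples_per_site_per_stratum = 1000, n_labs = 1,
    lab_efficiency = 0.95, lab_intercept = 37, seed = 23
  )
  camp <- simulate_campaign(cfg)
  wells <- camp$plates[camp$plates$role == "SAMPLE", ]
  wells$site_id <- sub("-(dry|wet)-\\d+$", "", wells$sample_id)
  p_pos <- prev * (1 - exp(-3 * mu))    # P(contaminated and >= 1 rep amplifies)
  for (i in 1:2) {
    sw <- wells[wells$site_id == paste0("s", i), ]
    amp1 <- tapply(!is.na(sw$cq), sw$sample_id, any)
    se <- sqrt(p_pos[i] * (1 - p_pos[i]) / length(amp1))
    expect_lt(abs(mean(amp1) - p_pos[i]), 3 * se)
  }
})

test_that("quantified concentrations are unbiased in log10 for quantifiable samples", {
  factor <- conversion_factor(volume_config(), 100)
  true_conc <- 100 * factor       # 100 copies/reaction, comfortably > LLOQ
  cfg <- simulation_config(
    make_site_truth("s1", prevalence_dry = 1, prevalence_wet = 1,
                    log10_mean_conc = log10(true_conc), log10_sd_conc = 0,
                    wet_multiplier = 1),
    samples_per_site_per_stratum = 200, n_labs = 1,
    lab_efficiency = 0.95, lab_intercept = 37, seed = 29
  )
  camp <- simulate_campaign(cfg)
  curves <- calibrate_labs(camp$plates)
  reps <- quantify_samples(camp$plates, camp$metadata, curves,
                           volume_config())
  q <- reps[reps$censor_class == "QUANT", ]
  err <- log10(q$conc_per_100ml) - log10(true_conc)
  se <- sd(err) / sqrt(nrow(q))
  expect_lt(abs(mean(err)), 3 * se)
})

test_that("the default scenario has the documented structure", {
  cfg <- default_study_like_scenario()
  truth <- cfg$site_truth
  expect_equal(nrow(truth), 22)
  expect_equal(cfg$samples_per_site_per_stratum, 50)
  expect_equal(cfg$n_labs, 8)
  expect_equal(sum(truth$prevalence_dry == 0), 2)
  expect_equal(sum(truth$prevalence_dry == 1), 1)
  expect_true(all(cfg$lab_efficiency >= 0.90 & cfg$lab_efficiency <= 0.98))
  # every gauge sees at least one qualifying wet event by construction
  camp <- simulate_campaign(
    simulation_config(truth[1:2, ], samples_per_site_per_stratum = 2,
                      n_labs = 1, lab_efficiency = 0.95,
                      lab_intercept = 37, seed = 37)
  )
  ev <- detect_wet_events(camp$rain)
  expect_gte(nrow(ev), 1)
  expect_setequal(unique(camp$rain$gauge_id), unique(ev$gauge_id))
})
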