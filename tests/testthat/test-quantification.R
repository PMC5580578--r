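curve <- make_test_curve()  # slope -3.5, intercept 37, limits at 1 and 10

test_that("Cq inverts to copies along the curve", {
  expect_equal(cq_to_copies(37, curve), 1)
  expect_equal(cq_to_copies(33.5, curve), 10)
  expect_equal(cq_to_copies(30, curve), 100)
  expect_error(cq_to_copies(NA_real_, curve), "finite")
})

test_that("replicates are classified on the censoring ladder", {
  expect_equal(classify_replicate(NA_real_, curve), "ND")
  cq_of <- function(copies) 37 - 3.5 * log10(copies)
  # brute-force comparison against the copy thresholds
  for (copies in c(0.2, 0.5, 0.99, 1, 2, 5, 9.9, 10, 50, 1e4)) {
    expected <- if (copies < 1) "DBLOD" else if (copies < 10) "DNQ" else "QUANT"
    expect_equal(classify_replicate(cq_of(copies), curve), expected)
  }
  # the LLOQ boundary is closed on the quantifiable side
  expect_equal(classify_replicate(33.5, curve), "QUANT")
  # classify(cq_to_copies inverse) round-trips on noise-free data
  for (cq in c(37, 33.5, 30, 25)) {
    expect_equal(cq_to_copies(37 - 3.5 * log10(cq_to_copies(cq, curve)),
                              curve),
                 cq_to_copies(cq, curve), tolerance = 1e-12)
  }
})

test_that("volume conversion scales with filtered volume", {
  vol <- volume_config(elution_volume_ul = 100, template_volume_ul = 2)
  expect_equal(copies_to_conc(1, 100, vol), 50)
  expect_equal(copies_to_conc(1, 50, vol), 100)
  expect_error(copies_to_conc(1, 0, vol), "positive")
  # the default composite factor reproduces the 1 -> 79, 10 -> 789 mapping
  expect_equal(round(copies_to_conc(c(1, 10), 100, volume_config())),
               c(79, 789))
})

test_that("MPN MLE matches grid-search likelihood maximization", {
  for (n in 1:5) {
    for (k in seq_len(n - 1)) {
      expect_lt(abs(estimate_lambda(n, k, "mpn_mle") - grid_mpn(n, k)), 1e-4)
    }
  }
  expect_equal(estimate_lambda(3, 2, "mpn_mle"), log(3), tolerance = 1e-9)
  expect_equal(estimate_lambda(3, 0, "mpn_mle"), 0)
  expect_error(estimate_lambda(3, 3, "mpn_mle"), "all replicates")
})

test_that("Bayes posterior mean matches the closed form and is well behaved", {
  expect_equal(estimate_lambda(3, 0, "bayes_posterior_mean", 1),
               0.2809, tolerance = 1e-3)
  for (n in 1:5) {
    for (k in 0:n) {
      for (upper in c(1, 10)) {
        est <- estimate_lambda(n, k, "bayes_posterior_mean", upper)
        expect_equal(est, bayes_closed_form(n, k, upper), tolerance = 1e-6)
        expect_gt(est, 0)
        expect_lt(est, upper)
      }
    }
    # monotone in k at fixed n
    ests <- vapply(0:n, estimate_lambda, numeric(1), n = n,
                   method = "bayes_posterior_mean", prior_upper = 10)
    expect_true(all(diff(ests) > 0))
  }
})

test_that("quantifiable replicates pass through substitution unchanged", {
  cq100 <- 37 - 3.5 * 2
  res <- substitute_censored(rep(cq100, 3), curve, 100, volume_config())
  expect_equal(res$censor_class, rep("QUANT", 3))
  expect_equal(res$copies_per_reaction, rep(100, 3), tolerance = 1e-9)
})

test_that("the Poisson scheme substitutes conditional and unconditional means", {
  vol <- volume_config()
  # one DBLOD (0.5 copies), two ND: lambda from the Bayes pattern estimate
  cq_dblod <- 37 - 3.5 * log10(0.5)
  res <- substitute_censored(c(NA, NA, cq_dblod), curve, 100, vol)
  lambda <- estimate_lambda(3, 1, "bayes_posterior_mean", 10)
  expect_equal(res$copies_per_reaction[1:2], rep(lambda, 2), tolerance = 1e-9)
  expect_equal(res$copies_per_reaction[3], lambda / (1 - exp(-lambda)),
               tolerance = 1e-9)
  # DBLOD substitute >= 1 >= ND substitute; both below the LLOQ
  expect_gte(res$copies_per_reaction[3], 1)
  expect_gte(res$copies_per_reaction[3], res$copies_per_reaction[1])
  expect_true(all(res$copies_per_reaction < 10))
  expect_true(all(res$conc_per_100ml > 0))

  # with a measurable replicate, lambda is that replicate's copy number
  cq5 <- 37 - 3.5 * log10(5)
  res2 <- substitute_censored(c(NA, cq5, NA), curve, 100, vol)
  expect_equal(res2$copies_per_reaction[c(1, 3)], c(5, 5), tolerance = 1e-9)

  # conditional-mean identity at a reference value (computed directly)
  expect_equal(0.4055 / (1 - exp(-0.4055)), 1.216420, tolerance = 1e-5)
})

test_that("conditional-mean substitute matches a Monte-Carlo oracle", {
  lambda <- estimate_lambda(3, 1, "bayes_posterior_mean", 10)
  set.seed(41)
  draws <- rpois(3e5, lambda)
  draws <- draws[draws >= 1][1:1e5]
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - lambda / (1 - exp(-lambda))), 3 * se)
})

test_that("the half-LOD scheme substitutes half and one LOD", {
  cq_dblod <- 37 - 3.5 * log10(0.5)
  res <- substitute_censored(c(NA, NA, cq_dblod), curve, 100,
                             volume_config(), scheme = "half_lod")
  expect_equal(res$copies_per_reaction, c(0.5, 0.5, 1))
})

test_that("quantify_samples joins wells, curves and metadata", {
  plate <- fixture_plate(sample_cq = 30)
  meta <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:22),
    site_id = rep(c("A", "B"), each = 11),
    timestamp = as.POSIXct("2014-06-01 08:00:00", tz = "UTC"),
    volume_filtered_ml = 100,
    enterococcus_per_100ml = 200,
    gauge_id = "G1"
  )
  curves <- calibrate_labs(plate)
  reps <- quantify_samples(plate, meta, curves, volume_config())
  expect_equal(nrow(reps), 66)
  expect_true(all(reps$censor_class == "QUANT"))
  expect_equal(unique(reps$copies_per_reaction), 100, tolerance = 1e-6)
  expect_error(
    quantify_samples(plate, meta, curves["nolab"], volume_config()),
    "no master curve"
  )
})
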