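#' The seven positivity definitions
#'
#' `AMP1`/`AMP2`/`AMP3`: at least 1, 2 or all 3 of the triplicate reactions
#' amplified (any Cq).  `DET1`/`DET2`/`DET3`: at least 1, 2 or 3 replicates
#' detected at or above the LOD (class `DNQ` or `QUANT`; below-LOD
#' amplifications do not count).  `MEANGT_LOD`: the sample geometric-mean
#' concentration, with non-detects set to half the LOD and below-LOD
#' detections to the LOD, exceeds the LOD in copies per 100 mL.
#'
#' @format Character vector of the seven definition codes.
#' @export
POSITIVITY_DEFINITIONS <- c("AMP1", "AMP2", "AMP3",
                            "DET1", "DET2", "DET3", "MEANGT_LOD")

#' Is a sample positive for the marker under a given definition?
#'
#' @param censor_class Length-3 character vector of replicate censor classes
#'   (see [classify_replicate()]).
#' @param copies_per_reaction Measured copies per reaction for `DNQ`/`QUANT`
#'   replicates (values for censored replicates are ignored; only used by
#'   `MEANGT_LOD`).
#' @param definition One of [POSITIVITY_DEFINITIONS].
#' @param lod_copies LOD in copies per reaction (default 1).
#' @param volume_filtered_ml,volumes Volume context for the `MEANGT_LOD`
#'   comparison, made in copies per 100 mL (the comparison is invariant to
#'   the conversion factor, which scales both sides).
#' @return `TRUE` or `FALSE`.
#' @export
sample_positive <- function(censor_class, copies_per_reaction = NULL,
                            definition = "AMP1", lod_copies = 1,
                            volume_filtered_ml = 100,
                            volumes = volume_config()) {
  definition <- match.arg(definition, POSITIVITY_DEFINITIONS)
  n_amp <- sum(censor_class != "ND")
  n_det <- sum(censor_class %in% c("DNQ", "QUANT"))
  switch(definition,
    AMP1 = n_amp >= 1, AMP2 = n_amp >= 2, AMP3 = n_amp >= 3,
    DET1 = n_det >= 1, DET2 = n_det >= 2, DET3 = n_det >= 3,
    MEANGT_LOD = {
      if (is.null(copies_per_reaction)) {
        abort("MEANGT_LOD needs `copies_per_reaction`.")
      }
      copies <- ifelse(censor_class == "ND", 0.5 * lod_copies,
                ifelse(censor_class == "DBLOD", lod_copies,
                       copies_per_reaction))
      conc <- copies_to_conc(copies, volume_filtered_ml, volumes)
      lod_conc <- copies_to_conc(lod_copies, volume_filtered_ml, volumes)
      10^mean(log10(conc)) > lod_conc
    }
  )
}

#' Percentage of positive samples
#'
#' @param positive Logical vector, one element per sample.
#' @return `100 * positives / n`.
#' @export
site_frequency <- function(positive) {
  if (length(positive) == 0) abort("no samples: frequency undefined.")
  100 * mean(positive)
}

#' Site geometric-mean marker concentration
#'
#' The arithmetic mean at the log10 scale, back-transformed: all replicate
#' concentrations from all samples at the site are pooled, after censored
#' replicates have been substituted (so every value is strictly positive).
#'
#' @param conc_per_100ml Pooled replicate concentrations, copies per 100 mL.
#' @return Geometric mean, copies per 100 mL.
#' @export
site_geomean_hf183 <- function(conc_per_100ml) {
  if (any(is.na(conc_per_100ml)) || any(conc_per_100ml <= 0)) {
    abort("all concentrations must be positive: substitute censored replicates first.")
  }
  10^mean(log10(conc_per_100ml))
}

#' Enterococcus exceedance and geometric-mean metrics
#'
#' Exceedance is judged against the California Ocean Plan single sample
#' maximum (SSM, 104 per 100 mL) and against 100 times the SSM.  Samples
#' without an Enterococcus measurement are dropped from the denominators.
#' Zero counts are floored at 1 per 100 mL for the geometric mean.
#'
#' @param counts Enterococcus per 100 mL (CFU and MPN pooled); `NA` = not
#'   measured.
#' @param ssm Single sample maximum (default 104).
#' @param fold High-exceedance multiplier (default 100).
#' @return A list: `exceed_pct`, `exceed_100x_pct`, `geomean`, `n`.
#' @export
entero_metrics <- function(counts, ssm = 104, fold = 100) {
  counts <- counts[!is.na(counts)]
  if (length(counts) == 0) abort("no Enterococcus measurements.")
  if (any(counts < 0)) abort("Enterococcus counts must be non-negative.")
  list(
    exceed_pct = 100 * mean(counts > ssm),
    exceed_100x_pct = 100 * mean(counts > ssm * fold),
    geomean = 10^mean(log10(pmax(counts, 1))),
    n = length(counts)
  )
}

#' Per-site, per-stratum summary metrics
#'
#' For every site and weather stratum (`DRY`, `WET`; excluded samples are
#' dropped) computes the detection frequency under all seven positivity
#' definitions, the pooled geometric-mean marker concentration under the
#' chosen substitution scheme, and the Enterococcus metrics.
#'
#' @param replicates Replicate-level table from [quantify_samples()].
#' @param metadata Sample metadata with a `weather` column (see
#'   [assign_weather()]) and `enterococcus_per_100ml`.
#' @param volumes A [volume_config()].
#' @param lod_copies LOD in copies per reaction (default 1).
#' @return A wide tibble, one row per site x stratum: `n_samples`, the seven
#'   `freq_*` percentages, `geomean_hf183`, and `entero_*` metrics (`NA` when
#'   no sample of the cell was measured for Enterococcus).
#' @export
summarize_sites <- function(replicates, metadata, volumes = volume_config(),
                            lod_copies = 1) {
  meta_cols <- c("sample_id", "timestamp", "volume_filtered_ml",
                 "enterococcus_per_100ml", "weather")
  if (!"weather" %in% names(metadata)) {
    abort("metadata lacks a `weather` column; run assign_weather() first.")
  }
  d <- dplyr::inner_join(replicates,
                         metadata[, intersect(meta_cols, names(metadata))],
                         by = "sample_id")
  d <- d[d$weather %in% c("DRY", "WET"), ]
  if (nrow(d) == 0) abort("no DRY or WET samples to summarize.")

  per_sample <- d |>
    dplyr::group_by(.data$site_id, .data$weather, .data$sample_id) |>
    dplyr::summarise(
      n_amp = sum(.data$censor_class != "ND"),
      n_det = sum(.data$censor_class %in% c("DNQ", "QUANT")),
      meangt = sample_positive(
        .data$censor_class, .data$copies_per_reaction, "MEANGT_LOD",
        lod_copies = lod_copies,
        volume_filtered_ml = .data$volume_filtered_ml[1], volumes = volumes
      ),
      entero = .data$enterococcus_per_100ml[1],
      .groups = "drop"
    )

  cells <- split(per_sample,
                 list(per_sample$site_id, per_sample$weather), drop = TRUE)
  rows <- lapply(cells, function(s) {
    reps <- d[d$site_id == s$site_id[1] & d$weather == s$weather[1], ]
    em <- if (all(is.na(s$entero))) {
      list(exceed_pct = NA_real_, exceed_100x_pct = NA_real_,
           geomean = NA_real_, n = 0L)
    } else {
      entero_metrics(s$entero)
    }
    tibble::tibble(
      site_id = s$site_id[1],
      stratum = s$weather[1],
      n_samples = nrow(s),
      freq_amp1 = site_frequency(s$n_amp >= 1),
      freq_amp2 = site_frequency(s$n_amp >= 2),
      freq_amp3 = site_frequency(s$n_amp >= 3),
      freq_det1 = site_frequency(s$n_det >= 1),
      freq_det2 = site_frequency(s$n_det >= 2),
      freq_det3 = site_frequency(s$n_det >= 3),
      freq_meangt_lod = site_frequency(s$meangt),
      geomean_hf183 = site_geomean_hf183(reps$conc_per_100ml),
      entero_exceed_pct = em$exceed_pct,
      entero_exceed_100x_pct = em$exceed_100x_pct,
      entero_geomean = em$geomean,
      entero_n = em$n
    )
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$stratum, out$site_id), ]
}
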