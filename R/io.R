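WELL_ROLES <- c("STANDARD", "SAMPLE", "NTC", "NEC")
WELL_TARGETS <- c("HF183", "SKETA22")

# readr column specs kept in one place so reader and writer stay in step
plate_cols <- function() {
  readr::cols(
    plate_id = readr::col_character(),
    lab_id = readr::col_character(),
    well = readr::col_character(),
    role = readr::col_character(),
    target = readr::col_character(),
    sample_id = readr::col_character(),
    standard_copies = readr::col_double(),
    cq = readr::col_double()
  )
}

#' Read a qPCR plate table
#'
#' One row per occupied well.  Columns: `plate_id`, `lab_id`, `well`
#' (A1--H12), `role` (`STANDARD`, `SAMPLE`, `NTC`, `NEC`), `target`
#' (`HF183` or `SKETA22`), `sample_id` (SAMPLE wells only),
#' `standard_copies` (STANDARD wells only, a power of ten between 1 and
#' 10^6 copies/reaction) and `cq`.  An empty `cq` cell means the reaction
#' did not amplify.
#'
#' @param path Path to the plate CSV.
#' @return A validated tibble of plate wells.
#' @export
read_plate_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  wells <- readr::read_csv(path, col_types = plate_cols(),
                           na = c("", "NA"), progress = FALSE)
  validate_plate_wells(wells)
}

#' Validate a plate-well table against the data-model invariants
#'
#' @param wells A data frame of plate wells.
#' @return The table as a tibble, invisibly unchanged, or an error naming the
#'   offending well.
#' @export
validate_plate_wells <- function(wells) {
  wells <- tibble::as_tibble(wells)
  required <- c("plate_id", "lab_id", "well", "role", "target",
                "sample_id", "standard_copies", "cq")
  missing <- setdiff(required, names(wells))
  if (length(missing) > 0) {
    abort(paste0("plate table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(wells) == 0) return(wells)

  bad_well <- !grepl("^[A-H](1[0-2]|[1-9])$", wells$well)
  if (any(bad_well)) {
    abort(paste0("invalid well position(s): ",
                 paste(unique(wells$well[bad_well]), collapse = ", ")))
  }
  key <- paste(wells$plate_id, wells$target, wells$well)
  if (anyDuplicated(key)) {
    dup <- wells$well[duplicated(key)][1]
    abort(sprintf("duplicate well %s on plate %s.", dup,
                  wells$plate_id[duplicated(key)][1]))
  }
  if (!all(wells$role %in% WELL_ROLES)) {
    abort("well role must be one of STANDARD, SAMPLE, NTC, NEC.")
  }
  if (!all(wells$target %in% WELL_TARGETS)) {
    abort("well target must be HF183 or SKETA22.")
  }
  bad_cq <- !is.na(wells$cq) & (wells$cq <= 0 | wells$cq > 45)
  if (any(bad_cq)) {
    i <- which(bad_cq)[1]
    abort(sprintf("malformed Cq %.3f in well %s of plate %s (must be in (0, 45]).",
                  wells$cq[i], wells$well[i], wells$plate_id[i]))
  }
  std <- wells$role == "STANDARD"
  if (any(std)) {
    sc <- wells$standard_copies[std]
    ok <- !is.na(sc) & sc %in% 10^(0:6)
    if (!all(ok)) {
      i <- which(std)[which(!ok)[1]]
      abort(sprintf("standard well %s has invalid standard_copies (%s).",
                    wells$well[i], format(wells$standard_copies[i])))
    }
  }
  ctrl <- wells$role %in% c("NTC", "NEC")
  if (any(ctrl & !is.na(wells$sample_id))) {
    i <- which(ctrl & !is.na(wells$sample_id))[1]
    abort(sprintf("control well %s must not carry a sample_id.", wells$well[i]))
  }
  smp <- wells$role == "SAMPLE"
  if (any(smp & is.na(wells$sample_id))) {
    i <- which(smp & is.na(wells$sample_id))[1]
    abort(sprintf("sample well %s lacks a sample_id.", wells$well[i]))
  }
  wells
}

#' Write a plate-well table
#' @param wells Validated plate-well table.
#' @param path Output CSV path.
#' @export
write_plate_table <- function(wells, path) {
  readr::write_csv(validate_plate_wells(wells), path, na = "", progress = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Columns: `sample_id`, `site_id`, `timestamp` (ISO 8601, timezone-naive
#' local time), `volume_filtered_ml` (defaults to 100 when empty),
#' `enterococcus_per_100ml` (CFU and MPN pooled without conversion; empty =
#' not measured), `gauge_id` (nearest rain gauge), and optionally
#' `sketa22_cq` (sample-processing control) and `weather`.
#'
#' @param path Path to the metadata CSV.
#' @return A tibble, one row per water sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  meta <- readr::read_csv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      site_id = readr::col_character(),
      timestamp = readr::col_datetime(format = ""),
      volume_filtered_ml = readr::col_double(),
      enterococcus_per_100ml = readr::col_double(),
      gauge_id = readr::col_character(),
      .default = readr::col_guess()
    ),
    na = c("", "NA"), progress = FALSE
  )
  if (anyDuplicated(meta$sample_id)) {
    abort(sprintf("duplicate sample_id: %s",
                  meta$sample_id[duplicated(meta$sample_id)][1]))
  }
  meta$volume_filtered_ml[is.na(meta$volume_filtered_ml)] <- 100
  bad <- meta$volume_filtered_ml <= 0 | meta$volume_filtered_ml > 100
  if (any(bad)) {
    abort(sprintf("sample %s: volume_filtered_ml must be in (0, 100].",
                  meta$sample_id[bad][1]))
  }
  if (any(!is.na(meta$enterococcus_per_100ml) & meta$enterococcus_per_100ml < 0)) {
    abort("enterococcus_per_100ml must be non-negative.")
  }
  meta
}

#' Write sample metadata
#' @param metadata Metadata tibble.
#' @param path Output CSV path.
#' @export
write_sample_metadata <- function(metadata, path) {
  readr::write_csv(metadata, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a rain-gauge depth series
#'
#' Columns: `gauge_id`, `timestamp`, `depth_inches` (>= 0).  Timestamps must
#' be strictly increasing within each gauge; gaps are allowed.
#'
#' @param path Path to the rain CSV.
#' @return A tibble grouped-ready by gauge.
#' @export
read_rain_series <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  rain <- readr::read_csv(
    path,
    col_types = readr::cols(
      gauge_id = readr::col_character(),
      timestamp = readr::col_datetime(format = ""),
      depth_inches = readr::col_double()
    ),
    na = c("", "NA"), progress = FALSE
  )
  validate_rain_series(rain)
}

#' Validate a rain series
#' @param rain A data frame with `gauge_id`, `timestamp`, `depth_inches`.
#' @return The validated tibble.
#' @export
validate_rain_series <- function(rain) {
  rain <- tibble::as_tibble(rain)
  if (any(is.na(rain$depth_inches)) || any(rain$depth_inches < 0)) {
    abort("rain depths must be non-negative and present.")
  }
  for (g in unique(rain$gauge_id)) {
    ts <- rain$timestamp[rain$gauge_id == g]
    if (is.unsorted(ts, strictly = TRUE)) {
      abort(sprintf("timestamps for gauge %s are not strictly increasing.", g))
    }
  }
  rain
}

# metric columns of a wide site-summary table, in canonical order
SUMMARY_METRICS <- c(
  "freq_amp1", "freq_amp2", "freq_amp3",
  "freq_det1", "freq_det2", "freq_det3", "freq_meangt_lod",
  "geomean_hf183",
  "entero_exceed_pct", "entero_exceed_100x_pct", "entero_geomean", "entero_n"
)

#' Write site summaries as a tidy CSV
#'
#' One row per site x stratum x metric, numeric values at 6 significant
#' digits (a write/read round trip reproduces values at that precision).
#'
#' @param summaries Wide site-summary tibble from [summarize_sites()].
#' @param path Output CSV path.
#' @export
write_site_summaries <- function(summaries, path) {
  cols <- intersect(SUMMARY_METRICS, names(summaries))
  long <- tidyr::pivot_longer(
    summaries,
    cols = dplyr::all_of(cols),
    names_to = "metric", values_to = "value"
  )
  long <- long[, c("site_id", "stratum", "n_samples", "metric", "value")]
  long$value <- signif(long$value, 6)
  readr::write_csv(long, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read site summaries written by [write_site_summaries()]
#' @param path Path to the tidy summary CSV.
#' @return The wide site-summary tibble.
#' @export
read_site_summaries <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  long <- readr::read_csv(
    path,
    col_types = readr::cols(
      site_id = readr::col_character(),
      stratum = readr::col_character(),
      n_samples = readr::col_integer(),
      metric = readr::col_character(),
      value = readr::col_double()
    ),
    na = c("", "NA"), progress = FALSE
  )
  if (nrow(long) == 0) return(long)
  tidyr::pivot_wider(long, names_from = "metric", values_from = "value")
}
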