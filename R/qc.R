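#' Summarize no-template and negative-extraction controls
#'
#' Pools all HF183 NTC and NEC wells across plates and reports the
#' percentage of clean (non-amplifying) control reactions together with the
#' list of amplified controls.  The result is invariant to plate order.
#'
#' @param wells Plate-well table.
#' @return A list: `pct_clean`, `n_controls`, `n_amplified` and a
#'   `flagged_controls` tibble (`plate_id`, `well`, `role`, `cq`).
#' @export
summarize_negative_controls <- function(wells) {
  ctrl <- wells[wells$role %in% c("NTC", "NEC") & wells$target == "HF183", ]
  if (nrow(ctrl) == 0) abort("no NTC/NEC control wells found.")
  amp <- ctrl[is.finite(ctrl$cq), ]
  list(
    pct_clean = 100 * (1 - nrow(amp) / nrow(ctrl)),
    n_controls = nrow(ctrl),
    n_amplified = nrow(amp),
    flagged_controls = tibble::as_tibble(
      amp[order(amp$plate_id, amp$well), c("plate_id", "well", "role", "cq")]
    )
  )
}

#' Flag samples showing qPCR inhibition on the sketa22 control
#'
#' Salmon testes DNA spiked during extraction is measured by the sketa22
#' assay; a delayed (or absent) sketa22 signal relative to clean extraction
#' blanks indicates inhibition or processing failure.
#'
#' @param metadata Sample metadata carrying a `sketa22_cq` column.
#' @param reference_sketa22_cq Reference Cq, e.g. the mean sketa22 Cq of the
#'   extraction blanks.
#' @param max_shift Maximum tolerated Cq delay before flagging (default 3).
#' @return Character vector of flagged `sample_id`s (empty when none).
#' @export
flag_inhibition <- function(metadata, reference_sketa22_cq, max_shift = 3.0) {
  if (!"sketa22_cq" %in% names(metadata)) {
    abort("metadata lacks a `sketa22_cq` column.")
  }
  if (!is.finite(reference_sketa22_cq)) {
    abort("`reference_sketa22_cq` must be provided.")
  }
  shift <- metadata$sketa22_cq - reference_sketa22_cq
  flagged <- is.na(metadata$sketa22_cq) | shift > max_shift
  metadata$sample_id[flagged]
}

#' Exclude site-stratum summaries with too few samples
#'
#' Site-stratum combinations with ten or fewer samples carry too much
#' sampling noise for frequency metrics and are set aside.
#'
#' @param summaries Wide site-summary tibble.
#' @param min_n Minimum sample count to retain (default 11, i.e. exclude
#'   n <= 10).
#' @return A list: `retained` (summary rows kept) and `excluded` (tibble
#'   `site_id`, `stratum`, `n_samples`).
#' @export
exclude_low_n_sites <- function(summaries, min_n = 11) {
  keep <- summaries$n_samples >= min_n
  list(
    retained = summaries[keep, ],
    excluded = tibble::as_tibble(
      summaries[!keep, c("site_id", "stratum", "n_samples")]
    )
  )
}

#' Build a QC report for a campaign
#'
#' @param wells Plate-well table.
#' @param metadata Sample metadata (with `sketa22_cq` if inhibition screening
#'   is wanted).
#' @param summaries Optional site summaries for the low-n exclusion listing.
#' @param reference_sketa22_cq Reference sketa22 Cq; defaults to the median
#'   observed sketa22 Cq (robust stand-in for extraction-blank values).
#' @param max_shift Inhibition threshold, Cq cycles.
#' @param min_n Minimum per-site-stratum sample count.
#' @return A list with the negative-control summary, inhibited samples and
#'   excluded sites.
#' @export
qc_report <- function(wells, metadata, summaries = NULL,
                      reference_sketa22_cq = NULL, max_shift = 3.0,
                      min_n = 11) {
  controls <- summarize_negative_controls(wells)
  inhibited <- character()
  if ("sketa22_cq" %in% names(metadata)) {
    if (is.null(reference_sketa22_cq)) {
      reference_sketa22_cq <- stats::median(metadata$sketa22_cq, na.rm = TRUE)
    }
    inhibited <- flag_inhibition(metadata, reference_sketa22_cq, max_shift)
  }
  excluded <- if (!is.null(summaries)) {
    exclude_low_n_sites(summaries, min_n)$excluded
  } else {
    tibble::tibble(site_id = character(), stratum = character(),
                   n_samples = integer())
  }
  list(
    pct_clean_control_reactions = controls$pct_clean,
    n_control_reactions = controls$n_controls,
    flagged_controls = controls$flagged_controls,
    inhibited_samples = inhibited,
    excluded_sites = excluded
  )
}
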