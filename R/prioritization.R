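#' Rank sites by a summary metric
#'
#' Rank 1 is the most contaminated site (largest metric value).  Ties are
#' broken deterministically: first by a secondary metric (the geometric-mean
#' concentration when ranking by a frequency, the AMP1 frequency when
#' ranking by concentration or Enterococcus metrics), then by site
#' identifier, so the ranks are always a permutation of `1..n_sites`.
#'
#' @param summaries Wide site-summary tibble for a single stratum.
#' @param metric_id Name of the metric column to rank by (e.g. `"freq_amp1"`,
#'   `"geomean_hf183"`).
#' @param tie_policy Currently only `"secondary_metric"`.
#' @return A `ranking_result` tibble: `metric_id`, `stratum`, `site_id`,
#'   `rank`, `metric_value`.
#' @export
rank_sites <- function(summaries, metric_id,
                       tie_policy = "secondary_metric") {
  tie_policy <- match.arg(tie_policy)
  if (nrow(summaries) < 2) abort("need at least 2 sites to rank.")
  if (!metric_id %in% names(summaries)) {
    abort(paste0("unknown metric: ", metric_id))
  }
  stratum <- unique(summaries$stratum)
  if (length(stratum) > 1) {
    abort("rank_sites() expects summaries from a single stratum.")
  }
  value <- summaries[[metric_id]]
  if (any(is.na(value))) {
    abort(sprintf("metric %s missing for site(s): %s", metric_id,
                  paste(summaries$site_id[is.na(value)], collapse = ", ")))
  }
  secondary_id <- if (grepl("^freq", metric_id)) "geomean_hf183" else "freq_amp1"
  secondary <- if (secondary_id %in% names(summaries)) {
    summaries[[secondary_id]]
  } else {
    rep(0, nrow(summaries))
  }
  secondary[is.na(secondary)] <- -Inf
  ord <- order(-value, -secondary, summaries$site_id)
  out <- tibble::tibble(
    metric_id = metric_id,
    stratum = stratum,
    site_id = summaries$site_id[ord],
    rank = seq_along(ord),
    metric_value = value[ord]
  )
  structure(out, class = c("ranking_result", class(out)),
            tie_policy = tie_policy)
}

#' Concordance between two site rankings
#'
#' @param ranking_a,ranking_b `ranking_result` objects over the same site
#'   set.
#' @return A `concordance_report`: Spearman `spearman_rho` between the rank
#'   vectors, per-site `shifts` (`rank_b - rank_a`; positive = dropped in
#'   priority), `n_sites_shifted`, and `max_shift_site` (largest absolute
#'   shift, ties broken by site identifier).
#' @export
rank_concordance <- function(ranking_a, ranking_b) {
  extra_a <- setdiff(ranking_a$site_id, ranking_b$site_id)
  extra_b <- setdiff(ranking_b$site_id, ranking_a$site_id)
  if (length(extra_a) > 0 || length(extra_b) > 0) {
    abort(paste0(
      "rankings cover different sites; only in first: {",
      paste(extra_a, collapse = ", "), "}; only in second: {",
      paste(extra_b, collapse = ", "), "}."
    ))
  }
  m <- dplyr::inner_join(
    ranking_a[, c("site_id", "rank")],
    ranking_b[, c("site_id", "rank")],
    by = "site_id", suffix = c("_a", "_b")
  )
  m$shift <- m$rank_b - m$rank_a
  m <- m[order(m$site_id), ]
  abs_max <- max(abs(m$shift))
  structure(
    list(
      spearman_rho = cor(m$rank_a, m$rank_b, method = "spearman"),
      shifts = tibble::as_tibble(m),
      n_sites_shifted = sum(m$shift != 0),
      max_shift_site = if (abs_max == 0) NA_character_ else
        m$site_id[abs(m$shift) == abs_max][1],
      max_shift = abs_max
    ),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report>\n")
  cat(sprintf("  Spearman rho = %.3f over %d sites; %d shifted\n",
              x$spearman_rho, nrow(x$shifts), x$n_sites_shifted))
  if (!is.na(x$max_shift_site)) {
    cat(sprintf("  largest shift: %s (%d positions)\n",
                x$max_shift_site, x$max_shift))
  }
  invisible(x)
}

#' Compare site rankings between dry and wet weather
#'
#' Restricts both strata to their shared sites, re-ranks within that subset,
#' and reports the rank concordance together with the sites whose metric
#' decreased from dry to wet (contamination usually expands in wet weather;
#' decreases flag possible storm-flow dilution).
#'
#' @param summaries_dry,summaries_wet Site summaries for the two strata.
#' @param metric_id Metric column to compare on.
#' @param tie_policy Passed to [rank_sites()].
#' @return A list: `concordance` (a `concordance_report` with dry as the
#'   first ranking), `decreased_sites`, `shared_sites`, and the two
#'   restricted rankings.
#' @export
dry_wet_comparison <- function(summaries_dry, summaries_wet, metric_id,
                               tie_policy = "secondary_metric") {
  shared <- intersect(summaries_dry$site_id, summaries_wet$site_id)
  if (length(shared) < 2) {
    abort("fewer than 2 sites sampled in both strata.")
  }
  sd_ <- summaries_dry[summaries_dry$site_id %in% shared, ]
  sw_ <- summaries_wet[summaries_wet$site_id %in% shared, ]
  rd <- rank_sites(sd_, metric_id, tie_policy)
  rw <- rank_sites(sw_, metric_id, tie_policy)
  vd <- setNames(sd_[[metric_id]], sd_$site_id)
  vw <- setNames(sw_[[metric_id]], sw_$site_id)
  decreased <- sort(names(vd)[vw[names(vd)] < vd])
  list(
    concordance = rank_concordance(rd, rw),
    decreased_sites = decreased,
    shared_sites = sort(shared),
    ranking_dry = rd,
    ranking_wet = rw
  )
}
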