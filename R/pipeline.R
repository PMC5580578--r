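#' Run the full analysis on a campaign
#'
#' Calibrates every lab's master curve from the pooled standards, assigns
#' weather strata from the rain series, quantifies all samples with censored
#' substitution, summarizes sites per stratum, applies the low-n exclusion,
#' ranks sites by frequency and by concentration in each stratum, and
#' computes the headline concordances (frequency vs. concentration per
#' stratum; dry vs. wet; HF183 vs. Enterococcus exceedance).
#'
#' @param plates Plate-well table.
#' @param metadata Sample metadata.
#' @param rain Rain series (omit if `metadata` already has a `weather`
#'   column).
#' @param volumes A [volume_config()].
#' @param scheme Censoring substitution scheme.
#' @param min_n Minimum per-site-stratum sample count (default 11).
#' @return A list: `curves`, `qc`, `replicates`, `summaries` (retained),
#'   `excluded_sites`, `rankings` (list by stratum and metric),
#'   `concordance` (list of `concordance_report`s and the dry-wet
#'   comparison).
#' @export
run_campaign_analysis <- function(plates, metadata, rain = NULL,
                                  volumes = volume_config(),
                                  scheme = c("poisson", "half_lod"),
                                  min_n = 11) {
  scheme <- match.arg(scheme)
  curves <- calibrate_labs(plates)
  if (!"weather" %in% names(metadata)) {
    if (is.null(rain)) abort("need `rain` when metadata has no weather column.")
    metadata <- assign_weather(metadata, rain)
  }
  replicates <- quantify_samples(plates, metadata, curves, volumes, scheme)
  summaries <- summarize_sites(replicates, metadata, volumes)
  excl <- exclude_low_n_sites(summaries, min_n)
  summaries <- excl$retained
  qc <- qc_report(plates, metadata, summaries = summaries, min_n = min_n)

  rankings <- list()
  concordance <- list()
  for (st in intersect(c("DRY", "WET"), summaries$stratum)) {
    s <- summaries[summaries$stratum == st, ]
    if (nrow(s) < 2) next
    key <- tolower(st)
    rankings[[paste0(key, "_freq_amp1")]] <- rank_sites(s, "freq_amp1")
    rankings[[paste0(key, "_geomean")]] <- rank_sites(s, "geomean_hf183")
    concordance[[paste0(key, "_freq_vs_geomean")]] <- rank_concordance(
      rankings[[paste0(key, "_freq_amp1")]],
      rankings[[paste0(key, "_geomean")]]
    )
    if (all(!is.na(s$entero_exceed_pct))) {
      r_ent <- rank_sites(s, "entero_exceed_pct")
      concordance[[paste0(key, "_hf183_vs_entero")]] <- rank_concordance(
        rankings[[paste0(key, "_freq_amp1")]], r_ent
      )
    }
  }
  if (all(c("DRY", "WET") %in% summaries$stratum)) {
    shared <- intersect(summaries$site_id[summaries$stratum == "DRY"],
                        summaries$site_id[summaries$stratum == "WET"])
    if (length(shared) >= 2) {
      concordance$dry_vs_wet_freq <- dry_wet_comparison(
        summaries[summaries$stratum == "DRY", ],
        summaries[summaries$stratum == "WET", ],
        "freq_amp1"
      )
    }
  }
  list(
    curves = curves,
    qc = qc,
    replicates = replicates,
    summaries = summaries,
    excluded_sites = excl$excluded,
    rankings = rankings,
    concordance = concordance
  )
}

#' Rebuild standard-curve objects from a curves table
#'
#' Inverse of [curve_table()], for pipeline stages that exchange curves on
#' disk.
#'
#' @param tab A data frame with the [curve_table()] columns.
#' @return Named list of `standard_curve` objects.
#' @export
curves_from_table <- function(tab) {
  curves <- lapply(seq_len(nrow(tab)), function(i) {
    structure(
      list(
        lab_id = tab$lab_id[i],
        slope = tab$slope[i],
        intercept = tab$intercept[i],
        r_squared = tab$r_squared[i],
        efficiency = tab$efficiency[i],
        n_points_used = tab$n_points_used[i],
        outliers_removed = tibble::tibble(log10_copies = numeric(),
                                          cq = numeric()),
        lod_copies = 1,
        lloq_copies = 10,
        lod_cq = tab$lod_cq[i],
        lloq_cq = tab$lloq_cq[i]
      ),
      class = "standard_curve"
    )
  })
  setNames(curves, tab$lab_id)
}

cli_log <- function(...) message("[hf183] ", ...)

cli_opt <- function(args, name, default = NULL) {
  flag <- paste0("--", name)
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) return(args[i + 1])
  default
}

#' Command-line pipeline entry point
#'
#' Subcommands: `simulate`, `calibrate`, `quantify`, `summarize`, `rank`,
#' `report`.  All operate on a campaign directory (`--dir`, default `.`)
#' holding the stage files (`plates.csv`, `metadata.csv`, `rain.csv`,
#' `curves.csv`, `replicates.csv`, `summaries.csv`, ...).  Each stage is
#' deterministic given its inputs, so re-running a stage reproduces its
#' outputs byte for byte.  A thin wrapper script is installed at
#' `system.file("scripts", "hf183-pipeline.R", package = "hf183monitor")`.
#'
#' Flags: `--seed` (simulate), `--scheme poisson|half_lod` (quantify),
#' `--metric` and `--stratum dry|wet` (rank).
#'
#' @param args Character vector of arguments (subcommand first).
#' @return Integer exit status, invisibly (0 on success).
#' @export
hf183_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0) {
      abort("usage: <simulate|calibrate|quantify|summarize|rank|report> [--dir DIR] ...")
    }
    cmd <- args[1]
    dir <- cli_opt(args, "dir", ".")
    p <- function(f) file.path(dir, f)
    need <- function(f) {
      if (!file.exists(p(f))) abort(paste0("missing input: ", p(f)))
      p(f)
    }
    switch(cmd,
      simulate = {
        seed <- as.integer(cli_opt(args, "seed", "1183"))
        cfg <- default_study_like_scenario(seed = seed)
        write_campaign(simulate_campaign(cfg), dir)
        cli_log("simulated campaign written to ", dir)
      },
      calibrate = {
        plates <- read_plate_table(need("plates.csv"))
        curves <- calibrate_labs(plates)
        readr::write_csv(curve_table(curves), p("curves.csv"), progress = FALSE)
        cli_log("calibrated ", length(curves), " lab(s)")
      },
      quantify = {
        scheme <- cli_opt(args, "scheme", "poisson")
        plates <- read_plate_table(need("plates.csv"))
        metadata <- read_sample_metadata(need("metadata.csv"))
        curves <- curves_from_table(
          readr::read_csv(need("curves.csv"), show_col_types = FALSE))
        reps <- quantify_samples(plates, metadata, curves, volume_config(),
                                 scheme = scheme)
        readr::write_csv(reps, p("replicates.csv"), na = "", progress = FALSE)
        cli_log("quantified ", length(unique(reps$sample_id)), " samples")
      },
      summarize = {
        reps <- readr::read_csv(need("replicates.csv"),
                                show_col_types = FALSE)
        metadata <- read_sample_metadata(need("metadata.csv"))
        metadata <- assign_weather(metadata,
                                   read_rain_series(need("rain.csv")))
        summaries <- summarize_sites(reps, metadata)
        write_site_summaries(summaries, p("summaries.csv"))
        plates <- read_plate_table(need("plates.csv"))
        qc <- qc_report(plates, metadata, summaries = summaries)
        jsonlite::write_json(
          list(
            pct_clean_control_reactions = qc$pct_clean_control_reactions,
            n_control_reactions = qc$n_control_reactions,
            inhibited_samples = qc$inhibited_samples,
            excluded_sites = qc$excluded_sites
          ),
          p("qc.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
        )
        cli_log("summaries for ", length(unique(summaries$site_id)), " sites")
      },
      rank = {
        metric <- cli_opt(args, "metric", "freq_amp1")
        stratum <- toupper(cli_opt(args, "stratum", "dry"))
        summaries <- read_site_summaries(need("summaries.csv"))
        keep <- exclude_low_n_sites(summaries)$retained
        s <- keep[keep$stratum == stratum, ]
        ranking <- rank_sites(s, metric)
        readr::write_csv(ranking, p(sprintf("ranking_%s_%s.csv",
                                            tolower(stratum), metric)),
                         progress = FALSE)
        cli_log("ranked ", nrow(ranking), " sites by ", metric)
      },
      report = {
        summaries <- read_site_summaries(need("summaries.csv"))
        plates <- read_plate_table(need("plates.csv"))
        metadata <- read_sample_metadata(need("metadata.csv"))
        res <- run_campaign_analysis(
          plates, metadata,
          rain = read_rain_series(need("rain.csv"))
        )
        writeLines(render_report(res), p("report.txt"))
        cli_log("report written to ", p("report.txt"))
      },
      abort(paste0("unknown subcommand: ", cmd))
    )
    0L
  }, error = function(e) {
    message("[hf183] error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

# human-readable campaign report
render_report <- function(res) {
  lines <- c(
    "HF183 monitoring campaign report",
    "================================",
    "",
    sprintf("Negative controls: %.1f%% clean (%d of %d reactions amplified)",
            res$qc$pct_clean_control_reactions,
            nrow(res$qc$flagged_controls), res$qc$n_control_reactions),
    sprintf("Inhibited samples: %d", length(res$qc$inhibited_samples)),
    sprintf("Site-stratum cells excluded (n <= 10): %d",
            nrow(res$excluded_sites)),
    "",
    "Master curves:",
    utils::capture.output(print(as.data.frame(curve_table(res$curves)))),
    ""
  )
  for (nm in names(res$concordance)) {
    obj <- res$concordance[[nm]]
    if (inherits(obj, "concordance_report")) {
      lines <- c(lines, sprintf("%s: Spearman rho = %.3f", nm,
                                obj$spearman_rho))
    } else {
      lines <- c(lines,
        sprintf("%s: Spearman rho = %.3f; %d site(s) decreased in wet",
                nm, obj$concordance$spearman_rho,
                length(obj$decreased_sites)))
    }
  }
  lines
}
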