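#' Convert quantification cycles to copies per reaction
#'
#' Inverts the master curve: `copies = 10^((cq - intercept) / slope)`.
#'
#' @param cq Quantification cycle value(s); must be finite (non-amplifying
#'   reactions are routed to the censoring machinery, not here).
#' @param curve A `standard_curve` with a negative slope.
#' @return Copies per reaction (vectorized over `cq`).
#' @export
cq_to_copies <- function(cq, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(!is.finite(cq))) {
    abort("`cq` must be finite; non-amplifying reactions have no Cq.")
  }
  10^((cq - curve$intercept) / curve$slope)
}

#' Censoring classes for qPCR replicates
#'
#' `ND` non-detected (no amplification); `DBLOD` amplified below the limit of
#' detection (< 1 copy/reaction); `DNQ` detected but not quantifiable
#' (1 to < 10 copies); `QUANT` quantifiable (>= 10 copies, the LLOQ boundary
#' is closed on the quantifiable side).
#'
#' @format A character vector of the four class labels.
#' @export
CENSOR_CLASSES <- c("ND", "DBLOD", "DNQ", "QUANT")

#' Classify a replicate against the detection and quantification limits
#'
#' @param cq Cq value(s); `NA` means no amplification.
#' @param curve A `standard_curve` (used to convert Cq to copies; the class
#'   boundaries are 1 and 10 copies per reaction).
#' @return Character vector of censor classes (see [CENSOR_CLASSES]).
#' @export
classify_replicate <- function(cq, curve) {
  out <- rep("ND", length(cq))
  amp <- is.finite(cq)
  if (any(amp)) {
    copies <- cq_to_copies(cq[amp], curve)
    # relative tolerance keeps copy numbers that hit a limit exactly (up to
    # floating point) on the closed side of the boundary
    tol <- 1 - 1e-9
    out[amp] <- ifelse(copies < curve$lod_copies * tol, "DBLOD",
                ifelse(copies < curve$lloq_copies * tol, "DNQ", "QUANT"))
  }
  out
}

#' Convert copies per reaction to copies per 100 mL of sample
#'
#' @param copies_per_reaction Copies per reaction.
#' @param volume_filtered_ml Volume of water filtered for this sample, in mL.
#' @param volumes A [volume_config()].
#' @return Copies per 100 mL.
#' @export
copies_to_conc <- function(copies_per_reaction, volume_filtered_ml, volumes) {
  copies_per_reaction * conversion_factor(volumes, volume_filtered_ml)
}

#' Poisson template-number estimate from a presence/absence pattern
#'
#' At low template numbers, whether a replicate amplifies is governed by
#' Poisson subsampling of marker copies into the reaction: a replicate is
#' positive when it receives at least one copy, with probability
#' `1 - exp(-lambda)`.  Given `k` of `n` replicates amplified, the mean
#' copies per reaction `lambda` is estimated either by maximum likelihood
#' (the classical most-probable-number estimator, `-ln(1 - k/n)`) or by the
#' posterior mean under a uniform prior on `[0, prior_upper]`, which unlike
#' the MLE is defined at the all-amplified boundary.
#'
#' @param n Number of replicates (>= 1).
#' @param k Number of amplified replicates, `0 <= k <= n`.
#' @param method `"mpn_mle"` or `"bayes_posterior_mean"`.
#' @param prior_upper Upper bound of the uniform prior on lambda, in copies
#'   per reaction.  Defaults to 10 (the LLOQ): a sample needing pattern-based
#'   estimation is by construction below the quantifiable range.
#' @return The estimate of lambda, copies per reaction.
#' @examples
#' estimate_lambda(3, 2)                              # log(3) = 1.0986
#' estimate_lambda(3, 0, "bayes_posterior_mean", 1)   # 0.2809
#' @export
estimate_lambda <- function(n, k,
                            method = c("mpn_mle", "bayes_posterior_mean"),
                            prior_upper = 10) {
  method <- match.arg(method)
  if (n < 1 || k < 0 || k > n) abort("need 0 <= k <= n and n >= 1.")
  if (method == "mpn_mle") {
    if (k == 0) return(0)
    if (k == n) {
      abort("MPN MLE undefined when all replicates amplified (k = n).")
    }
    return(-log(1 - k / n))
  }
  # posterior mean of lambda under likelihood (1 - e^-l)^k e^(-l(n-k)) and
  # uniform prior on [0, prior_upper]
  if (prior_upper <= 0) abort("`prior_upper` must be positive.")
  lik <- function(l) (1 - exp(-l))^k * exp(-l * (n - k))
  den <- integrate(lik, 0, prior_upper, rel.tol = 1e-9)$value
  num <- integrate(function(l) l * lik(l), 0, prior_upper, rel.tol = 1e-9)$value
  num / den
}

#' Substitute censored replicate measurements of one sample
#'
#' Quantifiable (`QUANT`) and detected-but-not-quantifiable (`DNQ`)
#' replicates keep their measured concentrations.  Censored replicates are
#' never zeroed; they are substituted:
#'
#' * `scheme = "poisson"`: a sample-level template estimate `lambda` is
#'   formed -- the geometric mean of the replicates measuring at or above
#'   1 copy/reaction when any exist, otherwise the Bayes posterior mean from
#'   the sample's amplification pattern ([estimate_lambda()], uniform prior
#'   on `[0, 10]` copies).  A non-detect is replaced by `lambda` (the
#'   unconditional Poisson mean) and an amplified-below-LOD replicate by
#'   `lambda / (1 - exp(-lambda))` (the Poisson mean conditional on at least
#'   one copy being present, hence always >= 1).
#' * `scheme = "half_lod"`: non-detects get half the LOD (0.5 copies) and
#'   below-LOD detections get the LOD (1 copy).
#'
#' @param cq Length-3 vector of replicate Cq values (`NA` = no amplification).
#' @param curve A `standard_curve` with detection limits set.
#' @param volume_filtered_ml Filtered volume of the sample, mL.
#' @param volumes A [volume_config()].
#' @param scheme `"poisson"` or `"half_lod"`.
#' @return A tibble with one row per replicate: `rep_index`, `cq`,
#'   `censor_class`, `copies_per_reaction` (measured or substituted) and
#'   `conc_per_100ml`; all concentrations strictly positive.
#' @export
substitute_censored <- function(cq, curve, volume_filtered_ml, volumes,
                                scheme = c("poisson", "half_lod")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(curve, "standard_curve"))
  cls <- classify_replicate(cq, curve)
  copies <- rep(NA_real_, length(cq))
  amp <- is.finite(cq)
  copies[amp] <- cq_to_copies(cq[amp], curve)

  censored <- cls %in% c("ND", "DBLOD")
  if (any(censored)) {
    if (scheme == "poisson") {
      measurable <- copies[amp & copies >= curve$lod_copies]
      if (length(measurable) > 0) {
        lambda <- exp(mean(log(measurable)))
      } else {
        lambda <- estimate_lambda(length(cq), sum(amp),
                                  method = "bayes_posterior_mean",
                                  prior_upper = curve$lloq_copies)
      }
      copies[cls == "ND"] <- lambda
      copies[cls == "DBLOD"] <- lambda / (1 - exp(-lambda))
    } else {
      copies[cls == "ND"] <- 0.5 * curve$lod_copies
      copies[cls == "DBLOD"] <- curve$lod_copies
    }
  }

  tibble::tibble(
    rep_index = seq_along(cq),
    cq = as.numeric(cq),
    censor_class = cls,
    copies_per_reaction = copies,
    conc_per_100ml = copies_to_conc(copies, volume_filtered_ml, volumes)
  )
}

#' Quantify every sample in a campaign
#'
#' Joins the SAMPLE wells of the plate table to their laboratory's master
#' curve and the sample metadata, classifies each replicate, substitutes
#' censored values, and returns the replicate-level tidy table the site
#' metrics are computed from.
#'
#' @param wells Plate-well table (see [read_plate_table()]).
#' @param metadata Sample metadata table (see [read_sample_metadata()]).
#' @param curves Named list of `standard_curve` objects keyed by `lab_id`.
#' @param volumes A [volume_config()].
#' @param scheme Censoring substitution scheme, `"poisson"` or `"half_lod"`.
#' @return A tibble: `sample_id`, `site_id`, `lab_id`, `rep_index`, `cq`,
#'   `censor_class`, `copies_per_reaction`, `conc_per_100ml`, `scheme`.
#' @export
quantify_samples <- function(wells, metadata, curves, volumes,
                             scheme = c("poisson", "half_lod")) {
  scheme <- match.arg(scheme)
  sw <- wells[wells$role == "SAMPLE" & wells$target == "HF183", ]
  if (nrow(sw) == 0) abort("no HF183 sample wells to quantify.")
  missing_labs <- setdiff(unique(sw$lab_id), names(curves))
  if (length(missing_labs) > 0) {
    abort(paste0("no master curve for lab(s): ",
                 paste(missing_labs, collapse = ", ")))
  }
  meta <- metadata[, c("sample_id", "site_id", "volume_filtered_ml")]
  sw <- dplyr::inner_join(sw, meta, by = "sample_id")

  parts <- lapply(split(sw, sw$sample_id), function(d) {
    d <- d[order(d$well), ]
    res <- substitute_censored(
      d$cq, curves[[d$lab_id[1]]], d$volume_filtered_ml[1], volumes,
      scheme = scheme
    )
    res$sample_id <- d$sample_id[1]
    res$site_id <- d$site_id[1]
    res$lab_id <- d$lab_id[1]
    res
  })
  out <- dplyr::bind_rows(parts)
  out$scheme <- scheme
  out[, c("sample_id", "site_id", "lab_id", "rep_index", "cq",
          "censor_class", "copies_per_reaction", "conc_per_100ml", "scheme")]
}
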