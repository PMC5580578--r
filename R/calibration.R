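#' Fit a per-laboratory master standard curve
#'
#' Ordinary least-squares regression of quantification cycle (Cq) on log10
#' standard copies per reaction, with iterative removal of outlying standard
#' points: at each pass the externally studentized residuals are computed and
#' the single worst point with |residual| > 3 is dropped, the curve refit, and
#' the loop repeated until no point exceeds the threshold.  One-at-a-time
#' removal avoids the masking that a single-pass sweep can suffer.  Standard
#' points from all of a laboratory's plates are pooled into one master fit.
#'
#' @param points A data frame with columns `log10_copies` and `cq`, one row
#'   per amplified standard reaction (non-amplifying standards are omitted by
#'   the caller).
#' @param lab_id Identifier of the laboratory the standards belong to.
#' @param residual_threshold Absolute externally studentized residual above
#'   which a point is declared an outlier. Default 3.
#' @param iterative If `TRUE` (default) remove one worst point per refit until
#'   none exceed the threshold; if `FALSE` remove every exceeding point in a
#'   single pass.
#' @return A `standard_curve` object: slope (Cq per log10 copies, negative),
#'   intercept (Cq at 1 copy per reaction), `r_squared`, amplification
#'   `efficiency`, points used, and the removed outliers.  The Cq detection
#'   limits (`lod_cq`, `lloq_cq`) are `NA` until set by
#'   [derive_detection_limits()].
#' @seealso [derive_detection_limits()], [efficiency_from_slope()],
#'   [cq_to_copies()]
#' @examples
#' pts <- data.frame(
#'   log10_copies = rep(0:5, each = 3),
#'   cq = 37 - 3.5 * rep(0:5, each = 3)
#' )
#' fit_master_curve(pts, "lab1")
#' @export
fit_master_curve <- function(points, lab_id,
                             residual_threshold = 3,
                             iterative = TRUE) {
  if (!all(c("log10_copies", "cq") %in% names(points))) {
    abort("`points` must have columns `log10_copies` and `cq`.")
  }
  pts <- tibble::as_tibble(points)[, c("log10_copies", "cq")]
  if (any(!is.finite(pts$log10_copies)) || any(!is.finite(pts$cq))) {
    abort("standard points must have finite `log10_copies` and `cq`.")
  }
  n_conc <- length(unique(pts$log10_copies))
  if (n_conc < 4) {
    abort(sprintf(
      "insufficient data: %d distinct concentrations (need at least 4).",
      n_conc
    ))
  }

  removed <- pts[0, ]
  repeat {
    if (nrow(pts) < 3 || length(unique(pts$log10_copies)) < 2) {
      abort("fewer than 2 usable points remain after outlier removal.")
    }
    fit <- lm(cq ~ log10_copies, data = pts)
    # an (almost) exact fit has no outliers; studentized residuals of
    # femto-cycle noise are meaningless
    if (max(abs(residuals(fit))) < 1e-8) break
    rs <- suppressWarnings(stats::rstudent(fit))
    rs[!is.finite(rs)] <- 0
    if (max(abs(rs)) <= residual_threshold) break
    if (iterative) {
      drop_idx <- which.max(abs(rs))
    } else {
      drop_idx <- which(abs(rs) > residual_threshold)
    }
    removed <- rbind(removed, pts[drop_idx, ])
    pts <- pts[-drop_idx, ]
    if (!iterative) {
      fit <- lm(cq ~ log10_copies, data = pts)
      break
    }
  }

  slope <- unname(coef(fit)[["log10_copies"]])
  intercept <- unname(coef(fit)[["(Intercept)"]])
  if (slope >= 0) {
    abort(sprintf("degenerate curve for lab %s: fitted slope %.3f is not negative.",
                  lab_id, slope))
  }
  r2 <- suppressWarnings(summary(fit)$r.squared)

  structure(
    list(
      lab_id = lab_id,
      slope = slope,
      intercept = intercept,
      r_squared = r2,
      efficiency = efficiency_from_slope(slope),
      n_points_used = nrow(pts),
      outliers_removed = tibble::as_tibble(removed),
      lod_copies = 1,
      lloq_copies = 10,
      lod_cq = NA_real_,
      lloq_cq = NA_real_
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve> lab", x$lab_id, "\n")
  cat(sprintf("  Cq = %.3f %+.4f * log10(copies)   R^2 = %.4f\n",
              x$intercept, x$slope, x$r_squared))
  cat(sprintf("  efficiency %.3f; %d points used, %d outliers removed\n",
              x$efficiency, x$n_points_used, nrow(x$outliers_removed)))
  if (is.finite(x$lod_cq)) {
    cat(sprintf("  LOD %g copies/rxn (Cq %.2f); LLOQ %g copies/rxn (Cq %.2f)\n",
                x$lod_copies, x$lod_cq, x$lloq_copies, x$lloq_cq))
  }
  invisible(x)
}

#' Amplification efficiency from a standard-curve slope
#'
#' `E = 10^(-1/slope) - 1`; a slope of -3.32 cycles per decade corresponds to
#' perfect doubling (efficiency 1).
#'
#' @param slope Standard-curve slope in Cq per log10 copies; must be negative.
#' @return The amplification efficiency (0.9--1.1 for a well-behaved assay).
#' @export
efficiency_from_slope <- function(slope) {
  if (any(!is.finite(slope)) || any(slope >= 0)) {
    abort("`slope` must be negative.")
  }
  10^(-1 / slope) - 1
}

#' Set the Cq detection limits of a master curve
#'
#' The limit of detection (LOD) is the lowest standard concentration, 1 copy
#' per reaction, expressed in Cq as the mean observed Cq of the amplified
#' 1-copy standards.  The lower limit of quantification (LLOQ) is the lowest
#' concentration at which every replicate amplifies, 10 copies per reaction,
#' expressed as the mean 10-copy Cq plus twice its sample standard deviation.
#'
#' @param curve A `standard_curve`.
#' @param cq_1copy Observed Cq values of amplified 1-copy standards (>= 2).
#' @param cq_10copy Observed Cq values of 10-copy standards (>= 2).
#' @return The curve with `lod_cq` and `lloq_cq` filled in.
#' @export
derive_detection_limits <- function(curve, cq_1copy, cq_10copy) {
  stopifnot(inherits(curve, "standard_curve"))
  cq_1copy <- cq_1copy[is.finite(cq_1copy)]
  cq_10copy <- cq_10copy[is.finite(cq_10copy)]
  if (length(cq_1copy) < 2) {
    abort("cannot set LOD: fewer than 2 amplified 1-copy standards.")
  }
  if (length(cq_10copy) < 2) {
    abort("cannot set LLOQ: fewer than 2 amplified 10-copy standards.")
  }
  curve$lod_cq <- mean(cq_1copy)
  curve$lloq_cq <- mean(cq_10copy) + 2 * sd(cq_10copy)
  if (curve$lloq_cq >= curve$lod_cq) {
    abort(sprintf(
      "invalid limits for lab %s: LLOQ Cq %.2f not below LOD Cq %.2f.",
      curve$lab_id, curve$lloq_cq, curve$lod_cq
    ))
  }
  curve
}

#' Calibrate one laboratory from its pooled standard wells
#'
#' Convenience wrapper: pools all STANDARD wells of one lab across plates,
#' fits the master curve on the amplified ones, and derives the Cq detection
#' limits from the 1- and 10-copy standards.
#'
#' @param wells Plate-well table (see [read_plate_table()]) for a single lab.
#' @inheritParams fit_master_curve
#' @return A `standard_curve` with detection limits set.
#' @export
calibrate_lab <- function(wells, residual_threshold = 3, iterative = TRUE) {
  std <- wells[wells$role == "STANDARD" & wells$target == "HF183", ]
  if (nrow(std) == 0) abort("no HF183 standard wells found.")
  lab <- unique(std$lab_id)
  if (length(lab) != 1) {
    abort("`calibrate_lab()` expects wells from exactly one lab.")
  }
  amp <- std[is.finite(std$cq), ]
  curve <- fit_master_curve(
    data.frame(log10_copies = log10(amp$standard_copies), cq = amp$cq),
    lab_id = lab,
    residual_threshold = residual_threshold,
    iterative = iterative
  )
  derive_detection_limits(
    curve,
    cq_1copy = amp$cq[amp$standard_copies == 1],
    cq_10copy = amp$cq[amp$standard_copies == 10]
  )
}

#' Calibrate every laboratory present in a plate-well table
#'
#' @param wells Plate-well table covering one or more labs.
#' @inheritParams fit_master_curve
#' @return A named list of `standard_curve` objects, one per `lab_id`.
#' @export
calibrate_labs <- function(wells, residual_threshold = 3, iterative = TRUE) {
  labs <- sort(unique(wells$lab_id[wells$role == "STANDARD"]))
  curves <- lapply(labs, function(l) {
    calibrate_lab(wells[wells$lab_id == l, ],
                  residual_threshold = residual_threshold,
                  iterative = iterative)
  })
  setNames(curves, labs)
}

#' Tabulate fitted master curves
#'
#' @param curves A list of `standard_curve` objects.
#' @return A tibble with one row per lab: slope, intercept, R^2, efficiency,
#'   Cq limits, points used and outliers removed.
#' @export
curve_table <- function(curves) {
  if (inherits(curves, "standard_curve")) curves <- list(curves)
  dplyr::bind_rows(lapply(curves, function(cv) {
    tibble::tibble(
      lab_id = cv$lab_id,
      slope = cv$slope,
      intercept = cv$intercept,
      r_squared = cv$r_squared,
      efficiency = cv$efficiency,
      lod_cq = cv$lod_cq,
      lloq_cq = cv$lloq_cq,
      n_points_used = cv$n_points_used,
      n_outliers = nrow(cv$outliers_removed)
    )
  }))
}
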