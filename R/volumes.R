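#' Volume configuration for copies-per-reaction to copies-per-100-mL conversion
#'
#' Captures the bench volumes that link a qPCR reaction back to the water
#' sample: the DNA extract elution volume, the template volume pipetted into
#' each reaction, and the fixed 100 mL reference volume that concentrations
#' are reported against.  The composite factor for a sample filtered at
#' `v` mL is `(elution / template) * (100 / v)`.
#'
#' The defaults (394.5 uL elution, 5 uL template) give a composite factor of
#' 78.9 for a 100 mL sample, so 1 and 10 copies per reaction correspond to
#' 79 and 789 copies per 100 mL (rounded).
#'
#' @param elution_volume_ul Elution volume of the DNA extract, in microliters.
#' @param template_volume_ul Template volume per qPCR reaction, in microliters.
#'   Must not exceed the elution volume.
#' @param reference_volume_ml Reporting reference volume; fixed at 100 mL.
#' @return A `volume_config` object (a named list).
#' @examples
#' vol <- volume_config()
#' copies_to_conc(1, 100, vol)   # ~78.9 copies per 100 mL
#' @export
volume_config <- function(elution_volume_ul = 394.5,
                          template_volume_ul = 5,
                          reference_volume_ml = 100) {
  if (!is.numeric(elution_volume_ul) || elution_volume_ul <= 0) {
    abort("`elution_volume_ul` must be a positive number.")
  }
  if (!is.numeric(template_volume_ul) || template_volume_ul <= 0) {
    abort("`template_volume_ul` must be a positive number.")
  }
  if (template_volume_ul > elution_volume_ul) {
    abort("`template_volume_ul` must not exceed `elution_volume_ul`.")
  }
  if (reference_volume_ml != 100) {
    abort("`reference_volume_ml` is fixed at 100 mL.")
  }
  structure(
    list(
      elution_volume_ul = elution_volume_ul,
      template_volume_ul = template_volume_ul,
      reference_volume_ml = 100
    ),
    class = "volume_config"
  )
}

#' @export
print.volume_config <- function(x, ...) {
  cat("<volume_config>\n")
  cat("  elution:  ", x$elution_volume_ul, "uL\n")
  cat("  template: ", x$template_volume_ul, "uL\n")
  cat("  factor at 100 mL filtered:",
      x$elution_volume_ul / x$template_volume_ul, "\n")
  invisible(x)
}

# composite copies/reaction -> copies/100 mL factor for a given filtered volume
conversion_factor <- function(volumes, volume_filtered_ml) {
  stopifnot(inherits(volumes, "volume_config"))
  if (any(!is.finite(volume_filtered_ml)) || any(volume_filtered_ml <= 0)) {
    abort("`volume_filtered_ml` must be positive.")
  }
  (volumes$elution_volume_ul / volumes$template_volume_ul) *
    (volumes$reference_volume_ml / volume_filtered_ml)
}
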