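#' UV calibration curve
#'
#' A linear Beer-Lambert calibration `A = slope * c + intercept` mapping
#' analyte concentration (mg/mL) in the measured well to absorbance.
#' The default parameters are those of the packaged PER reference assay
#' (see [ref_compound()]), calibrated over 9-90 ug/mL.
#'
#' @param slope Absorbance per (mg/mL). Must be positive.
#' @param intercept Blank absorbance.
#' @param valid_range Length-2 numeric, concentration validity interval in
#'   ug/mL (the range actually spanned by the calibration standards).
#' @param n_points Number of calibration standards.
#' @param r_squared Coefficient of determination of the calibration fit.
#' @return An object of class `calibration_curve`.
#' @examples
#' cal <- calibration_curve()
#' absorbance_to_concentration(1.18960, cal)
#' @export
calibration_curve <- function(slope = 117.95, intercept = 0.01,
                              valid_range = c(9, 90), n_points = 9L,
                              r_squared = 0.9997) {
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) || slope <= 0) {
    stop("calibration slope must be a single positive number", call. = FALSE)
  }
  if (length(valid_range) != 2L || !all(is.finite(valid_range)) ||
      valid_range[1] >= valid_range[2]) {
    stop("valid_range must be an increasing concentration interval (ug/mL)",
         call. = FALSE)
  }
  structure(
    list(slope = slope, intercept = intercept,
         valid_range = as.numeric(valid_range),
         n_points = as.integer(n_points), r_squared = r_squared),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve: A = %.5g c + %.5g (R^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  cat(sprintf("  valid range: %g-%g ug/mL\n", x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Invert a calibration curve
#'
#' Converts a measured absorbance to the concentration in the original
#' (undiluted) sample, `dilution * (A - intercept) / slope`. Absorbances
#' below the blank intercept are clamped to zero concentration and flagged
#' (`below_blank`) rather than erroring: readings slightly under the blank
#' are expected instrument noise. When the *undiluted well* concentration
#' falls outside the calibration validity range an `out_of_range` flag is
#' attached.
#'
#' @param A Numeric vector of absorbances.
#' @param calib A [calibration_curve()].
#' @param dilution Dilution factor(s) applied before reading (>= 1),
#'   recycled against `A`.
#' @return Numeric vector of concentrations in mg/mL, with a character-list
#'   attribute `"flags"` (one character vector per element).
#' @export
absorbance_to_concentration <- function(A, calib = calibration_curve(),
                                        dilution = 1) {
  stopifnot(inherits(calib, "calibration_curve"))
  if (any(!is.finite(A))) stop("non-finite absorbance", call. = FALSE)
  if (any(dilution < 1)) stop("dilution factors must be >= 1", call. = FALSE)
  n <- max(length(A), length(dilution))
  A <- rep_len(A, n); dilution <- rep_len(dilution, n)

  c_well <- (A - calib$intercept) / calib$slope      # mg/mL in the read well
  flags <- vector("list", n)
  below <- c_well < 0
  c_well[below] <- 0
  # validity range is stated in ug/mL; c_well is mg/mL
  rng <- calib$valid_range / 1000
  oor <- !below & (c_well < rng[1] | c_well > rng[2])
  for (i in seq_len(n)) {
    fl <- character()
    if (below[i]) fl <- c(fl, "below_blank")
    if (oor[i]) fl <- c(fl, "out_of_range")
    flags[[i]] <- fl
  }
  conc <- dilution * c_well
  attr(conc, "flags") <- flags
  conc
}

#' Forward calibration map
#'
#' Predicts the absorbance that a well at concentration `c_well` (mg/mL,
#' already diluted) would read. Inverse of [absorbance_to_concentration()]
#' within the linear range; used by the simulator to emit raw plate data.
#'
#' @param c_well Concentration in the read well, mg/mL.
#' @param calib A [calibration_curve()].
#' @return Numeric vector of absorbances.
#' @export
concentration_to_absorbance <- function(c_well, calib = calibration_curve()) {
  stopifnot(inherits(calib, "calibration_curve"))
  calib$slope * c_well + calib$intercept
}
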