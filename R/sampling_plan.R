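#' Acceptor sampling plan
#'
#' Describes the geometry and sampling schedule of a permeation cell: when
#' the acceptor (receptor) compartment is sampled, how much is withdrawn,
#' and whether the whole acceptor phase is replaced (`full_replacement`,
#' typical for plate-based PAMPA) or a fixed aliquot is withdrawn and
#' replaced with fresh fluid (`sample_and_replace`, typical for Franz-type
#' diffusion cells). All bookkeeping of cumulative permeated amounts is
#' driven by this object.
#'
#' Canonical units are fixed here and throughout the package: time in
#' hours, area in cm^2, volume in mL, concentration in mg/mL, amount in
#' ug. Convert at the boundary (see [read_timecourse()]).
#'
#' @param sampling_times Strictly increasing sampling times in hours (> 0).
#' @param acceptor_volume Acceptor/receptor volume, mL.
#' @param sampled_volume Volume withdrawn at each sampling, mL
#'   (<= `acceptor_volume`).
#' @param replacement_mode `"full_replacement"` or `"sample_and_replace"`.
#' @param exposure_area Membrane area exposed to the donor, cm^2.
#' @param donor_volume Donor volume, mL.
#' @param donor_concentration Donor concentration C_D, mg/mL.
#' @param dilution_factors Per-timepoint dilution factors applied before
#'   the UV read (>= 1), recycled to the number of sampling times.
#' @return An object of class `sampling_plan`.
#' @seealso [pampa_sampling_plan()], [pigskin_sampling_plan()]
#' @export
sampling_plan <- function(sampling_times, acceptor_volume, sampled_volume,
                          replacement_mode = c("full_replacement",
                                               "sample_and_replace"),
                          exposure_area, donor_volume, donor_concentration,
                          dilution_factors = 1) {
  replacement_mode <- match.arg(replacement_mode)
  sampling_times <- as.numeric(sampling_times)
  if (length(sampling_times) < 1L || any(!is.finite(sampling_times)) ||
      any(sampling_times <= 0) || is.unsorted(sampling_times, strictly = TRUE)) {
    stop("sampling_times must be strictly increasing and > 0 (hours)",
         call. = FALSE)
  }
  if (sampled_volume > acceptor_volume) {
    stop("sampled_volume cannot exceed acceptor_volume", call. = FALSE)
  }
  if (exposure_area <= 0) stop("exposure_area must be > 0", call. = FALSE)
  if (donor_concentration <= 0) stop("donor_concentration must be > 0", call. = FALSE)
  if (acceptor_volume <= 0 || sampled_volume <= 0 || donor_volume <= 0) {
    stop("volumes must be > 0", call. = FALSE)
  }
  if (any(dilution_factors < 1)) stop("dilution factors must be >= 1", call. = FALSE)
  structure(
    list(sampling_times = sampling_times,
         acceptor_volume = acceptor_volume,
         sampled_volume = sampled_volume,
         replacement_mode = replacement_mode,
         exposure_area = exposure_area,
         donor_volume = donor_volume,
         donor_concentration = donor_concentration,
         dilution_factors = rep_len(as.numeric(dilution_factors),
                                    length(sampling_times))),
    class = "sampling_plan"
  )
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat(sprintf("Sampling plan (%s)\n", x$replacement_mode))
  cat(sprintf("  times [h]: %s\n", paste(signif(x$sampling_times, 4), collapse = ", ")))
  cat(sprintf("  acceptor %g mL (sampled %g mL), area %g cm^2\n",
              x$acceptor_volume, x$sampled_volume, x$exposure_area))
  cat(sprintf("  donor: %g mL at C_D = %g mg/mL (%g uL/cm^2)\n",
              x$donor_volume, x$donor_concentration,
              application_volume_per_area(x)))
  invisible(x)
}

#' Standard plate-assay (Skin-PAMPA) sampling plan
#'
#' The reference plate geometry: 70 uL donor over a 0.3 cm^2 exposure
#' area, 180 uL acceptor buffer fully replaced after each of the
#' 7.5, 15, 30, 60, 120, 240 and 360 min samplings. Although only part of
#' the acceptor is physically transferred to the UV plate, the acceptor
#' phase itself is exchanged completely, so the mass balance is that of
#' full replacement; the transferred fraction affects only measurement.
#'
#' @param donor_concentration Donor concentration C_D, mg/mL.
#' @param sampling_times Sampling times, hours.
#' @param dilution_factors Per-timepoint dilution factors for the UV read.
#' @return A [sampling_plan()].
#' @export
pampa_sampling_plan <- function(donor_concentration,
                                sampling_times = c(7.5, 15, 30, 60, 120, 240, 360) / 60,
                                dilution_factors = 1) {
  sampling_plan(sampling_times = sampling_times,
                acceptor_volume = 0.18, sampled_volume = 0.18,
                replacement_mode = "full_replacement",
                exposure_area = 0.3, donor_volume = 0.07,
                donor_concentration = donor_concentration,
                dilution_factors = dilution_factors)
}

#' Diffusion-cell (ex vivo skin) sampling plan
#'
#' Hourly sample-and-replace schedule up to 16 h: 200 uL of receptor fluid
#' is withdrawn at each timepoint and replaced with fresh fluid. The
#' receptor volume and the exposed skin area vary by cell and are not part
#' of any published standard for this assay, so both are mandatory. The
#' donor volume defaults to the infinite-dose application of 1.13 mL/cm^2.
#'
#' @param acceptor_volume Receptor compartment volume, mL (mandatory; no
#'   default exists for this geometry).
#' @param exposure_area Exposed skin area, cm^2 (mandatory).
#' @param donor_concentration Donor concentration C_D, mg/mL.
#' @param sampling_times Sampling times, hours.
#' @param sampled_volume Withdrawn aliquot, mL.
#' @param donor_volume Donor volume, mL; default 1.13 mL/cm^2 times area.
#' @return A [sampling_plan()].
#' @export
pigskin_sampling_plan <- function(acceptor_volume, exposure_area,
                                  donor_concentration,
                                  sampling_times = 1:16,
                                  sampled_volume = 0.2,
                                  donor_volume = 1.13 * exposure_area) {
  if (missing(acceptor_volume)) {
    stop("acceptor_volume is mandatory for skin diffusion cells (no default)",
         call. = FALSE)
  }
  if (missing(exposure_area)) {
    stop("exposure_area is mandatory for skin diffusion cells (no default)",
         call. = FALSE)
  }
  sampling_plan(sampling_times = sampling_times,
                acceptor_volume = acceptor_volume,
                sampled_volume = sampled_volume,
                replacement_mode = "sample_and_replace",
                exposure_area = exposure_area, donor_volume = donor_volume,
                donor_concentration = donor_concentration)
}

#' Applied dose normalisations
#'
#' `application_volume_per_area()` returns the applied donor volume per
#' unit area in uL/cm^2; `applied_dose_per_area()` the applied amount of
#' permeant per unit area in ug/cm^2. Both are the denominators of the
#' standard infinite-dose QC rules.
#'
#' @param plan A [sampling_plan()].
#' @return A single number.
#' @examples
#' application_volume_per_area(pampa_sampling_plan(1)) # 233.3 uL/cm^2
#' @export
application_volume_per_area <- function(plan) {
  stopifnot(inherits(plan, "sampling_plan"))
  plan$donor_volume * 1000 / plan$exposure_area
}

#' @rdname application_volume_per_area
#' @export
applied_dose_per_area <- function(plan) {
  stopifnot(inherits(plan, "sampling_plan"))
  if (plan$exposure_area <= 0) stop("zero exposure area", call. = FALSE)
  plan$donor_concentration * plan$donor_volume * 1000 / plan$exposure_area
}
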