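#' Acceptor concentration records
#'
#' Tidy carrier of measured acceptor concentrations: one row per
#' (solvent, replicate, timepoint). This is the interchange format between
#' raw-plate conversion and cumulative-amount assembly.
#'
#' @param solvent_code Character solvent labels (free-form, e.g. "S1").
#' @param replicate Integer replicate indices.
#' @param time_h Sampling times, hours.
#' @param concentration Measured acceptor concentrations, mg/mL (>= 0).
#' @return A `data.frame` of class `concentration_records`.
#' @export
concentration_records <- function(solvent_code, replicate, time_h, concentration) {
  df <- data.frame(solvent_code = as.character(solvent_code),
                   replicate = as.integer(replicate),
                   time_h = as.numeric(time_h),
                   concentration = as.numeric(concentration),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$concentration)) || any(df$concentration < 0)) {
    stop("concentrations must be finite and >= 0", call. = FALSE)
  }
  class(df) <- c("concentration_records", "data.frame")
  df
}

#' Cumulative permeated amount per unit area
#'
#' Converts the sequence of acceptor concentrations measured at the plan's
#' sampling times into the cumulative amount of permeant that has crossed
#' the membrane, per unit exposed area (Q, ug/cm^2).
#'
#' With full acceptor replacement each sampled concentration represents
#' only the interval since the previous exchange, so
#' `Q(t_i) = (V_A / A) * sum_{j <= i} c_j`.
#' With sample-and-replace, only `V_s` of the acceptor is exchanged, so
#' earlier samplings each removed `c_j * V_s` while the remainder is still
#' in the cell: `Q(t_i) = (c_i * V_A + V_s * sum_{j < i} c_j) / A`
#' (the standard Franz-cell replacement correction).
#' Concentrations are mg/mL, so amounts pick up a factor 1000 to land in ug.
#'
#' @param conc Acceptor concentrations (mg/mL): either a numeric vector
#'   with one value per plan sampling time, or a [concentration_records()]
#'   frame for a single solvent/replicate.
#' @param plan A [sampling_plan()].
#' @param solvent_code,replicate Labels attached to the profile when
#'   `conc` is a bare numeric vector.
#' @return An object of class `cumulative_profile`: list with
#'   `solvent_code`, `replicate`, `times` (h), `Q` (ug/cm^2), `flags`.
#'   `Q` excludes the implicit origin (0, 0).
#' @export
cumulative_amount <- function(conc, plan, solvent_code = NA_character_,
                              replicate = 1L) {
  stopifnot(inherits(plan, "sampling_plan"))
  if (is.data.frame(conc)) {
    if (length(unique(conc$solvent_code)) > 1L || length(unique(conc$replicate)) > 1L) {
      stop("cumulative_amount() expects records for a single solvent/replicate; ",
           "use assemble_profiles() for batches", call. = FALSE)
    }
    solvent_code <- conc$solvent_code[1]
    replicate <- conc$replicate[1]
    ord <- order(conc$time_h)
    conc <- conc[ord, , drop = FALSE]
    if (length(conc$time_h) != length(plan$sampling_times) ||
        any(abs(conc$time_h - plan$sampling_times) > 1e-9)) {
      stop("records do not cover the plan sampling times exactly ",
           "(missing or extra timepoint)", call. = FALSE)
    }
    conc <- conc$concentration
  }
  if (length(conc) != length(plan$sampling_times)) {
    stop("need exactly one concentration per plan sampling time", call. = FALSE)
  }
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("negative or non-finite concentration", call. = FALSE)
  }

  VA <- plan$acceptor_volume; Vs <- plan$sampled_volume; A <- plan$exposure_area
  Q <- switch(plan$replacement_mode,
    full_replacement = 1000 * VA * cumsum(conc) / A,
    sample_and_replace = {
      prior <- c(0, cumsum(conc)[-length(conc)])
      1000 * (conc * VA + Vs * prior) / A
    })
  structure(
    list(solvent_code = solvent_code, replicate = as.integer(replicate),
         times = plan$sampling_times, Q = Q, flags = character()),
    class = "cumulative_profile"
  )
}

#' @export
print.cumulative_profile <- function(x, ...) {
  cat(sprintf("Cumulative permeation profile [%s, replicate %d]\n",
              x$solvent_code, x$replicate))
  print(data.frame(time_h = x$times, Q_ug_cm2 = signif(x$Q, 5)), row.names = FALSE)
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Sink-condition check
#'
#' Infinite-dose kinetics assume the acceptor stays far from saturation so
#' back-diffusion is negligible; the conventional cap is 10 percent of the
#' permeant's solubility in the acceptor medium. The flag is raised only
#' when a measured concentration *strictly* exceeds the cap (boundary
#' values pass).
#'
#' @param conc Measured acceptor concentrations, mg/mL (vector or
#'   [concentration_records()]).
#' @param acceptor_solubility Solubility in the acceptor medium, mg/mL.
#' @param fraction Cap as a fraction of solubility; default 0.1.
#' @return `TRUE` if the sink condition was violated.
#' @export
sink_check <- function(conc, acceptor_solubility, fraction = 0.1) {
  if (is.data.frame(conc)) conc <- conc$concentration
  if (!is.numeric(acceptor_solubility) || acceptor_solubility <= 0) {
    stop("acceptor_solubility must be > 0", call. = FALSE)
  }
  any(conc > fraction * acceptor_solubility)
}

#' Donor-depletion check
#'
#' Permeability estimates are biased low once a substantial share of the
#' applied dose has permeated; the conventional limit is 10 percent.
#' Flags the profile when the final cumulative amount strictly exceeds
#' `fraction` of the applied dose per area (`C_D * V_D / A`).
#'
#' @param profile A `cumulative_profile`.
#' @param plan The [sampling_plan()] (supplies dose and area).
#' @param fraction Allowed permeated fraction of the dose; default 0.1.
#' @return `TRUE` if depletion exceeded the limit.
#' @export
donor_depletion_check <- function(profile, plan, fraction = 0.1) {
  stopifnot(inherits(profile, "cumulative_profile"))
  dose <- applied_dose_per_area(plan)   # errors on zero area
  profile$Q[length(profile$Q)] > fraction * dose
}

#' Assemble QC-flagged profiles for a whole experiment
#'
#' Splits a [concentration_records()] frame by (solvent, replicate), runs
#' [cumulative_amount()] on each group and attaches `sink_violation` and
#' `donor_depletion` QC flags.
#'
#' @param records A [concentration_records()] frame.
#' @param plan A [sampling_plan()] shared by all groups, or a named list of
#'   plans keyed by solvent code (donor concentrations differ by solvent).
#' @param acceptor_solubility Optional solubility in the acceptor medium
#'   (mg/mL) enabling the sink check.
#' @param sink_fraction,depletion_fraction QC caps (fractions).
#' @return A list of `cumulative_profile` objects.
#' @seealso [profiles_to_frame()] for the tidy export.
#' @export
assemble_profiles <- function(records, plan, acceptor_solubility = NULL,
                              sink_fraction = 0.1, depletion_fraction = 0.1) {
  stopifnot(is.data.frame(records))
  groups <- split(records,
                  list(records$solvent_code, records$replicate), drop = TRUE)
  lapply(unname(groups), function(g) {
    p <- if (inherits(plan, "sampling_plan")) plan else plan[[g$solvent_code[1]]]
    if (is.null(p)) stop("no sampling plan for solvent ", g$solvent_code[1],
                         call. = FALSE)
    prof <- cumulative_amount(g, p)
    if (!is.null(acceptor_solubility) &&
        sink_check(g, acceptor_solubility, sink_fraction)) {
      prof$flags <- c(prof$flags, "sink_violation")
    }
    if (donor_depletion_check(prof, p, depletion_fraction)) {
      prof$flags <- c(prof$flags, "donor_depletion")
    }
    prof
  })
}

#' Flatten profiles to a tidy frame
#'
#' @param profiles A list of `cumulative_profile` objects (or a single one).
#' @return A `data.frame` with columns `solvent_code`, `replicate`,
#'   `time_h`, `Q_ug_cm2`, `flags` (semicolon-joined).
#' @export
profiles_to_frame <- function(profiles) {
  if (inherits(profiles, "cumulative_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(solvent_code = p$solvent_code, replicate = p$replicate,
               time_h = p$times, Q_ug_cm2 = p$Q,
               flags = paste(p$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}
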