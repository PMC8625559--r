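#' Linear fit window for flux estimation
#'
#' Under infinite dosing the cumulative profile is linear once the
#' membrane is saturated; flux is the slope of that early linear range.
#' The default window covers 0-0.5 h, i.e. the first three samplings of
#' the standard plate schedule, *excluding* the implicit origin (0, 0):
#' the origin lies on the transient, not on the steady-state line
#' `J (t - lag)`, so including it biases both slope and x-intercept
#' toward zero lag (see the methods vignette).
#'
#' @param t_min,t_max Window bounds in hours (`t_min < t_max`).
#' @param include_origin Include the implicit (0, 0) point in the fit
#'   (only sensible when the lag is truly negligible).
#' @return An object of class `fit_window`.
#' @export
fit_window <- function(t_min = 0, t_max = 0.5, include_origin = FALSE) {
  if (!(t_min < t_max)) stop("t_min must be < t_max", call. = FALSE)
  structure(list(t_min = t_min, t_max = t_max,
                 include_origin = isTRUE(include_origin)),
            class = "fit_window")
}

#' Steady-state flux and lag time
#'
#' Ordinary least squares of Q on t over the fit window. The flux J is the
#' slope (ug cm^-2 h^-1); the lag time is the x-intercept of the fitted
#' line (`-intercept/slope`), reported in minutes and clamped at zero.
#' A negative fitted slope is clamped to `J = 0` with a `negative_slope`
#' flag rather than erroring (flat/noisy profiles occur at very low
#' permeability).
#'
#' @param profile A `cumulative_profile` (see [cumulative_amount()]).
#' @param window A [fit_window()].
#' @return List with `J` (ug cm^-2 h^-1), `lag_min` (minutes),
#'   `intercept` (ug/cm^2), `flags`.
#' @examples
#' plan <- pampa_sampling_plan(1)
#' prof <- cumulative_amount(rep(0.01, 7), plan)
#' fit_flux(prof, fit_window())
#' @export
fit_flux <- function(profile, window = fit_window()) {
  stopifnot(inherits(profile, "cumulative_profile"),
            inherits(window, "fit_window"))
  keep <- profile$times >= window$t_min & profile$times <= window$t_max
  t <- profile$times[keep]; Q <- profile$Q[keep]
  if (window$include_origin && !any(t == 0)) {
    t <- c(0, t); Q <- c(0, Q)
  }
  if (length(t) < 2L) stop("need at least 2 points in the fit window", call. = FALSE)
  if (diff(range(t)) == 0) stop("singular fit: all times equal", call. = FALSE)

  # closed-form simple OLS (oracle-checked against stats::lm in the tests)
  tb <- mean(t); Qb <- mean(Q)
  slope <- sum((t - tb) * (Q - Qb)) / sum((t - tb)^2)
  intercept <- Qb - slope * tb

  flags <- character()
  if (slope < 0) {
    slope <- 0
    flags <- c(flags, "negative_slope")
    lag_min <- 0
  } else if (slope == 0) {
    lag_min <- 0
  } else {
    lag_min <- max(0, -intercept / slope) * 60
  }
  list(J = slope, lag_min = lag_min, intercept = intercept, flags = flags)
}

#' Permeability coefficient from flux
#'
#' `P = J / C_D` with the donor concentration converted from mg/mL to
#' ug/cm^3 (factor 1000), giving P in cm/h; the log10 is returned, the
#' scale on which membrane permeabilities are compared. The same formula
#' yields logP_m for plate assays and logK_p for skin diffusion cells.
#'
#' @param J Steady-state flux, ug cm^-2 h^-1.
#' @param C_D Donor concentration, mg/mL.
#' @return log10 permeability coefficient (log10 cm/h). `J = 0` returns
#'   `-Inf` with a `zero_flux` flag attribute instead of erroring.
#' @examples
#' permeability_coefficient(12033, 500)  # -1.62
#' @export
permeability_coefficient <- function(J, C_D) {
  if (any(C_D <= 0)) stop("C_D must be > 0", call. = FALSE)
  if (any(J < 0)) stop("J must be >= 0", call. = FALSE)
  out <- log10(J / (C_D * 1000))
  if (any(J == 0)) {
    attr(out, "flags") <- ifelse(J == 0, "zero_flux", "")
  }
  out
}

#' Normalised area under the cumulative profile
#'
#' Trapezoidal integral of Q(t) from 0 (with the implicit origin (0, 0))
#' to `horizon`, divided by the donor concentration. An exposure-like
#' summary comparable across donor concentrations,
#' units (ug h cm^-2) / (mg/mL).
#'
#' @param profile A `cumulative_profile`.
#' @param horizon Integration horizon, hours (must not exceed the last
#'   sampling time; Q at an interior horizon is linearly interpolated).
#' @param C_D Donor concentration, mg/mL.
#' @return A single number.
#' @export
auc_normalized <- function(profile, horizon = 6, C_D) {
  stopifnot(inherits(profile, "cumulative_profile"))
  if (C_D <= 0) stop("C_D must be > 0", call. = FALSE)
  t <- c(0, profile$times); Q <- c(0, profile$Q)
  if (horizon > max(t) + 1e-9) {
    stop("horizon lies beyond the last sampling time", call. = FALSE)
  }
  if (!any(abs(t - horizon) < 1e-9)) {
    Qh <- stats::approx(t, Q, xout = horizon)$y
    keep <- t < horizon
    t <- c(t[keep], horizon); Q <- c(Q[keep], Qh)
  } else {
    keep <- t <= horizon + 1e-9
    t <- t[keep]; Q <- Q[keep]
  }
  sum(diff(t) * (utils::head(Q, -1) + utils::tail(Q, -1)) / 2) / C_D
}

#' Permeability class
#'
#' Three-band classification of log10 permeability coefficients:
#' `low` below the lower cutpoint, `high` above the upper cutpoint,
#' `medium` between (boundaries inclusive in `medium`; strict
#' inequalities at both cuts). Defaults at -2.4 and -1.5 resolve the
#' conventional gapped reporting bands (low < -2.4; medium -2.3 to -1.5)
#' into contiguous ones; both cutpoints are configurable.
#'
#' @param logPm Numeric vector of log10 permeability coefficients.
#' @param cutpoints Length-2 numeric `c(low_below, high_above)`, ordered.
#' @return Character vector in `c("low", "medium", "high")`.
#' @export
classify_permeability <- function(logPm, cutpoints = c(-2.4, -1.5)) {
  if (length(cutpoints) != 2L || cutpoints[1] >= cutpoints[2]) {
    stop("cutpoints must be an ordered pair (low_below, high_above)",
         call. = FALSE)
  }
  ifelse(logPm < cutpoints[1], "low",
         ifelse(logPm > cutpoints[2], "high", "medium"))
}

#' Per-replicate permeation metrics
#'
#' Runs flux/lag estimation, the permeability coefficient, the permeated
#' amount at the horizon and the normalised AUC for one replicate profile.
#'
#' @param profile A `cumulative_profile`.
#' @param C_D Donor concentration, mg/mL.
#' @param window A [fit_window()].
#' @param horizon AUC / permeated-amount horizon, hours.
#' @param cutpoints Class cutpoints, see [classify_permeability()].
#' @return A one-row `data.frame` of class `permeation_metrics`.
#' @export
permeation_metrics <- function(profile, C_D, window = fit_window(),
                               horizon = 6, cutpoints = c(-2.4, -1.5)) {
  fit <- fit_flux(profile, window)
  logPm <- if (fit$J > 0) permeability_coefficient(fit$J, C_D) else NA_real_
  it <- max(profile$times[profile$times <= horizon + 1e-9])
  Qh <- if (any(abs(profile$times - horizon) < 1e-9)) {
    profile$Q[which.min(abs(profile$times - horizon))]
  } else {
    stats::approx(c(0, profile$times), c(0, profile$Q), xout = min(horizon, it))$y
  }
  out <- data.frame(
    solvent_code = profile$solvent_code, replicate = profile$replicate,
    C_D_mg_ml = C_D, J = fit$J, lag_min = fit$lag_min,
    Q_horizon = Qh, auc_norm = auc_normalized(profile, horizon, C_D),
    logPm = as.numeric(logPm),
    perm_class = if (is.na(logPm)) NA_character_ else classify_permeability(logPm, cutpoints),
    flags = paste(unique(c(profile$flags, fit$flags,
                           if (fit$J == 0) "zero_flux")), collapse = ";"),
    stringsAsFactors = FALSE)
  class(out) <- c("permeation_metrics", "data.frame")
  out
}

#' Per-solvent replicate summary
#'
#' Aggregates per-replicate metrics to per-solvent mean and sample SD for
#' J, lag time, Q at horizon, normalised AUC and logPm. The permeability
#' coefficient is averaged on the log scale (mean of per-replicate log10
#' values), the convention under which replicate variability is symmetric.
#' The class label is recomputed from the mean logPm.
#'
#' @param metrics A `data.frame` of per-replicate metrics rows
#'   (rbind of [permeation_metrics()] outputs).
#' @param cutpoints Class cutpoints for the summary label.
#' @return A `data.frame`, one row per solvent, columns
#'   `code, C_D_mg_ml, J_mean, J_sd, lag_min_mean, lag_min_sd, Q_mean,
#'   Q_sd, auc_norm_mean, logPm_mean, logPm_sd, n, perm_class, flags`.
#'   SDs are `NA` for single replicates.
#' @export
summarize_replicates <- function(metrics, cutpoints = c(-2.4, -1.5)) {
  stopifnot(is.data.frame(metrics), nrow(metrics) >= 1L)
  groups <- split(metrics, metrics$solvent_code)
  out <- do.call(rbind, lapply(groups, function(g) {
    msd <- function(x) c(mean(x), if (length(x) > 1L) stats::sd(x) else NA_real_)
    J <- msd(g$J); lag <- msd(g$lag_min); Q <- msd(g$Q_horizon)
    auc <- msd(g$auc_norm); lp <- msd(g$logPm)
    data.frame(code = g$solvent_code[1], C_D_mg_ml = g$C_D_mg_ml[1],
               J_mean = J[1], J_sd = J[2],
               lag_min_mean = lag[1], lag_min_sd = lag[2],
               Q_mean = Q[1], Q_sd = Q[2],
               auc_norm_mean = auc[1],
               logPm_mean = lp[1], logPm_sd = lp[2],
               n = nrow(g),
               perm_class = if (is.na(lp[1])) NA_character_ else
                 classify_permeability(lp[1], cutpoints),
               flags = paste(unique(unlist(strsplit(g$flags, ";"))), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Full per-solvent analysis of an experiment
#'
#' Convenience wrapper: profiles in, per-solvent summary table out.
#'
#' @param profiles List of `cumulative_profile` objects.
#' @param plans A single [sampling_plan()] or named list keyed by solvent
#'   code (supplies C_D per solvent).
#' @inheritParams permeation_metrics
#' @return The [summarize_replicates()] table.
#' @export
analyze_profiles <- function(profiles, plans, window = fit_window(),
                             horizon = 6, cutpoints = c(-2.4, -1.5)) {
  per_rep <- do.call(rbind, lapply(profiles, function(p) {
    pl <- if (inherits(plans, "sampling_plan")) plans else plans[[p$solvent_code]]
    if (is.null(pl)) stop("no plan for solvent ", p$solvent_code, call. = FALSE)
    permeation_metrics(p, pl$donor_concentration, window, horizon, cutpoints)
  }))
  summarize_replicates(per_rep, cutpoints)
}
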