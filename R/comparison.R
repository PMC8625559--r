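#' Pair screen and ex vivo metric tables by solvent
#'
#' Inner join on solvent code between an artificial-membrane (PAMPA)
#' summary table and an ex vivo skin summary table. Codes present in only
#' one table are dropped from the pairing and reported via the
#' `"unpaired"` attribute (with a warning when nothing pairs).
#'
#' @param pampa Data frame with columns `code`, `logPm_mean` (or `logPm`),
#'   `J_mean` (or `J`), `auc_norm_mean` (or `auc_norm`).
#' @param skin Data frame with columns `code`, `logKp_mean` (or `logKp`),
#'   `J_mean` (or `J`), `Q_mean` (or `Qt`).
#' @return A `data.frame` of class `paired_permeability` with columns
#'   `code, logPm_pampa, logKp_skin, auc_norm_pampa, Qt_skin, J_pampa,
#'   J_skin`; attribute `unpaired` lists codes found in one table only.
#' @export
pair_models <- function(pampa, skin) {
  pick <- function(df, ...) {
    for (nm in c(...)) if (nm %in% names(df)) return(df[[nm]])
    stop("missing column: one of ", paste(c(...), collapse = "/"), call. = FALSE)
  }
  for (df in list(pampa, skin)) {
    if (anyDuplicated(df$code)) {
      stop("duplicate solvent codes: ",
           paste(unique(df$code[duplicated(df$code)]), collapse = ", "),
           call. = FALSE)
    }
  }
  common <- intersect(pampa$code, skin$code)
  unpaired <- setdiff(union(pampa$code, skin$code), common)
  if (length(common) == 0L) warning("no solvent codes in common; empty pairing")
  ip <- match(common, pampa$code); is_ <- match(common, skin$code)
  out <- data.frame(
    code = common,
    logPm_pampa = pick(pampa, "logPm_mean", "logPm")[ip],
    logKp_skin = pick(skin, "logKp_mean", "logKp")[is_],
    auc_norm_pampa = pick(pampa, "auc_norm_mean", "auc_norm")[ip],
    Qt_skin = pick(skin, "Q_mean", "Qt")[is_],
    J_pampa = pick(pampa, "J_mean", "J")[ip],
    J_skin = pick(skin, "J_mean", "J")[is_],
    stringsAsFactors = FALSE)
  attr(out, "unpaired") <- unpaired
  class(out) <- c("paired_permeability", "data.frame")
  out
}

ols_summary <- function(x, y, excluded = character()) {
  if (length(x) < 2L) stop("need at least 2 points", call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance in predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  # R^2 computed directly; summary.lm() warns on exact fits
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (tss == 0) NA_real_ else 1 - rss / tss,
                 n = length(x), excluded = excluded, fit = fit),
            class = "regression_summary")
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf("OLS: slope %.4g, intercept %.4g, R^2 = %.4f, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$n))
  if (length(x$excluded)) cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Log-permeability regression between models
#'
#' OLS of the skin log-permeability on the screen log-permeability
#' (the screen is the predictor). No automatic exclusions; R-squared is
#' direction-invariant so the regression orientation affects only slope
#' and intercept.
#'
#' @param pairs A [pair_models()] result (>= 3 rows).
#' @return A `regression_summary`: `slope`, `intercept`, `r_squared`, `n`,
#'   `excluded`.
#' @export
regress_log_permeability <- function(pairs) {
  if (nrow(pairs) < 3L) stop("need at least 3 pairs", call. = FALSE)
  ols_summary(pairs$logPm_pampa, pairs$logKp_skin)
}

#' Permeated-amount correlation between models
#'
#' OLS of the ex vivo permeated amount on the screen's normalised AUC over
#' the non-excluded pairs. Exclusions are caller-specified (outlier calls
#' in this comparison are judgement calls, not algorithmic; see
#' [flag_outliers()] for a formal helper) and are recorded in the output.
#'
#' @param pairs A [pair_models()] result.
#' @param exclude Character vector of solvent codes to drop.
#' @return A `regression_summary`.
#' @export
correlate_amounts <- function(pairs, exclude = character()) {
  keep <- !(pairs$code %in% exclude)
  if (sum(keep) < 3L) stop("fewer than 3 pairs left after exclusion", call. = FALSE)
  ols_summary(pairs$auc_norm_pampa[keep], pairs$Qt_skin[keep],
              excluded = intersect(exclude, pairs$code))
}

#' Flag regression outliers by studentized residual
#'
#' Formalises visual outlier calls: fits the requested pairwise OLS and
#' flags pairs whose externally studentized residual exceeds `threshold`
#' in absolute value.
#'
#' @param pairs A [pair_models()] result (>= 4 rows).
#' @param quantity Which comparison: `"amount"` (Qt_skin ~ auc_norm_pampa),
#'   `"log_permeability"` (logKp_skin ~ logPm_pampa) or `"flux"`
#'   (J_skin ~ J_pampa).
#' @param threshold Absolute studentized-residual cutoff, default 2.
#' @return Logical vector (named by code): `TRUE` = flagged.
#' @export
flag_outliers <- function(pairs,
                          quantity = c("amount", "log_permeability", "flux"),
                          threshold = 2.0) {
  quantity <- match.arg(quantity)
  if (nrow(pairs) < 4L) stop("need at least 4 pairs", call. = FALSE)
  xy <- switch(quantity,
    amount = list(pairs$auc_norm_pampa, pairs$Qt_skin),
    log_permeability = list(pairs$logPm_pampa, pairs$logKp_skin),
    flux = list(pairs$J_pampa, pairs$J_skin))
  fit <- ols_summary(xy[[1]], xy[[2]])$fit
  rs <- stats::rstudent(fit)
  # exact fits make rstudent 0/0 (or numerical garbage): a residual that is
  # zero at the response scale is no outlier; a genuine residual whose
  # leave-one-out sigma vanishes is an infinite one
  res <- stats::residuals(fit)
  tol <- 1e-10 * max(abs(xy[[2]]), 1)
  rs[abs(res) < tol] <- 0
  rs[!is.finite(rs)] <- Inf
  out <- abs(rs) > threshold
  names(out) <- pairs$code
  out
}

#' Flux concordance between models
#'
#' Per-solvent log10 ratio of screen to ex vivo flux, banded into
#' `within_1_order` (|ratio| < 1), `1_to_2_orders` (1 <= |ratio| < 2) and
#' `over_2_orders` (|ratio| >= 2). Invariant to common rescaling of both
#' fluxes. A zero flux on either side yields an `NA` ratio with category
#' `"undefined"`.
#'
#' @param pairs A [pair_models()] result.
#' @return `data.frame` with `code`, `log10_ratio`, `category`.
#' @export
flux_concordance <- function(pairs) {
  ratio <- ifelse(pairs$J_pampa > 0 & pairs$J_skin > 0,
                  log10(pairs$J_pampa / pairs$J_skin), NA_real_)
  category <- ifelse(is.na(ratio), "undefined",
               ifelse(abs(ratio) < 1, "within_1_order",
                ifelse(abs(ratio) < 2, "1_to_2_orders", "over_2_orders")))
  data.frame(code = pairs$code, log10_ratio = ratio, category = category,
             stringsAsFactors = FALSE)
}

#' Membrane-integrity assessment
#'
#' After pre-treating membranes with each solvent, a reference permeant of
#' precisely known permeability is re-measured; shifts or inflated
#' variance of its logPm indicate membrane damage. A solvent passes when
#' the absolute shift of its mean probe logPm from the reference is at
#' most `delta_threshold` (default one order of magnitude) and its
#' replicate SD is at most `sd_threshold`.
#'
#' @param probe Data frame with columns `code` and `logPm` (one row per
#'   probe replicate), or columns `code`, `logPm_mean`, `logPm_sd` for
#'   pre-aggregated data.
#' @param reference Reference probe logPm on untreated membranes.
#' @param reference_sd Its SD (reported, not used in the criterion).
#' @param delta_threshold Maximum |mean - reference|, log10 units.
#' @param sd_threshold Maximum per-solvent SD, log10 units.
#' @return List of class `integrity_report`: `per_solvent` frame
#'   (`code, logPm_mean, logPm_sd, delta, pass`), `reference`,
#'   `reference_sd`, `overall_mean`, `overall_sd` (across solvent means).
#' @export
integrity_assessment <- function(probe, reference, reference_sd = NA_real_,
                                 delta_threshold = 1.0, sd_threshold = 0.3) {
  stopifnot(is.data.frame(probe), "code" %in% names(probe))
  per <- if ("logPm_mean" %in% names(probe)) {
    data.frame(code = probe$code, logPm_mean = probe$logPm_mean,
               logPm_sd = if ("logPm_sd" %in% names(probe)) probe$logPm_sd else NA_real_,
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(split(probe, probe$code), function(g) {
      data.frame(code = g$code[1], logPm_mean = mean(g$logPm),
                 logPm_sd = if (nrow(g) > 1L) stats::sd(g$logPm) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  per$delta <- abs(per$logPm_mean - reference)
  sd_ok <- is.na(per$logPm_sd) | per$logPm_sd <= sd_threshold
  per$pass <- per$delta <= delta_threshold & sd_ok
  rownames(per) <- NULL
  structure(list(per_solvent = per, reference = reference,
                 reference_sd = reference_sd,
                 overall_mean = mean(per$logPm_mean),
                 overall_sd = if (nrow(per) > 1L) stats::sd(per$logPm_mean) else NA_real_),
            class = "integrity_report")
}

#' @export
print.integrity_report <- function(x, ...) {
  cat(sprintf("Membrane integrity: probe logPm %.2f +/- %.2f (reference %.2f)\n",
              x$overall_mean, x$overall_sd, x$reference))
  print(transform(x$per_solvent,
                  logPm_mean = round(logPm_mean, 2),
                  delta = round(delta, 2)), row.names = FALSE)
  invisible(x)
}
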