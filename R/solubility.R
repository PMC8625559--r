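#' Stepwise solubility grid
#'
#' The semi-quantitative solubility scale used to pick near-saturation
#' donor concentrations: decade categories spanning 1-1000 mg/mL, each
#' refined by quarter-decade subclasses (2.5, 5, 7.5 within 1-10, and so
#' on multiplicatively), 13 probe values in total.
#'
#' @param decades Category anchors, mg/mL, strictly ascending.
#' @param subclasses Within-decade multipliers in (1, 10).
#' @return Object of class `solubility_grid` with `values` (ascending
#'   probe concentrations) and `top` (the top grid value).
#' @export
solubility_grid <- function(decades = c(1, 10, 100, 1000),
                            subclasses = c(2.5, 5, 7.5)) {
  if (is.unsorted(decades, strictly = TRUE) || any(decades <= 0)) {
    stop("decades must be positive and strictly ascending", call. = FALSE)
  }
  vals <- sort(unique(c(decades,
                        as.numeric(outer(subclasses, utils::head(decades, -1))))))
  vals <- vals[vals <= max(decades)]
  structure(list(values = vals, decades = decades, top = max(decades)),
            class = "solubility_grid")
}

#' Dissolution oracle
#'
#' Abstracts the visual "fully dissolved?" assessment of the stepwise
#' solubility protocol as a monotone predicate: if a compound dissolves
#' completely at concentration c it dissolves at any lower concentration.
#' [make_dissolution_oracle()] builds the ideal threshold oracle used by
#' the simulator; any function with the same contract can be supplied
#' (e.g. one backed by recorded observations).
#'
#' @param S_true True saturation solubility, mg/mL (> 0). Queries at
#'   exactly `S_true` report dissolved (boundary inclusive).
#' @return A function `query(concentration) -> logical`.
#' @export
make_dissolution_oracle <- function(S_true) {
  if (!is.numeric(S_true) || S_true <= 0) stop("S_true must be > 0", call. = FALSE)
  force(S_true)
  function(concentration) concentration <= S_true
}

#' Stepwise approximate solubility
#'
#' Classifies solubility on the grid by probing the coarse decade
#' categories first and then the subclasses inside the located category,
#' mirroring the add-solvent-and-inspect bench procedure. Returns the
#' largest grid concentration at which the oracle reports complete
#' dissolution.
#'
#' @param oracle A monotone dissolution predicate
#'   (see [make_dissolution_oracle()]).
#' @param grid A [solubility_grid()].
#' @return List of class `approx_solubility`: `value` (mg/mL, `Inf` above
#'   the top of the grid, `NA` below the bottom), `label` (printable,
#'   e.g. `">1000"`), `flags`.
#' @examples
#' approximate_solubility(make_dissolution_oracle(1.3))   # "1"
#' approximate_solubility(make_dissolution_oracle(2000))  # ">1000"
#' @export
approximate_solubility <- function(oracle, grid = solubility_grid()) {
  stopifnot(is.function(oracle), inherits(grid, "solubility_grid"))
  res <- function(value, label, flags = character()) {
    structure(list(value = value, label = label, flags = flags),
              class = "approx_solubility")
  }
  dec <- grid$decades
  if (!isTRUE(oracle(dec[1]))) {
    return(res(NA_real_, paste0("<", dec[1]), "insoluble_below_grid"))
  }
  if (isTRUE(oracle(grid$top))) {
    return(res(Inf, paste0(">", grid$top)))
  }
  # highest decade at which dissolution was seen; category above it failed
  k <- max(which(vapply(dec, function(d) isTRUE(oracle(d)), logical(1))))
  within <- grid$values[grid$values > dec[k] & grid$values < dec[k + 1]]
  best <- dec[k]
  for (v in within) {
    if (isTRUE(oracle(v))) best <- v else break
  }
  res(best, format(best, trim = TRUE))
}

#' @export
print.approx_solubility <- function(x, ...) {
  cat("Approximate solubility:", x$label, "mg/mL\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Donor concentration rule
#'
#' Donor solutions are prepared at the approximate solubility, capped at
#' half the top solubility category (default 500 mg/mL); the above-grid
#' sentinel maps to the cap. A below-grid result means the compound cannot
#' be dosed in that solvent and is an error.
#'
#' @param approx An `approx_solubility` result or a plain mg/mL number.
#' @param cap Maximum donor concentration, mg/mL.
#' @return Donor concentration C_D, mg/mL.
#' @export
donor_concentration_rule <- function(approx, cap = 500) {
  value <- if (inherits(approx, "approx_solubility")) approx$value else approx
  if (is.na(value)) {
    stop("compound not soluble at the lowest grid concentration; ",
         "unusable in this solvent", call. = FALSE)
  }
  min(value, cap)
}

#' Intrinsic solubility from replicate saturation measurements
#'
#' @param measurements Numeric vector of equilibrium solubilities, mg/mL.
#' @return List `mean`, `sd` (`NA` for a single measurement), `n`.
#' @export
intrinsic_solubility <- function(measurements) {
  if (length(measurements) < 1L) stop("no measurements", call. = FALSE)
  list(mean = mean(measurements),
       sd = if (length(measurements) > 1L) stats::sd(measurements) else NA_real_,
       n = length(measurements))
}

#' Sink-condition concentration cap
#'
#' The target upper limit for acceptor concentrations: a fraction
#' (conventionally 10 percent) of the intrinsic solubility in the acceptor
#' medium.
#'
#' @param S0 Intrinsic solubility, mg/mL (> 0).
#' @param fraction Cap fraction, default 0.1.
#' @return Cap in mg/mL.
#' @examples
#' sink_cap(3.45)  # 0.345
#' @export
sink_cap <- function(S0, fraction = 0.1) {
  if (S0 <= 0) stop("S0 must be > 0", call. = FALSE)
  fraction * S0
}

#' Shake-flask run
#'
#' One octanol/water partition experiment quantified by the drop in
#' aqueous-phase absorbance: `A0` before and `A1` after equilibration,
#' with phase volumes `Vaq` and `Voct`.
#'
#' @param A0,A1 Aqueous absorbance before/after partition (0 < A1 <= A0).
#' @param Vaq,Voct Aqueous and octanol phase volumes, mL (> 0).
#' @return Object of class `shake_flask_run`.
#' @export
shake_flask_run <- function(A0, A1, Vaq, Voct) {
  if (Vaq <= 0 || Voct <= 0) stop("phase volumes must be > 0", call. = FALSE)
  if (A1 <= 0 || A1 > A0) stop("need 0 < A1 <= A0", call. = FALSE)
  structure(list(A0 = A0, A1 = A1, Vaq = Vaq, Voct = Voct),
            class = "shake_flask_run")
}

#' Shake-flask logP
#'
#' `logP = log10( ((A0 - A1)/A1) * (Vaq/Voct) )`: the partition
#' coefficient recovered from the aqueous absorbance drop at a known phase
#' ratio. `A1 = A0` (no measurable partition) yields `-Inf` with a
#' `no_partition` flag attribute rather than an error.
#'
#' @param run A [shake_flask_run()].
#' @return logP (unitless log10).
#' @export
shake_flask_logP <- function(run) {
  stopifnot(inherits(run, "shake_flask_run"))
  if (run$A1 == run$A0) {
    out <- -Inf
    attr(out, "flags") <- "no_partition"
    return(out)
  }
  log10(((run$A0 - run$A1) / run$A1) * (run$Vaq / run$Voct))
}

#' Mean logP across phase ratios
#'
#' Per-run logP values averaged with equal weights (mean and sample SD).
#'
#' @param runs A list of [shake_flask_run()] objects.
#' @return List `mean`, `sd` (`NA` for a single run), `n`, `logP` (per run).
#' @export
mean_logP <- function(runs) {
  if (length(runs) < 1L) stop("no runs", call. = FALSE)
  lp <- vapply(runs, function(r) as.numeric(shake_flask_logP(r)), numeric(1))
  list(mean = mean(lp),
       sd = if (length(lp) > 1L) stats::sd(lp) else NA_real_,
       n = length(lp), logP = lp)
}
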