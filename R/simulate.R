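#' Mechanistic membrane parameters
#'
#' A homogeneous membrane of thickness `h` with permeant diffusivity `D`
#' and membrane/vehicle partition coefficient `K` has steady-state
#' permeability `P = K D / h` (cm/h) and diffusional lag time
#' `h^2 / (6 D)`. These three numbers fully determine the infinite-dose,
#' perfect-sink cumulative permeation curve.
#'
#' @param K Partition coefficient, unitless (> 0).
#' @param D Diffusivity, cm^2/h (> 0).
#' @param h Membrane thickness, cm (> 0).
#' @return Object of class `membrane_params` with derived `Pm` (cm/h) and
#'   `lag_min` (minutes).
#' @seealso [membrane_params_from()] to parameterise by target P and lag.
#' @export
membrane_params <- function(K, D, h) {
  if (any(c(K, D, h) <= 0)) stop("K, D, h must all be > 0", call. = FALSE)
  structure(list(K = K, D = D, h = h,
                 Pm = K * D / h, lag_min = h^2 / (6 * D) * 60),
            class = "membrane_params")
}

#' @rdname membrane_params
#' @param Pm Target permeability coefficient, cm/h.
#' @param lag_min Target lag time, minutes.
#' @export
membrane_params_from <- function(Pm, lag_min, h = 0.01) {
  if (Pm <= 0 || lag_min <= 0) stop("Pm and lag_min must be > 0", call. = FALSE)
  D <- h^2 / (6 * (lag_min / 60))
  membrane_params(K = Pm * h / D, D = D, h = h)
}

#' @export
print.membrane_params <- function(x, ...) {
  cat(sprintf("Membrane: K = %g, D = %g cm^2/h, h = %g cm\n", x$K, x$D, x$h))
  cat(sprintf("  => P = %g cm/h (logP = %.3f), lag = %.3g min\n",
              x$Pm, log10(x$Pm), x$lag_min))
  invisible(x)
}

#' Analytic infinite-dose cumulative permeation
#'
#' Exact series solution of diffusion through a homogeneous membrane with
#' a constant donor concentration and a perfect sink on the acceptor side:
#' \deqn{Q(t) = K h C_D [D t/h^2 - 1/6
#'   - (2/\pi^2) \sum_{n\ge1} ((-1)^n/n^2) e^{-D n^2 \pi^2 t / h^2}]}
#' (the factor 1000 converts mg/mL to ug/cm^3). The series is truncated
#' once a term falls below 1e-12 of the leading scale; `t = 0` returns an
#' exact 0 (the alternating series cancels there only in the limit).
#' For `t >> h^2/D` the curve approaches the line `J_ss (t - lag)` with
#' `J_ss = K D C_D 1000 / h`.
#'
#' @param t Times, hours (>= 0); vectorised.
#' @param mp A [membrane_params()].
#' @param C_D Donor concentration, mg/mL.
#' @return Cumulative permeated amount per area, ug/cm^2.
#' @export
analytic_cumulative <- function(t, mp, C_D) {
  stopifnot(inherits(mp, "membrane_params"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  scale <- mp$K * mp$h * C_D * 1000
  tau <- mp$D / mp$h^2          # 1/h
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    acc <- tau * ti - 1 / 6
    lead <- max(abs(acc), 1)
    n <- 1
    repeat {
      term <- (-1)^n / n^2 * exp(-tau * n^2 * pi^2 * ti)
      acc <- acc - 2 / pi^2 * term
      if (abs(term) < 1e-12 * lead || n >= 1e5) break
      n <- n + 1
    }
    max(scale * acc, 0)   # series tail can leave a ~1e-12 negative residue
  }, numeric(1))
}

#' Simulate a permeation assay
#'
#' Generates the acceptor concentrations a plate reader (or LC sampler)
#' would report for a membrane with known parameters: cumulative amounts
#' from [analytic_cumulative()] at the plan's sampling times, converted to
#' per-sampling acceptor concentrations according to the replacement mode,
#' with multiplicative lognormal measurement noise (mean-one, coefficient
#' of variation `cv`). The known true metrics are carried along so
#' recovery can be tested end to end. Optionally emits raw absorbances via
#' the forward calibration map.
#'
#' @param mp A [membrane_params()].
#' @param plan A [sampling_plan()]; its `donor_concentration` drives the
#'   simulation.
#' @param cv Coefficient of variation of the multiplicative measurement
#'   noise; 0 disables noise. Default 0.05 (typical UV plate-read
#'   replicate scatter).
#' @param seed Integer RNG seed; same seed, same records (the global RNG
#'   state is restored on exit).
#' @param replicates Number of replicate wells (independent noise draws).
#' @param calib Optional [calibration_curve()]; when supplied, absorbances
#'   `A = slope * c/dilution + intercept` are attached.
#' @param solvent_code Label for the generated records.
#' @param donor_decay Optional fractional exponential decline of the
#'   effective donor concentration per hour; a stress-test knob for
#'   creating donor-depletion scenarios, 0 (infinite dose) by default.
#' @return Object of class `simulated_assay`: `plan`, `params`,
#'   `true_metrics` (`J_ss`, `lag_min`, `logPm`), `records`
#'   ([concentration_records()]), and `absorbances` (data frame or NULL).
#' @export
simulate_assay <- function(mp, plan, cv = 0.05, seed = 1L, replicates = 1L,
                           calib = NULL, solvent_code = "SIM",
                           donor_decay = 0) {
  stopifnot(inherits(mp, "membrane_params"), inherits(plan, "sampling_plan"))
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  C_D <- plan$donor_concentration
  tt <- plan$sampling_times
  Q <- analytic_cumulative(tt, mp, C_D)
  dQ <- diff(c(0, Q))
  if (donor_decay > 0) {
    mids <- (c(0, utils::head(tt, -1)) + tt) / 2
    dQ <- dQ * exp(-donor_decay * mids)
  }
  A <- plan$exposure_area; VA <- plan$acceptor_volume; Vs <- plan$sampled_volume

  conc_true <- switch(plan$replacement_mode,
    full_replacement = A * dQ / (VA * 1000),
    sample_and_replace = {
      m <- 0; out <- numeric(length(dQ))
      for (i in seq_along(dQ)) {
        m <- m + A * dQ[i]               # ug in acceptor before sampling
        out[i] <- m / (VA * 1000)        # mg/mL
        m <- m * (1 - Vs / VA)           # aliquot removed, fresh fluid added
      }
      out
    })

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + cv^2))
  recs <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    noise <- if (cv > 0) {
      exp(stats::rnorm(length(conc_true), -sdlog^2 / 2, sdlog))  # mean one
    } else rep(1, length(conc_true))
    concentration_records(solvent_code, r, tt, conc_true * noise)
  }))
  class(recs) <- c("concentration_records", "data.frame")

  absorb <- NULL
  if (!is.null(calib)) {
    absorb <- data.frame(
      solvent_code = recs$solvent_code, replicate = recs$replicate,
      time_h = recs$time_h, dilution = rep(plan$dilution_factors, replicates),
      absorbance = concentration_to_absorbance(
        recs$concentration / rep(plan$dilution_factors, replicates), calib),
      stringsAsFactors = FALSE)
  }

  structure(
    list(plan = plan, params = mp,
         true_metrics = list(J_ss = mp$Pm * C_D * 1000, lag_min = mp$lag_min,
                             logPm = log10(mp$Pm)),
         records = recs, absorbances = absorb),
    class = "simulated_assay"
  )
}

#' Simulate a shake-flask partition experiment
#'
#' Equilibrium two-phase mass balance with the aqueous absorbance
#' proportional to the aqueous concentration:
#' `A1 = A0 * Vaq / (Vaq + P * Voct)`. Round-tripping through
#' [shake_flask_logP()] recovers `log10(P)` exactly.
#'
#' @param P True partition coefficient (unitless, > 0).
#' @param Vaq,Voct Phase volumes, mL.
#' @param A0 Initial aqueous absorbance.
#' @return A [shake_flask_run()].
#' @export
simulate_partition <- function(P, Vaq, Voct, A0 = 1) {
  if (any(c(P, Vaq, Voct, A0) <= 0)) stop("all inputs must be > 0", call. = FALSE)
  shake_flask_run(A0 = A0, A1 = A0 * Vaq / (Vaq + P * Voct),
                  Vaq = Vaq, Voct = Voct)
}
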