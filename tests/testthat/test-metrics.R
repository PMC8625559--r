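test_that("flux and lag recover exact lines", {
  t3 <- c(0.125, 0.25, 0.5)
  # line through the origin
  f0 <- fit_flux(linear_profile(t3, 100), fit_window())
  expect_equal(f0$J, 100, tolerance = 1e-12)
  expect_equal(f0$lag_min, 0, tolerance = 1e-9)
  # x-intercept at 0.05 h = 3 min (origin excluded by default)
  f1 <- fit_flux(linear_profile(t3, 100, lag_h = 0.05))
  expect_equal(f1$J, 100, tolerance = 1e-12)
  expect_equal(f1$lag_min, 3, tolerance = 1e-9)
  # negative intercept-implied lag clamps to zero
  prof <- linear_profile(t3, 100, lag_h = -0.02)
  expect_equal(fit_flux(prof)$lag_min, 0)
  # the origin option is honoured
  f2 <- fit_flux(linear_profile(t3, 100), fit_window(include_origin = TRUE))
  expect_equal(f2$J, 100, tolerance = 1e-12)
})

test_that("degenerate fits error or clamp as specified", {
  bad <- structure(list(solvent_code = "X", replicate = 1L,
                        times = c(0.25, 0.25), Q = c(1, 2), flags = character()),
                   class = "cumulative_profile")
  expect_error(fit_flux(bad), "singular")
  one <- linear_profile(0.25, 100)
  expect_error(fit_flux(one), "at least 2 points")
  declining <- structure(list(solvent_code = "X", replicate = 1L,
                              times = c(0.125, 0.25, 0.5), Q = c(3, 2, 1),
                              flags = character()),
                         class = "cumulative_profile")
  fd <- fit_flux(declining)
  expect_equal(fd$J, 0)
  expect_true("negative_slope" %in% fd$flags)
})

test_that("fit_flux agrees with the lm oracle on noisy data", {
  set.seed(5)
  for (i in 1:10) {
    t <- sort(runif(5, 0.05, 0.6))
    Q <- 50 * t + rnorm(5, sd = 2)
    prof <- structure(list(solvent_code = "X", replicate = 1L, times = t,
                           Q = Q, flags = character()),
                      class = "cumulative_profile")
    f <- fit_flux(prof, fit_window(0, 1))
    cf <- coef(lm(Q ~ t))
    expect_equal(f$J, unname(cf[2]), tolerance = 1e-10)
    expect_equal(f$intercept, unname(cf[1]), tolerance = 1e-10)
  }
})

test_that("permeability coefficient reproduces worked examples", {
  expect_equal(round(permeability_coefficient(12033, 500), 2), -1.62)
  expect_equal(round(permeability_coefficient(589, 10), 2), -1.23)
  expect_equal(permeability_coefficient(1000, 1), 0)
  z <- permeability_coefficient(0, 10)
  expect_identical(as.numeric(z), -Inf)
  expect_true("zero_flux" %in% attr(z, "flags"))
  expect_error(permeability_coefficient(10, 0), "C_D")
  expect_error(permeability_coefficient(-1, 10), ">= 0")
})

test_that("logPm is invariant to common rescaling of J and C_D", {
  set.seed(9)
  for (i in 1:20) {
    J <- runif(1, 1, 1e4); C_D <- runif(1, 0.5, 500); k <- runif(1, 1e-3, 1e3)
    expect_equal(permeability_coefficient(J, C_D),
                 permeability_coefficient(k * J, k * C_D), tolerance = 1e-12)
  }
})

test_that("normalised AUC matches closed forms", {
  plan <- plate_plan()
  lin <- linear_profile(plan$sampling_times, 100)
  # J*T^2/2/C_D for a linear profile through the origin
  expect_equal(auc_normalized(lin, 6, C_D = 1), 100 * 36 / 2, tolerance = 1e-9)
  set.seed(13)
  for (i in 1:10) {
    J <- runif(1, 1, 500); C_D <- runif(1, 0.5, 100)
    lp <- linear_profile(plan$sampling_times, J)
    expect_equal(auc_normalized(lp, 6, C_D), J * 18 / C_D, tolerance = 1e-9)
  }
  # hand trapezoid: (0,0), (3,30), (6,60) -> 45 + 135 = 180; / C_D = 90
  two <- structure(list(solvent_code = "X", replicate = 1L, times = c(3, 6),
                        Q = c(30, 60), flags = character()),
                   class = "cumulative_profile")
  expect_equal(auc_normalized(two, 6, C_D = 2), 90)
  expect_equal(auc_normalized(linear_profile(plan$sampling_times, 0), 6, 1), 0)
  expect_error(auc_normalized(two, 7, 1), "beyond")
  # interior horizon interpolates
  expect_equal(auc_normalized(two, 4.5, 2), (0.5 * 3 * 30 + 1.5 * (30 + 45) / 2) / 2)
})

test_that("permeability classes use strict contiguous cutpoints", {
  expect_equal(classify_permeability(-1.12), "high")
  expect_equal(classify_permeability(-2.63), "low")
  expect_equal(classify_permeability(c(-1.5, -2.4)), c("medium", "medium"))
  expect_equal(classify_permeability(-1.49999), "high")
  expect_equal(classify_permeability(-1.20, cutpoints = c(-2.4, -1.2)), "medium")
  expect_error(classify_permeability(-1, cutpoints = c(-1, -2)), "ordered")
})

test_that("replicate summaries use hand mean/SD, log-scale for logPm", {
  prof <- function(r, J) linear_profile(c(0.125, 0.25, 0.5, 6), J,
                                        code = "S1", rep = r)
  m <- rbind(permeation_metrics(prof(1, 70), C_D = 1),
             permeation_metrics(prof(2, 75), C_D = 1))
  s <- summarize_replicates(m)
  expect_equal(s$J_mean, 72.5)
  expect_equal(s$J_sd, sd(c(70, 75)), tolerance = 1e-12)  # 3.5355
  expect_equal(s$logPm_mean, mean(log10(c(70, 75) / 1000)), tolerance = 1e-12)
  expect_equal(s$n, 2)

  # hand case from log values {-1.60, -1.64}
  expect_equal(mean(c(-1.60, -1.64)), -1.62)
  expect_equal(sd(c(-1.60, -1.64)), 0.02828427, tolerance = 1e-6)

  s1 <- summarize_replicates(permeation_metrics(prof(1, 70), C_D = 1))
  expect_true(is.na(s1$J_sd))
  expect_equal(s1$n, 1)
})

test_that("analyze_profiles produces a per-solvent report from simulations", {
  plan <- plate_plan(10)
  mp <- membrane_params_from(Pm = 0.05, lag_min = 1)
  sim <- simulate_assay(mp, plan, cv = 0, seed = 2, replicates = 3,
                        solvent_code = "SX")
  profs <- assemble_profiles(sim$records, plan)
  rep_tab <- analyze_profiles(profs, plan)
  expect_equal(nrow(rep_tab), 1)
  expect_equal(rep_tab$code, "SX")
  expect_equal(rep_tab$logPm_mean, log10(0.05), tolerance = 1e-6)
  expect_equal(rep_tab$perm_class, "high")  # log10(0.05) = -1.30 > -1.5
})
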