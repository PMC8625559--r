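test_that("cumulative amount matches hand mass balances", {
  # full replacement: Q(t_i) = 1000 * (V_A/A) * cumsum(c)
  p1 <- sampling_plan(c(0.125, 0.25), acceptor_volume = 0.18,
                      sampled_volume = 0.18, replacement_mode = "full_replacement",
                      exposure_area = 0.3, donor_volume = 0.07,
                      donor_concentration = 1)
  expect_equal(cumulative_amount(c(0.01, 0.02), p1)$Q, c(6, 18))
  expect_equal(cumulative_amount(c(0, 0), p1)$Q, c(0, 0))

  # sample-and-replace Franz correction
  p2 <- sampling_plan(c(1, 2), acceptor_volume = 2, sampled_volume = 0.2,
                      replacement_mode = "sample_and_replace",
                      exposure_area = 1, donor_volume = 1,
                      donor_concentration = 1)
  expect_equal(cumulative_amount(c(0.01, 0.01), p2)$Q, c(20, 22))
})

test_that("input contract violations are hard errors", {
  p <- plate_plan()
  expect_error(cumulative_amount(rep(0.01, 6), p), "one concentration per")
  expect_error(cumulative_amount(c(rep(0.01, 6), -0.01), p), "negative")
  recs <- concentration_records("S1", 1, c(7.5, 15, 30, 60, 120, 240) / 60,
                                rep(0.01, 6))
  expect_error(cumulative_amount(recs, p), "missing or extra timepoint")
})

test_that("mass is conserved under full replacement", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(3:10, 1)
    plan <- sampling_plan(sort(runif(n, 0.1, 16)),
                          acceptor_volume = runif(1, 0.1, 5),
                          sampled_volume = 0.05,
                          replacement_mode = "full_replacement",
                          exposure_area = runif(1, 0.2, 2),
                          donor_volume = 1, donor_concentration = 1)
    plan$sampled_volume <- plan$acceptor_volume
    conc <- runif(n, 0, 0.5)
    Q <- cumulative_amount(conc, plan)$Q
    removed <- sum(conc * plan$acceptor_volume * 1000)  # ug withdrawn in total
    expect_equal(removed, plan$exposure_area * Q[n],
                 tolerance = 1e-9)
    expect_true(all(diff(Q) >= 0))
  }
})

test_that("sample_and_replace with V_s = V_A reduces to full replacement", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    times <- sort(runif(n, 0.1, 16))
    conc <- runif(n, 0, 0.5)
    args <- list(sampling_times = times, acceptor_volume = 2,
                 sampled_volume = 2, exposure_area = 0.7,
                 donor_volume = 1, donor_concentration = 3)
    qa <- do.call(sampling_plan, c(args, replacement_mode = "full_replacement"))
    qb <- do.call(sampling_plan, c(args, replacement_mode = "sample_and_replace"))
    expect_identical(cumulative_amount(conc, qa)$Q, cumulative_amount(conc, qb)$Q)
  }
})

test_that("Q is non-decreasing for physically generated records in both modes", {
  # sample-and-replace can only dilute the acceptor by Vs/VA between
  # samplings, so concentrations from a real influx never make Q decrease
  for (mode in c("full_replacement", "sample_and_replace")) {
    for (seed in 1:5) {
      mp <- membrane_params_from(Pm = 10^runif(1, -3, -1), lag_min = runif(1, 0.5, 5))
      plan <- if (mode == "full_replacement") plate_plan(10) else
        pigskin_sampling_plan(acceptor_volume = 5, exposure_area = 1,
                              donor_concentration = 10)
      sim <- simulate_assay(mp, plan, cv = 0, seed = seed)
      Q <- cumulative_amount(sim$records, plan)$Q
      expect_true(all(diff(Q) >= -1e-12))
    }
  }
})

test_that("sink check uses a strict cap at fraction * solubility", {
  expect_false(sink_check(c(0.1, 0.3), 3.45))
  expect_false(sink_check(0.345, 3.45))          # boundary passes
  expect_true(sink_check(c(0.1, 0.40), 3.45))
  expect_true(sink_check(0.40, 3.45, fraction = 0.1))
  expect_false(sink_check(0.40, 3.45, fraction = 0.2))
  expect_error(sink_check(0.1, 0), "> 0")
})

test_that("donor depletion flags profiles past 10% of the applied dose", {
  plan <- plate_plan(1)  # dose/area = 1 * 0.07 * 1000 / 0.3 = 233.3 ug/cm^2
  expect_equal(applied_dose_per_area(plan), 1000 * 0.07 / 0.3)
  prof_hi <- linear_profile(plan$sampling_times, slope = 169 / 6)  # Q(6h)=169
  expect_true(donor_depletion_check(prof_hi, plan))
  prof_0 <- linear_profile(plan$sampling_times, slope = 0)
  expect_false(donor_depletion_check(prof_0, plan))

  plan500 <- plate_plan(500)  # dose/area = 116,667; 13,575 is 11.6% -> flag
  prof <- linear_profile(plan500$sampling_times, slope = 13575 / 6)
  expect_true(donor_depletion_check(prof, plan500))
  expect_false(donor_depletion_check(prof, plan500, fraction = 0.15))
})

test_that("assemble_profiles attaches QC flags per replicate", {
  plan <- plate_plan(1)
  mp <- membrane_params_from(Pm = 0.1, lag_min = 1)
  sim <- simulate_assay(mp, plan, cv = 0, seed = 3, replicates = 2)
  profs <- assemble_profiles(sim$records, plan, acceptor_solubility = 3.45)
  expect_length(profs, 2)
  # J ~ 100 ug/cm^2/h at C_D = 1 -> Q(6h) ~ 600 >> 23.3 -> depletion flag
  expect_true(all(vapply(profs, function(p) "donor_depletion" %in% p$flags,
                         logical(1))))
  df <- profiles_to_frame(profs)
  expect_equal(nrow(df), 2 * length(plan$sampling_times))
  expect_named(df, c("solvent_code", "replicate", "time_h", "Q_ug_cm2", "flags"))
})
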