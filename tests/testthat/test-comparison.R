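test_that("pairing inner-joins on solvent code and reports the rest", {
  pairs <- ref_paired()
  expect_equal(nrow(pairs), 9)
  expect_setequal(attr(pairs, "unpaired"), c("S3", "S11", "S12", "S13"))

  a <- data.frame(code = c("A", "B"), logPm = 1:2, auc_norm = 1:2, J = 1:2)
  b <- data.frame(code = c("C", "D"), logKp = 1:2, Qt = 1:2, J = 1:2)
  expect_warning(empty <- pair_models(a, b), "no solvent codes")
  expect_equal(nrow(empty), 0)

  dup <- data.frame(code = c("S1", "S1"), logPm = 1:2, auc_norm = 1:2, J = 1:2)
  expect_error(pair_models(dup, b), "duplicate")
})

test_that("log-permeability regression matches independent oracles", {
  # perfectly collinear -> R^2 = 1
  expect_equal(regress_log_permeability(collinear_pairs())$r_squared, 1,
               tolerance = 1e-12)
  # R^2 identity with squared correlation, and axis-swap invariance
  set.seed(17)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    x <- rnorm(n); y <- 2 * x + rnorm(n)
    pr <- collinear_pairs(n)
    pr$logPm_pampa <- x; pr$logKp_skin <- y
    r2 <- regress_log_permeability(pr)$r_squared
    expect_equal(r2, cor(x, y)^2, tolerance = 1e-12)
    swapped <- pr
    swapped$logPm_pampa <- y; swapped$logKp_skin <- x
    expect_equal(regress_log_permeability(swapped)$r_squared, r2,
                 tolerance = 1e-12)
  }
  # frozen oracle value for the packaged nine-solvent table (lm oracle)
  reg <- regress_log_permeability(ref_paired())
  expect_gt(reg$slope, 0)
  expect_equal(reg$r_squared, 0.7984301, tolerance = 1e-6)
  expect_equal(reg$slope, 2.317769, tolerance = 1e-6)
  expect_equal(reg$n, 9)

  same_x <- collinear_pairs(3)
  same_x$logPm_pampa <- rep(1, 3)
  expect_error(regress_log_permeability(same_x), "zero variance")
  expect_error(regress_log_permeability(collinear_pairs(2)), "at least 3")
})

test_that("amount correlation honours caller exclusions", {
  amt <- correlate_amounts(ref_paired(), exclude = c("S1", "S6"))
  expect_equal(amt$n, 7)
  expect_setequal(amt$excluded, c("S1", "S6"))
  expect_equal(correlate_amounts(collinear_pairs())$r_squared, 1,
               tolerance = 1e-12)
  expect_error(correlate_amounts(collinear_pairs(4), exclude = c("S1", "S2")),
               "fewer than 3")
})

test_that("studentized-residual outlier flags behave at the edges", {
  # one displaced point against an otherwise perfect line
  shifted <- collinear_pairs(8, offsets = c(rep(0, 7), 5))
  fl <- flag_outliers(shifted, "amount")
  expect_true(fl[["S8"]])
  expect_false(any(fl[paste0("S", 1:7)]))
  # all points exactly on a line -> nothing to flag
  expect_false(any(flag_outliers(collinear_pairs(6), "amount")))
  # infinite threshold disables flagging entirely
  expect_false(any(flag_outliers(shifted, "amount", threshold = Inf)))
  # agreement with the rstudent oracle on noisy data
  set.seed(31)
  pr <- collinear_pairs(10, offsets = rnorm(10))
  fl2 <- flag_outliers(pr, "log_permeability", threshold = 1.5)
  oracle <- abs(rstudent(lm(pr$logKp_skin ~ pr$logPm_pampa))) > 1.5
  expect_equal(unname(fl2), unname(oracle))
  expect_error(flag_outliers(collinear_pairs(3)), "at least 4")
})

test_that("flux concordance bands and invariances", {
  pairs <- ref_paired()
  fc <- flux_concordance(pairs)
  expect_equal(fc$log10_ratio[fc$code == "S1"], log10(72.4 / 25),
               tolerance = 1e-12)  # 0.46
  expect_equal(fc$category[fc$code == "S1"], "within_1_order")
  expect_equal(fc$log10_ratio[fc$code == "S4"], log10(209 / 0.08),
               tolerance = 1e-12)  # 3.42
  expect_equal(fc$category[fc$code == "S4"], "over_2_orders")

  eq <- collinear_pairs(3)
  eq$J_pampa <- eq$J_skin <- c(1, 10, 100)
  expect_equal(flux_concordance(eq)$log10_ratio, rep(0, 3))

  # invariant to common rescaling of both fluxes
  sc <- pairs
  sc$J_pampa <- sc$J_pampa * 37.5; sc$J_skin <- sc$J_skin * 37.5
  expect_equal(flux_concordance(sc)$category, fc$category)
  expect_equal(flux_concordance(sc)$log10_ratio, fc$log10_ratio,
               tolerance = 1e-12)

  z <- eq; z$J_skin <- c(0, 1, 1)
  fz <- flux_concordance(z)
  expect_true(is.na(fz$log10_ratio[1]))
  expect_equal(fz$category[1], "undefined")
})

test_that("integrity assessment applies delta and SD criteria uniformly", {
  probe <- data.frame(code = c("S1", "S2", "S3"),
                      logPm_mean = c(-4.81, -4.25, -3.82),
                      logPm_sd = c(0.08, 0.23, 0.5))
  ir <- integrity_assessment(probe, reference = -4.98, reference_sd = 0.01)
  per <- ir$per_solvent
  expect_true(per$pass[per$code == "S1"])    # delta 0.17, sd 0.08
  expect_true(per$pass[per$code == "S2"])    # sd 0.23 <= 0.3
  expect_false(per$pass[per$code == "S3"])   # sd 0.5 and delta 1.16 both fail
  expect_equal(ir$overall_mean, mean(probe$logPm_mean))
  expect_equal(ir$overall_sd, sd(probe$logPm_mean))

  # raw replicate input aggregates first
  raw <- data.frame(code = rep(c("A", "B"), each = 3),
                    logPm = c(-4.9, -5.0, -5.1, -4.0, -4.2, -4.4))
  r2 <- integrity_assessment(raw, reference = -4.98)
  expect_equal(r2$per_solvent$logPm_mean, c(-5.0, -4.2))
  expect_equal(r2$per_solvent$logPm_sd, c(0.1, 0.2), tolerance = 1e-9)
  expect_true(all(r2$per_solvent$pass))
})
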